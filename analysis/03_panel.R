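#!/usr/bin/env Rscript
# Step 3 — qPCR candidate validation and panel sizing: aggregate the
# technical replicates of the 28-candidate Ct experiment, rank the
# candidates by stability, compute the pairwise variation V(n,n+1)
# between nested normalization factors, and recommend a panel size by
# the 0.15-threshold rule and the elbow rule.

suppressMessages(library(refpanel))

data_dir <- "results/data"
out <- "results"
ct <- read_ct_table(file.path(data_dir, "ct_validation.csv"))
truth <- jsonlite::read_json(file.path(data_dir, "truth.json"),
                             simplifyVector = TRUE)

agg <- aggregate_technical_replicates(ct)
em <- ct_to_expression_matrix(agg)
rk <- genorm_rank(em)
write_ranking(rk, file.path(out, "ct_stability_ranking.tsv"))

top6 <- stable_order(rk)[1:6]
cat("most stable candidates:", paste(top6, collapse = ", "), "\n")
cat("planted stable candidates among the top 6:",
    sum(truth$ct_validation$stable_set %in% top6), "of",
    length(truth$ct_validation$stable_set), "\n")

ps <- pairwise_variation_series(rk, em, max_n = 10)
print(ps)
write_panel_size_report(ps, file.path(out, "panel_size.tsv"),
                        json_path = file.path(out, "panel_size.json"))

panel_n <- ps$n_elbow  # headline: the elbow, as the threshold rule
                       # saturates as soon as V dips under 0.15
panel <- stable_order(rk)[seq_len(panel_n)]
cat("recommended panel (", panel_n, " genes): ",
    paste(panel, collapse = ", "), "\n", sep = "")
nf <- normalization_factor(em, panel)
utils::write.table(data.frame(sample = names(nf$nf_log2),
                              nf_log2 = unname(nf$nf_log2)),
                   file.path(out, "normalization_factor.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
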