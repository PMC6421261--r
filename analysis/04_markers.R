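#!/usr/bin/env Rscript
# Step 4 — does the new panel change conclusions? Compares the
# stable-panel normalization factor against classical single-gene and
# combined NFs (Pearson r with Fisher-z CIs), then runs matched marker
# tests (delta-Ct, paired t) for the SASP markers under both NFs.

suppressMessages(library(refpanel))

data_dir <- "results/data"
out <- "results"
classics <- c("UBC_like", "GAPDH_like", "ACTB_like")

## NF comparison on the validation arm (control + senescent, n = 6)
ct <- read_ct_table(file.path(data_dir, "ct_validation.csv"))
agg <- aggregate_technical_replicates(ct)
em <- ct_to_expression_matrix(agg)
rk <- genorm_rank(em)
panel <- stable_order(rk)[1:4]
keep <- sample_ids(em)[em$condition_of %in% c("control", "senescent")]
em6 <- subset_matrix(em, samples = keep)
nf_new <- normalization_factor(em6, panel)
classic_nfs <- c(lapply(stats::setNames(classics, sub("_like", "", classics)),
                        function(g) normalization_factor(em6, g)),
                 list(classic = normalization_factor(em6, classics)))
cmp <- compare_nfs(nf_new, classic_nfs)
utils::write.table(cmp, file.path(out, "nf_comparison.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("NF comparison (new panel:", paste(panel, collapse = ", "), ")\n")
print(cmp, digits = 3)
if (all(cmp$contains_zero))
  cat("all CIs include zero: no evidence the new NF tracks any classical NF\n")

## matched marker tests on the young vs late-passage arm
mk <- read_ct_table(file.path(data_dir, "ct_markers.csv"))
magg <- aggregate_technical_replicates(mk)
mem <- ct_to_expression_matrix(magg)
mpanel <- stable_order(genorm_rank(mem))[1:4]
young <- paste0("young_", 1:4)
lp <- paste0("late_passage_", 1:4)
markers <- c("IL6_like", "IGFBP7_like", "UBC_like")

res <- rbind(
  cbind(nf = "new",
        marker_test_batch(delta_ct(magg, mpanel), markers, young, lp)),
  cbind(nf = "classic",
        marker_test_batch(delta_ct(magg, classics), markers, young, lp)))
utils::write.table(res, file.path(out, "marker_tests.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
cat("\nmarker tests, late passage vs young (negative estimate = upregulated):\n")
print(res, digits = 3)
for (g in markers) {
  nsig <- res$significant[res$nf == "new" & res$gene == g]
  csig <- res$significant[res$nf == "classic" & res$gene == g]
  cat(sprintf("%s: %s under the new NF, %s under the classical NF\n", g,
              if (nsig) "significant" else "not significant",
              if (csig) "significant" else "not significant"))
}
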