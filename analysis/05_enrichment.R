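#!/usr/bin/env Rscript
# Step 5 — what are the most stable genes? Over-representation analysis
# of the most stable decile of the screened transcriptome against gene
# sets (here: the planted ribosomal-like set and random controls,
# standing in for GO/KEGG collections supplied as GMT).

suppressMessages(library(refpanel))

data_dir <- "results/data"
out <- "results"
em <- read_expression_matrix(file.path(data_dir, "expression_matrix.csv"),
                             sample_sheet = file.path(data_dir, "sample_sheet.csv"))
truth <- jsonlite::read_json(file.path(data_dir, "truth.json"),
                             simplifyVector = TRUE)
ranked <- read.delim("results/stability_ranking.tsv")

# gene sets as a GMT round-trip, the interchange format for collections
gmt <- file.path(out, "gene_sets_synthetic.gmt")
writeLines(c(
  paste(c("RIBOSOMAL_LIKE", "planted stable set",
          truth$expression$stable_set), collapse = "\t"),
  paste(c("RANDOM_A", "random control", sprintf("GENE%04d", 1:40)),
        collapse = "\t"),
  paste(c("RANDOM_B", "random control", sprintf("GENE%04d", 301:340)),
        collapse = "\t")), gmt)
sets <- read_gmt(gmt)

# rebuild the ranking object interface from the serialized TSV
rk <- structure(list(order = rev(ranked$gene),
                     m_at_exclusion = stats::setNames(
                       rev(ranked$m_at_exclusion), rev(ranked$gene))),
                class = "stability_ranking")

res <- enrich_top_stable(rk, top_k = 50, sets = sets)
utils::write.table(res, file.path(out, "enrichment.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
print(res, digits = 3)
cat(sprintf("top hit: %s (%d/%d of the set in the top 50; BH p = %.2g)\n",
            res$set[1], res$k[1], res$K[1], res$adjusted_p[1]))
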