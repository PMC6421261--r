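#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study data for all downstream steps:
#   (a) a transcriptome arm: 500-gene log2 expression matrix over
#       control, quiescent and three senescence conditions (3 biological
#       replicates each), with 20 planted ribosomal-like stable genes;
#   (b) a qPCR validation arm: 28 candidate genes, Ct values with 3
#       technical replicates over control/quiescent/senescent;
#   (c) a matched marker arm: young vs late-passage, 4 clones each.
# Writes the matrices, sample sheets, Ct tables and ground truth under
# results/data/, plus the resolved configuration.

suppressMessages(library(refpanel))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr_cfg <- sim_config(seed = seed)
expr <- simulate_expression(expr_cfg)
write_expression_matrix(expr$matrix, file.path(out, "expression_matrix.csv"),
                        sample_sheet = file.path(out, "sample_sheet.csv"))

ct_cfg <- sim_config_ct(seed = seed + 1L)
ct <- simulate_ct(ct_cfg)
write_ct_table(ct$ct, file.path(out, "ct_validation.csv"))

mk_cfg <- sim_config_markers(seed = seed + 2L)
mk <- simulate_ct(mk_cfg)
write_ct_table(mk$ct, file.path(out, "ct_markers.csv"))

truth <- list(expression = expr$truth[c("stable_set", "seed")],
              ct_validation = ct$truth[c("stable_set", "seed")],
              markers = mk$truth[c("stable_set", "seed")])
jsonlite::write_json(truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA)
jsonlite::write_json(list(seed = seed,
                          package_version = as.character(
                            utils::packageVersion("refpanel")),
                          conditions = as.list(expr_cfg$conditions),
                          lod = expr_cfg$lod,
                          n_tech_reps = ct_cfg$n_tech_reps),
                     file.path(out, "run_config.json"),
                     auto_unbox = TRUE, digits = NA)

cat("simulated", length(gene_ids(expr$matrix)), "genes x",
    length(sample_ids(expr$matrix)), "samples (expression arm);",
    nrow(ct$ct$records), "Ct records (validation arm);",
    nrow(mk$ct$records), "Ct records (marker arm)\n")
cat("planted stable genes:", length(expr$truth$stable_set),
    "(expression) /", length(ct$truth$stable_set), "(validation)\n")
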