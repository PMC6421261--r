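test_that("top-n abundance filter keeps exactly the highest-mean genes", {
  em <- random_em(5, 4, seed = 51)
  expect_identical(gene_ids(filter_top_n_by_mean(em, 5)), gene_ids(em))
  expect_error(filter_top_n_by_mean(em, 0), "between 1")
  expect_error(filter_top_n_by_mean(em, 6), "between 1")

  forced <- matrix(rep(c(10, 9, 8, 7, 6), each = 4), 5, 4, byrow = TRUE,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  fem <- expression_matrix(forced, setNames(rep("c", 4), paste0("s", 1:4)))
  expect_identical(gene_ids(filter_top_n_by_mean(fem, 2)), c("g1", "g2"))

  # sort oracle: min kept mean >= max dropped mean
  em2 <- random_em(40, 6, seed = 52)
  kept <- filter_top_n_by_mean(em2, 15)
  dropped <- setdiff(gene_ids(em2), gene_ids(kept))
  expect_gte(min(rowMeans(kept$values)),
             max(rowMeans(em2$values[dropped, ])))
})

test_that("minimum-expression floor drops any gene dipping below it", {
  em <- random_em(10, 5, seed = 53)
  expect_identical(
    gene_ids(suppressMessages(filter_by_min_expression(em, -Inf))),
    gene_ids(em))
  em$values["g03", 2] <- 0
  kept <- suppressMessages(filter_by_min_expression(em, 5))
  expect_false("g03" %in% gene_ids(kept))
  # brute-force row scan oracle
  expect_identical(gene_ids(kept),
                   gene_ids(em)[apply(em$values, 1, min) >= 5])
})

test_that("filters are idempotent", {
  em <- random_em(20, 5, seed = 54)
  once <- filter_top_n_by_mean(em, 8)
  expect_identical(filter_top_n_by_mean(once, 8)$values, once$values)
  fl <- suppressMessages(filter_by_min_expression(em, 9.5))
  expect_identical(suppressMessages(filter_by_min_expression(fl, 9.5))$values,
                   fl$values)
})

test_that("MA statistics give per-gene abundance and log2 fold change", {
  em <- random_em(6, 6, seed = 55)  # conditions alternate A, B
  same <- ma_statistics(em, "A", "A")
  expect_equal(same$M_fc, rep(0, 6))

  em2 <- em
  b_samples <- sample_ids(em2)[em2$condition_of == "B"]
  em2$values[, b_samples] <- em2$values[, b_samples] + 1
  expect_equal(ma_statistics(em2, "A", "B")$M_fc,
               ma_statistics(em, "A", "B")$M_fc + 1)

  # two-pass mean oracle
  ma <- ma_statistics(em, "A", "B")
  a_s <- sample_ids(em)[em$condition_of == "A"]
  for (i in seq_along(gene_ids(em))) {
    g <- gene_ids(em)[i]
    expect_equal(ma$M_fc[i],
                 mean(em$values[g, b_samples]) - mean(em$values[g, a_s]),
                 tolerance = 1e-12)
    expect_equal(ma$A[i], mean(em$values[g, ]), tolerance = 1e-12)
  }
  expect_error(ma_statistics(em, "A", "nope"), "unknown condition")
})

test_that("stability-expression trend recovers forced and null correlations", {
  # M strictly decreasing in mean expression -> rho = -1
  pg <- data.frame(gene = paste0("g", 1:10),
                   mean_expr = 1:10,
                   fold_change = 0,
                   stability = seq(2, 0.2, length.out = 10))
  rep1 <- structure(list(per_gene = pg, filter_config = list()),
                    class = "screen_report")
  tr <- stability_expression_trend(rep1)
  expect_equal(tr$rho, -1)

  # independent M and expression: |rho| small at n = 500
  set.seed(56)
  hits <- vapply(1:20, function(i) {
    pg2 <- data.frame(gene = seq_len(500), mean_expr = rnorm(500),
                      fold_change = 0, stability = rexp(500))
    r <- stability_expression_trend(
      structure(list(per_gene = pg2), class = "screen_report"))$rho
    abs(r) < 0.2
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  # constant stability -> undefined flag
  pg$stability <- 1
  expect_true(stability_expression_trend(
    structure(list(per_gene = pg), class = "screen_report"))$undefined)
})

test_that("screen report combines abundance, fold change and stability", {
  sim <- simulate_expression(sim_config(n_genes = 60, n_stable = 10,
                                        seed = 57))
  em <- sim$matrix
  rk <- genorm_rank(em)
  rep <- screen_report(em, rk, group_a = "control",
                       group_b = c("etoposide", "xray", "replicative"),
                       filter_config = list(top_n = 60))
  expect_identical(nrow(rep$per_gene), 60L)
  expect_equal(unname(rep$per_gene$stability),
               unname(rk$m_at_exclusion[rep$per_gene$gene]))
  # planted high-abundance low-noise genes drive a negative trend
  tr <- stability_expression_trend(rep)
  expect_lt(tr$rho, 0)

  path <- withr::local_tempfile(fileext = ".tsv")
  jp <- withr::local_tempfile(fileext = ".json")
  write_screen_report(rep, path, json_path = jp)
  expect_identical(read.delim(path)$gene, rep$per_gene$gene)
  expect_equal(jsonlite::read_json(jp)$top_n, 60)
})

test_that("planted stable genes land in the most-stable decile after the screen", {
  sim <- simulate_expression(sim_config(seed = 58))
  kept <- filter_top_n_by_mean(sim$matrix, 400)
  rk <- genorm_rank(kept)
  pos <- match(sim$truth$stable_set, stable_order(rk))
  expect_lte(median(pos), length(gene_ids(kept)) / 10)
})
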