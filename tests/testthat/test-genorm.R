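test_that("pairwise variation is the SD of log2 ratios", {
  expect_equal(pairwise_variation(c(1, 2, 3), c(0, 1, 2)), 0)
  expect_equal(pairwise_variation(c(0, 2), c(0, 0)), sqrt(2))
  x <- rnorm(10)
  expect_equal(pairwise_variation(x, x), 0)
  expect_error(pairwise_variation(1, 1), ">= 2")
  expect_error(pairwise_variation(1:3, 1:2), "equal length")
})

test_that("stability measure matches the brute-force double loop", {
  em <- random_em(5, 6, seed = 7)
  expect_equal(stability_measure(em), naive_m(em$values), tolerance = 1e-10)
})

test_that("stability measure handles shift-duplicates and constant genes", {
  # g3 is g1 shifted by a constant: V_13 = 0, so M_1 = V_12/2 = M_3
  s <- rnorm(4)
  x <- rbind(g1 = s, g2 = s + rnorm(4), g3 = s + 0.5)
  colnames(x) <- paste0("s", 1:4)
  M <- stability_measure(x)
  expect_equal(M[["g1"]], M[["g3"]])
  expect_equal(M[["g1"]], naive_v(x["g1", ], x["g2", ]) / 2)

  const <- matrix(5, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(unname(stability_measure(const)), rep(0, 4))

  expect_error(stability_measure(x[1:2, ]), ">= 3 genes")
})

test_that("ranking excludes a planted outlier first and keeps the stable pair", {
  set.seed(5)
  s <- rnorm(6, 10)
  x <- rbind(g1 = s, g2 = s + 1, g3 = s + rnorm(6, sd = 3))
  colnames(x) <- paste0("s", 1:6)
  rk <- genorm_rank(x)
  expect_identical(rk$order[1], "g3")
  expect_setequal(rk$final_pair, c("g1", "g2"))
  # the terminal pair shares the M of the terminal computation = their V
  expect_equal(unname(rk$m_at_exclusion[c("g1", "g2")]), c(0, 0))
})

test_that("ranking needs more genes than min_remaining", {
  x <- matrix(rnorm(4), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(genorm_rank(x), "at least")
})

test_that("ranking is invariant to sample order and per-gene/per-sample shifts", {
  em <- random_em(8, 6, seed = 11)
  rk <- genorm_rank(em)
  perm <- em$values[, c(3, 1, 6, 2, 5, 4)]
  expect_identical(genorm_rank(perm)$order, rk$order)
  # per-gene constant shifts leave every V, M and the ranking unchanged
  shifted <- em$values + rnorm(nrow(em$values))
  rks <- genorm_rank(shifted)
  expect_identical(rks$order, rk$order)
  expect_equal(rks$m_at_exclusion, rk$m_at_exclusion, tolerance = 1e-9)
  # a global shift of one sample is absorbed the same way
  glob <- em$values
  glob[, 2] <- glob[, 2] + 3
  expect_equal(genorm_rank(glob)$m_at_exclusion, rk$m_at_exclusion,
               tolerance = 1e-9)
})

test_that("incremental M updates agree with full recomputation at every step", {
  for (seed in 1:5) {
    em <- random_em(20, 8, seed = 100 + seed)
    rk <- genorm_rank(em)
    nv <- naive_genorm_rank(em$values)
    expect_identical(rk$order, nv$order)
    expect_equal(rk$m_at_exclusion, nv$m_at_exclusion, tolerance = 1e-9)
    expect_equal(rk$mean_m_trajectory, nv$mean_m_trajectory, tolerance = 1e-9)
  }
})

test_that("whole-pipeline ranking equals the naive reference on small inputs", {
  set.seed(301)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    s <- sample(3:8, 1)
    em <- random_em(n, s)
    rk <- genorm_rank(em)
    nv <- naive_genorm_rank(em$values)
    expect_identical(rk$order, nv$order)
    expect_equal(rk$m_at_exclusion, nv$m_at_exclusion, tolerance = 1e-9)
  }
})

test_that("chunked two-pass path gives the same result as the full matrix", {
  em <- random_em(30, 6, seed = 21)
  full <- genorm_rank(em)
  chunked <- genorm_rank(em, memory_budget = 1024)  # forces chunking
  expect_identical(chunked$order, full$order)
  expect_equal(chunked$m_at_exclusion, full$m_at_exclusion, tolerance = 1e-12)
})

test_that("ties on max M break lexicographically and are reported", {
  delta <- c(0, 0.5, 0, 0.5)
  x <- rbind(b = rep(5, 4), a = 5 + delta, c = 5 - delta, d = rep(6, 4))
  colnames(x) <- paste0("s", 1:4)
  # a and c are mirror images around the constant genes: identical M
  expect_message(rk <- genorm_rank(x), "lexicographic")
  expect_identical(rk$order[1], "a")
})

test_that("stability-threshold counts are monotone and match the ranking", {
  em <- random_em(12, 6, seed = 31)
  rk <- genorm_rank(em)
  counts <- count_below_stability(rk, c(0, 0.5, 1, Inf))
  expect_identical(unname(counts[["Inf"]]), 12L)
  expect_identical(unname(counts[["0"]]), 0L)
  expect_true(all(diff(counts) >= 0))

  # planted proportional genes: zero noise, so their M is exactly 0
  s <- rnorm(6, 10)
  planted <- t(vapply(1:10, function(i) s + i * 0.1, numeric(6)))
  noisy <- matrix(rnorm(40 * 6, 10, 1), 40, 6)
  x <- rbind(planted, noisy)
  dimnames(x) <- list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6))
  rk2 <- suppressMessages(genorm_rank(x))  # exact-zero M ties are expected
  expect_gte(unname(count_below_stability(rk2, 0.05)[[1]]), 10L)
})

test_that("ranking serializes to TSV with rank 1 as the most stable gene", {
  em <- random_em(6, 5, seed = 41)
  rk <- genorm_rank(em)
  path <- withr::local_tempfile(fileext = ".tsv")
  jp <- withr::local_tempfile(fileext = ".json")
  write_ranking(rk, path, json_path = jp)
  df <- read.delim(path)
  expect_identical(df$gene, stable_order(rk))
  expect_identical(df$rank, seq_len(6))
  js <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(js$mean_m_trajectory, unname(rk$mean_m_trajectory))
})
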