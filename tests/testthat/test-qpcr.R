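test_that("technical replicates aggregate with LOD policies", {
  tbl <- ct_fixture(list(clean = c(20.0, 20.2, 20.4),
                         partial = c(34, 36, 36),
                         gone = c(36, 36, 36)))
  agg <- suppressMessages(aggregate_technical_replicates(tbl))
  pp <- agg$per_pair
  expect_equal(pp$mean_ct[pp$gene == "clean"], 20.2)
  expect_identical(pp$n_reps[pp$gene == "clean"], 3L)

  expect_equal(pp$mean_ct[pp$gene == "partial"], 34)
  expect_identical(pp$n_reps[pp$gene == "partial"], 1L)
  expect_true(pp$censored_flag[pp$gene == "partial"])

  expect_true(pp$undetected[pp$gene == "gone"])
  expect_true(is.na(pp$mean_ct[pp$gene == "gone"]))

  clamped <- aggregate_technical_replicates(tbl, policy = "clamp")
  cp <- clamped$per_pair
  expect_equal(cp$mean_ct[cp$gene == "partial"], mean(c(34, 35, 35)))
  expect_equal(cp$mean_ct[cp$gene == "gone"], 35)
  expect_false(any(cp$undetected))
})

test_that("Ct converts to log2 quantity as -Ct * log2(E)", {
  tbl <- ct_fixture(list(g = c(20, 20, 20)))
  agg <- aggregate_technical_replicates(tbl)
  em2 <- ct_to_expression_matrix(agg, efficiency = 2)
  expect_equal(unname(em2$values["g", "s1"]), -20)
  expect_identical(em2$scale_tag, "ct")

  em19 <- ct_to_expression_matrix(agg, efficiency = 1.9)
  expect_equal(unname(em19$values["g", "s1"]), -20 * log2(1.9))

  # lower Ct means more template, for any efficiency above 1
  tbl2 <- ct_fixture(list(lo = c(18, 18, 18), hi = c(25, 25, 25)))
  for (E in c(1.8, 2)) {
    v <- ct_to_expression_matrix(aggregate_technical_replicates(tbl2),
                                 efficiency = E)$values
    expect_gt(v["lo", "s1"], v["hi", "s1"])
  }
  expect_error(ct_to_expression_matrix(agg, efficiency = 1), "> 1")
})

test_that("undetected entries are dropped from or block the conversion", {
  tbl <- ct_fixture(list(ok = c(20, 21, 20), gone = c(36, 36, 36)))
  agg <- suppressMessages(aggregate_technical_replicates(tbl))
  expect_message(em2 <- ct_to_expression_matrix(agg), "gone")
  expect_identical(gene_ids(em2), "ok")
  expect_error(ct_to_expression_matrix(agg, drop_undetected = FALSE),
               "gone")
})

test_that("delta-Ct subtracts the panel-mean reference Ct", {
  tbl <- ct_fixture(list(target = c(25, 25, 25), r1 = c(20, 20, 20),
                         r2 = c(22, 22, 22)))
  agg <- aggregate_technical_replicates(tbl)
  d <- delta_ct(agg, c("r1", "r2"))
  expect_equal(d$dct[d$gene == "target"], 4)
  # a single-gene panel of the target itself gives dCt = 0
  d0 <- delta_ct(agg, "target")
  expect_equal(d0$dct[d0$gene == "target"], 0)
  expect_error(delta_ct(agg, "absent"), "absent")
})

test_that("delta-Ct agrees with the log2-quantity normalization route", {
  sim <- simulate_ct(sim_config_ct(seed = 71))
  agg <- aggregate_technical_replicates(sim$ct)
  panel <- c("RIBO001", "RIBO002", "RIBO003")
  d <- delta_ct(agg, panel)
  em2 <- ct_to_expression_matrix(agg, efficiency = 2)
  nf <- normalization_factor(em2, panel)
  via_log2 <- -(em2$values[cbind(d$gene, d$sample)] - nf$nf_log2[d$sample])
  expect_equal(d$dct, unname(via_log2), tolerance = 1e-9)
})

test_that("a global per-sample Ct shift leaves dCt unchanged", {
  sim <- simulate_ct(sim_config_ct(seed = 72))
  agg <- aggregate_technical_replicates(sim$ct)
  d <- delta_ct(agg, c("RIBO001", "RIBO002"))
  shifted <- sim$ct
  s1 <- shifted$records$sample == shifted$records$sample[1]
  shifted$records$ct[s1] <- shifted$records$ct[s1] + 2.5
  d2 <- delta_ct(aggregate_technical_replicates(shifted),
                 c("RIBO001", "RIBO002"))
  expect_equal(d2$dct, d$dct, tolerance = 1e-9)
})

test_that("marker test handles matched designs and degenerate inputs", {
  mk <- function(a_vals, b_vals) {
    data.frame(gene = "g",
               sample = c(paste0("a", seq_along(a_vals)),
                          paste0("b", seq_along(b_vals))),
               dct = c(a_vals, b_vals))
  }
  ga <- paste0("a", 1:4); gb <- paste0("b", 1:4)

  r0 <- rc <- NULL
  expect_warning(
    r0 <- marker_test(mk(c(1, 2, 3, 4), c(1, 2, 3, 4)), "g", ga, gb),
    "identically zero")
  expect_equal(r0$p_value, 1)
  expect_false(r0$significant)

  expect_warning(
    rc <- marker_test(mk(c(1, 2, 3, 4), c(2, 3, 4, 5)), "g", ga, gb),
    "floor")
  expect_true(rc$significant)
  expect_true(rc$degenerate)

  set.seed(73)
  d <- mk(rnorm(4), rnorm(4) + 1)
  fwd <- marker_test(d, "g", ga, gb)
  rev <- marker_test(d, "g", gb, ga)
  expect_equal(rev$difference, -fwd$difference)
  expect_equal(rev$p_value, fwd$p_value)

  welch <- marker_test(d, "g", ga, gb, paired = FALSE)
  expect_match(welch$method, "Welch")
  expect_error(marker_test(mk(1, 1:2), "g", "a1", paste0("b", 1:2)),
               ">= 2")
})

test_that("batch marker testing applies BH across genes", {
  sim <- simulate_ct(sim_config_markers(seed = 74))
  agg <- aggregate_technical_replicates(sim$ct)
  d <- delta_ct(agg, c("RIBO001", "RIBO002", "RIBO003", "RIBO004"))
  res <- marker_test_batch(d, c("IL6_like", "IGFBP7_like", "GENE0001"),
                           paste0("young_", 1:4),
                           paste0("late_passage_", 1:4))
  expect_true(all(res$adjusted_p >= res$p))
  ord <- order(res$p)
  expect_true(all(diff(res$adjusted_p[ord]) >= -1e-15))
  expect_equal(res$adjusted_p,
               p.adjust(res$p, method = "BH"))
})
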