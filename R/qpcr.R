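#' Aggregate technical replicates of a Ct table
#'
#' Collapses the (typically three) technical replicates of each
#' (gene, sample) pair to a mean Ct, with the replicate SD as a QC
#' column. Replicates beyond the limit of detection are handled per
#' `policy`: `"exclude"` drops them from the mean (the default — hard-to-
#' detect readings are discarded rather than imputed), `"clamp"` sets
#' them to the LOD. A pair whose replicates are all censored under
#' `"exclude"` is marked undetected.
#'
#' @param tbl a `ct_table`.
#' @param policy `"exclude"` or `"clamp"`.
#' @return An object of class `aggregated_ct`: list with `per_pair`
#'   (data.frame gene, sample, condition, mean_ct, replicate_sd, n_reps,
#'   censored_flag, undetected), `lod`, `policy`.
#' @export
aggregate_technical_replicates <- function(tbl, policy = c("exclude", "clamp")) {
  policy <- match.arg(policy)
  r <- tbl$records
  if (nrow(r) == 0) stop("empty Ct table")
  key <- interaction(r$gene, r$sample, drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(seq_len(nrow(r)), key), function(idx) {
    ct <- r$ct[idx]
    cens <- r$censored[idx]
    if (policy == "clamp") ct[cens] <- tbl$lod
    use <- if (policy == "exclude") !cens else rep(TRUE, length(ct))
    data.frame(gene = r$gene[idx[1]], sample = r$sample[idx[1]],
               condition = r$condition[idx[1]],
               mean_ct = if (any(use)) mean(ct[use]) else NA_real_,
               replicate_sd = if (sum(use) > 1) stats::sd(ct[use]) else NA_real_,
               n_reps = sum(use),
               censored_flag = any(cens),
               undetected = !any(use),
               stringsAsFactors = FALSE)
  })
  per_pair <- do.call(rbind, rows)
  rownames(per_pair) <- NULL
  if (any(per_pair$undetected))
    message(sum(per_pair$undetected),
            " (gene, sample) pair(s) undetected (all replicates beyond LOD ",
            tbl$lod, " under policy '", policy, "')")
  structure(list(per_pair = per_pair, lod = tbl$lod, policy = policy),
            class = "aggregated_ct")
}

#' @export
print.aggregated_ct <- function(x, ...) {
  cat(sprintf("<aggregated_ct> %d (gene, sample) pairs, policy '%s', %d undetected\n",
              nrow(x$per_pair), x$policy, sum(x$per_pair$undetected)))
  invisible(x)
}

#' Convert aggregated Ct values to a log2-quantity expression matrix
#'
#' Under amplification efficiency E, one cycle corresponds to a factor E
#' of template, so the log2 relative quantity of a well with cycle value
#' Ct is -Ct * log2(E); E = 2 (perfect doubling) gives -Ct. The resulting
#' matrix is tagged `scale_tag = "ct"` and feeds the same stability
#' ranking and normalization-factor machinery as microarray data.
#'
#' @param a an `aggregated_ct`.
#' @param efficiency amplification efficiency E > 1 (default 2).
#' @param genes optional subset of genes to convert (default: all).
#' @param drop_undetected drop genes with any undetected (gene, sample)
#'   pair (with a message) instead of erroring. This is the default
#'   screening behaviour: genes that cannot be measured in every sample
#'   are removed from the ranking rather than imputed.
#' @return an `expression_matrix`.
#' @export
ct_to_expression_matrix <- function(a, efficiency = 2.0, genes = NULL,
                                    drop_undetected = TRUE) {
  if (efficiency <= 1) stop("efficiency must be > 1")
  pp <- a$per_pair
  if (!is.null(genes)) {
    miss <- setdiff(genes, unique(pp$gene))
    if (length(miss)) stop("gene(s) not in Ct data: ", paste(miss, collapse = ", "))
    pp <- pp[pp$gene %in% genes, , drop = FALSE]
  }
  bad <- pp[pp$undetected, , drop = FALSE]
  if (nrow(bad)) {
    if (!drop_undetected)
      stop("undetected (gene, sample) pairs: ",
           paste(sprintf("%s/%s", bad$gene, bad$sample), collapse = ", "))
    drop_genes <- unique(bad$gene)
    message("dropping ", length(drop_genes),
            " gene(s) with undetected samples: ",
            paste(drop_genes, collapse = ", "))
    pp <- pp[!pp$gene %in% drop_genes, , drop = FALSE]
    if (!nrow(pp)) stop("no detectable genes remain")
  }
  g <- sort(unique(pp$gene))
  s <- sort(unique(pp$sample))
  m <- matrix(NA_real_, length(g), length(s), dimnames = list(g, s))
  m[cbind(pp$gene, pp$sample)] <- -pp$mean_ct * log2(efficiency)
  if (any(is.na(m))) stop("Ct data is not complete over genes x samples")
  cond <- pp$condition[match(s, pp$sample)]
  expression_matrix(m, stats::setNames(cond, s), scale_tag = "ct")
}

#' Delta-Ct normalization against a reference-panel normalization factor
#'
#' dCt(gene, sample) = mean Ct of the gene minus the reference Ct of the
#' sample, where the reference Ct is the arithmetic mean of the panel
#' genes' mean Ct in that sample — equivalent, at efficiency 2, to
#' dividing the gene's linear quantity by the geometric mean of the
#' panel quantities. Lower dCt means higher expression.
#'
#' @param a an `aggregated_ct`.
#' @param panel character vector of reference gene ids present in `a`
#'   (alternatively a `normalization_factor` with `source_scale = "ct"`,
#'   whose panel is used).
#' @return data.frame with columns gene, sample, condition, dct.
#' @export
delta_ct <- function(a, panel) {
  if (inherits(panel, "normalization_factor")) {
    if (panel$source_scale != "ct")
      stop("normalization factor was not built on the Ct scale")
    panel <- panel$panel
  }
  pp <- a$per_pair
  miss <- setdiff(panel, unique(pp$gene))
  if (length(miss)) stop("panel gene(s) not in Ct data: ",
                         paste(miss, collapse = ", "))
  ref <- pp[pp$gene %in% panel, , drop = FALSE]
  if (any(ref$undetected))
    stop("panel gene undetected in sample(s): ",
         paste(unique(ref$sample[ref$undetected]), collapse = ", "))
  ref_ct <- tapply(ref$mean_ct, ref$sample, mean)
  no_ref <- setdiff(unique(pp$sample), names(ref_ct))
  if (length(no_ref)) stop("sample(s) missing from the reference panel: ",
                           paste(no_ref, collapse = ", "))
  out <- pp[!pp$undetected, c("gene", "sample", "condition", "mean_ct")]
  out$dct <- out$mean_ct - as.numeric(ref_ct[out$sample])
  rownames(out) <- NULL
  out[c("gene", "sample", "condition", "dct")]
}

#' Two-group marker test on dCt values
#'
#' Compares the dCt of one gene between two sample groups with a
#' two-sided t test — paired when the samples are matched one-to-one by
#' biological replicate (pairing follows the order of `group_a` /
#' `group_b`), Welch otherwise. Reports per-group means with t-based 95%
#' confidence half-widths and the group difference (group_b - group_a on
#' the dCt scale; remember lower dCt = higher expression).
#'
#' Degenerate zero-variance cases are handled by convention rather than
#' error: identical paired differences of exactly zero give p = 1; equal
#' nonzero differences give a p reported at the smallest positive
#' double, with a warning either way.
#'
#' @param d data.frame from [delta_ct()], or any data.frame with columns
#'   `gene`, `sample`, `dct`.
#' @param gene gene to test.
#' @param group_a,group_b character vectors of sample ids.
#' @param paired logical; default TRUE (matched designs).
#' @param alpha significance level (default 0.05).
#' @param level confidence level for the group CIs (default 0.95).
#' @return An object of class `marker_test_result`: list with `gene`,
#'   `groups`, per-group `mean_dct` and `ci_half_width`, `difference`
#'   (b - a), `conf_int`, `p_value`, `significant`, `method`,
#'   `degenerate`.
#' @export
marker_test <- function(d, gene, group_a, group_b, paired = TRUE,
                        alpha = 0.05, level = 0.95) {
  dg <- d[d$gene == gene, , drop = FALSE]
  if (!nrow(dg)) stop("gene not found in dCt table: ", gene)
  pick <- function(samples) {
    i <- match(samples, dg$sample)
    if (any(is.na(i))) stop("sample(s) missing for ", gene, ": ",
                            paste(samples[is.na(i)], collapse = ", "))
    dg$dct[i]
  }
  a <- pick(group_a)
  b <- pick(group_b)
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 samples")
  if (paired && length(a) != length(b))
    stop("paired test requires matched groups of equal size")

  group_ci <- function(v) {
    if (length(v) < 2) return(NA_real_)
    stats::qt(1 - (1 - level) / 2, df = length(v) - 1) *
      stats::sd(v) / sqrt(length(v))
  }

  degenerate <- FALSE
  if (paired) {
    diffs <- b - a
    if (stats::sd(diffs) == 0) {
      degenerate <- TRUE
      if (all(diffs == 0)) {
        warning("paired differences identically zero; p = 1 by convention")
        p <- 1
        ci <- c(0, 0)
      } else {
        warning("zero-variance nonzero paired differences; ",
                "p reported at the double floor")
        p <- .Machine$double.xmin
        ci <- rep(mean(diffs), 2)
      }
      est <- mean(diffs)
      method <- "paired t (degenerate)"
    } else {
      tt <- stats::t.test(b, a, paired = TRUE, conf.level = level)
      p <- tt$p.value
      est <- unname(tt$estimate)
      ci <- as.numeric(tt$conf.int)
      method <- "paired t"
    }
  } else {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      degenerate <- TRUE
      if (mean(a) == mean(b)) {
        warning("zero variance, identical means; p = 1 by convention")
        p <- 1
      } else {
        warning("zero variance, different means; p at the double floor")
        p <- .Machine$double.xmin
      }
      est <- mean(b) - mean(a)
      ci <- rep(est, 2)
      method <- "Welch t (degenerate)"
    } else {
      tt <- stats::t.test(b, a, paired = FALSE, conf.level = level)
      p <- tt$p.value
      est <- unname(diff(rev(tt$estimate)))
      ci <- as.numeric(tt$conf.int)
      method <- "Welch t"
    }
  }

  structure(list(gene = gene,
                 groups = list(a = group_a, b = group_b),
                 mean_dct = c(a = mean(a), b = mean(b)),
                 ci_half_width = c(a = group_ci(a), b = group_ci(b)),
                 difference = est,
                 conf_int = ci,
                 p_value = p,
                 significant = p < alpha,
                 alpha = alpha,
                 method = method,
                 degenerate = degenerate),
            class = "marker_test_result")
}

#' @export
print.marker_test_result <- function(x, ...) {
  cat(sprintf("<marker_test> %s: dCt difference %.3f (b - a; lower dCt = higher expression)\n",
              x$gene, x$difference))
  cat(sprintf("  %s: p = %.3g [%s at alpha %g]\n", x$method, x$p_value,
              if (x$significant) "significant" else "not significant", x$alpha))
  invisible(x)
}

#' Batch marker tests with Benjamini-Hochberg correction
#'
#' Runs [marker_test()] for each gene and adjusts the p-values across
#' the batch (BH). Correction is deliberately a separate, explicit step
#' rather than hidden inside the single-gene test.
#'
#' @param d dCt data.frame.
#' @param genes genes to test.
#' @inheritParams marker_test
#' @return data.frame with columns gene, estimate, ci_low, ci_high, p,
#'   adjusted_p, significant (on adjusted p).
#' @export
marker_test_batch <- function(d, genes, group_a, group_b, paired = TRUE,
                              alpha = 0.05) {
  res <- lapply(genes, function(g)
    marker_test(d, g, group_a, group_b, paired = paired, alpha = alpha))
  out <- data.frame(gene = genes,
                    estimate = vapply(res, function(r) r$difference, 1),
                    ci_low = vapply(res, function(r) r$conf_int[1], 1),
                    ci_high = vapply(res, function(r) r$conf_int[2], 1),
                    p = vapply(res, function(r) r$p_value, 1))
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$adjusted_p < alpha
  out
}
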