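#' Pearson correlation with a Fisher-z confidence interval
#'
#' Wraps the standard Pearson test (as `stats::cor.test` computes it:
#' r with CI tanh(atanh(r) +/- z_crit / sqrt(n - 3))) and classifies the
#' result by whether the CI spans zero. A CI containing zero is reported
#' as absence of evidence for a correlation, not as evidence of
#' independence.
#'
#' @param x,y numeric vectors, equal length n >= 4.
#' @param level confidence level (default 0.95).
#' @param label optional pair label carried into the result.
#' @return An object of class `nf_comparison`: list with `label`, `r`,
#'   `ci`, `n`, `contains_zero`, `degenerate` (TRUE when |r| = 1 and the
#'   CI collapses to the point r), `undefined_r` (TRUE when either input
#'   has zero variance).
#' @export
pearson_ci <- function(x, y, level = 0.95, label = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n <= 3) stop("Pearson CI requires n > 3 samples (got ", n, ")")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(label = label, r = NA_real_,
                          ci = c(NA_real_, NA_real_), n = n,
                          contains_zero = NA, degenerate = FALSE,
                          undefined_r = TRUE),
                     class = "nf_comparison"))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-12) {
    # atanh singularity: report the CI as the point {r}, flagged
    ci <- c(r, r)
    degenerate <- TRUE
  } else {
    ct <- stats::cor.test(x, y, conf.level = level)
    ci <- as.numeric(ct$conf.int)
    degenerate <- FALSE
  }
  structure(list(label = label, r = r, ci = ci, n = n,
                 contains_zero = ci[1] <= 0 && 0 <= ci[2],
                 degenerate = degenerate, undefined_r = FALSE),
            class = "nf_comparison")
}

#' @export
print.nf_comparison <- function(x, ...) {
  if (isTRUE(x$undefined_r)) {
    cat(sprintf("<nf_comparison> %s: r undefined (zero variance)\n",
                x$label %||% ""))
    return(invisible(x))
  }
  cat(sprintf("<nf_comparison> %s: r = %.3f, CI [%.3f, %.3f], n = %d\n",
              x$label %||% "", x$r, x$ci[1], x$ci[2], x$n))
  if (isTRUE(x$contains_zero))
    cat("  CI includes zero: not enough evidence of a correlation\n")
  invisible(x)
}

#' Compare a candidate normalization factor with classical ones
#'
#' Pearson correlation (with Fisher-z CI) between the candidate panel's
#' per-sample log2 normalization factor and each classical NF — single
#' classical genes are one-gene panels. Correlations are computed on the
#' nf_log2 values, the scale on which NFs are geometric means.
#'
#' @param nf_new a `normalization_factor`.
#' @param classics named list of `normalization_factor`s over the same
#'   samples.
#' @param level confidence level (default 0.95).
#' @return data.frame with columns pair, r, ci_low, ci_high, n,
#'   contains_zero; attribute `"comparisons"` holds the full
#'   `nf_comparison` objects.
#' @export
compare_nfs <- function(nf_new, classics, level = 0.95) {
  if (!length(classics)) stop("no classical NFs supplied")
  if (is.null(names(classics)))
    names(classics) <- vapply(classics, function(nf)
      paste(nf$panel, collapse = "+"), "")
  samples <- names(nf_new$nf_log2)
  comps <- lapply(names(classics), function(nm) {
    nf_c <- classics[[nm]]
    if (!identical(sort(names(nf_c$nf_log2)), sort(samples)))
      stop("NF '", nm, "' is not over the same sample set")
    pearson_ci(nf_new$nf_log2[samples], nf_c$nf_log2[samples],
               level = level, label = paste0("new-vs-", nm))
  })
  out <- data.frame(pair = vapply(comps, function(cp) cp$label, ""),
                    r = vapply(comps, function(cp) cp$r, 1),
                    ci_low = vapply(comps, function(cp) cp$ci[1], 1),
                    ci_high = vapply(comps, function(cp) cp$ci[2], 1),
                    n = vapply(comps, function(cp) cp$n, 1L),
                    contains_zero = vapply(comps, function(cp)
                      isTRUE(cp$contains_zero), TRUE))
  attr(out, "comparisons") <- comps
  out
}
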