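#' Normalization factor over a gene panel
#'
#' The per-sample normalization factor is the geometric mean of the panel
#' genes' linear quantities; on the log2 scale this is the arithmetic
#' mean of the panel rows, which is how it is stored (`nf_log2`).
#'
#' @param m an `expression_matrix` (log2 scale).
#' @param panel character vector of gene ids, all present in `m`.
#' @return An object of class `normalization_factor`: list with `panel`,
#'   `nf_log2` (named per-sample vector) and `source_scale`
#'   (`"microarray_log2"` or `"ct"` depending on the matrix scale tag).
#' @export
normalization_factor <- function(m, panel) {
  if (!length(panel)) stop("panel must be non-empty")
  missing_g <- setdiff(panel, gene_ids(m))
  if (length(missing_g))
    stop("panel gene(s) absent from matrix: ", paste(missing_g, collapse = ", "))
  nf <- colMeans(m$values[panel, , drop = FALSE])
  structure(list(panel = panel,
                 nf_log2 = nf,
                 source_scale = if (m$scale_tag == "ct") "ct" else "microarray_log2"),
            class = "normalization_factor")
}

#' @export
print.normalization_factor <- function(x, ...) {
  cat(sprintf("<normalization_factor> %d-gene panel (%s), %d samples\n",
              length(x$panel), paste(x$panel, collapse = ", "),
              length(x$nf_log2)))
  invisible(x)
}

#' Pairwise variation V(n,n+1) between nested normalization factors
#'
#' Builds normalization factors from the n most stable genes for
#' n = 2..max_n (stability order from the ranking) and measures, for each
#' step, the sample standard deviation across samples of
#' nf_log2(n) - nf_log2(n+1) — the geNorm V(n,n+1) used to decide how
#' many reference genes a panel needs.
#'
#' @param ranking a `stability_ranking` over genes of `m`.
#' @param m the `expression_matrix` the ranking came from.
#' @param max_n largest panel size to evaluate, 2 <= max_n <= ranked
#'   genes (V(max_n, max_n+1) requires gene max_n+1, so max_n is capped
#'   at ranked genes - 1).
#' @param threshold V threshold for the panel-size rule (default 0.15).
#' @param epsilon minimal-improvement margin for the elbow rule (default
#'   0.01 V-units).
#' @return An object of class `panel_size_report`: list with `v_series`
#'   (named vector, entry "n" = V(n,n+1)), `n_threshold`, `n_elbow`,
#'   `n_min_variability` (the n whose step variability is smallest),
#'   `threshold`, `epsilon`, and `stable_genes` (the max_n + 1 genes
#'   used, most stable first).
#' @export
pairwise_variation_series <- function(ranking, m, max_n,
                                      threshold = 0.15, epsilon = 0.01) {
  genes <- stable_order(ranking)
  if (max_n < 2 || max_n > length(genes) - 1)
    stop("max_n must be in [2, ", length(genes) - 1, "]")
  used <- genes[seq_len(max_n + 1)]
  missing_g <- setdiff(used, gene_ids(m))
  if (length(missing_g))
    stop("ranked gene(s) absent from matrix: ", paste(missing_g, collapse = ", "))

  x <- m$values[used, , drop = FALSE]
  csum <- apply(x, 2, cumsum)               # cumulative panel sums per sample
  v <- numeric(max_n - 1)
  for (n in 2:max_n) {
    nf_n <- csum[n, ] / n
    nf_n1 <- csum[n + 1, ] / (n + 1)
    v[n - 1] <- stats::sd(nf_n - nf_n1)
  }
  names(v) <- as.character(2:max_n)

  rec <- recommend_panel_size_from_series(v, threshold, epsilon)
  structure(c(list(v_series = v, threshold = threshold, epsilon = epsilon,
                   stable_genes = used), rec),
            class = "panel_size_report")
}

#' Recommend a panel size from a V(n,n+1) series
#'
#' Two decision rules are evaluated. The threshold rule returns the
#' smallest n with V(n,n+1) < threshold (the classic 0.15 guideline);
#' `NA` with a message if no step qualifies. The elbow rule returns the
#' smallest n such that every subsequent improvement
#' V(n-1,n) - V(n,n+1) is below epsilon — the point past which adding
#' genes buys only marginal variability reduction. When the rules
#' disagree both are reported; the elbow value is the headline.
#'
#' @param report a `panel_size_report` (or pass a bare named v_series via
#'   [recommend_panel_size_from_series()]).
#' @param threshold,epsilon override the report's stored values.
#' @return list with `n_threshold`, `n_elbow`, `n_min_variability`.
#' @export
recommend_panel_size <- function(report, threshold = report$threshold,
                                 epsilon = report$epsilon) {
  recommend_panel_size_from_series(report$v_series, threshold, epsilon)
}

#' @rdname recommend_panel_size
#' @param v_series named numeric vector, entry "n" holding V(n,n+1).
#' @export
recommend_panel_size_from_series <- function(v_series, threshold = 0.15,
                                             epsilon = 0.01) {
  if (!length(v_series)) stop("empty v_series")
  ns <- if (is.null(names(v_series))) seq_along(v_series) + 1L
        else as.integer(names(v_series))
  below <- ns[v_series < threshold]
  n_threshold <- if (length(below)) min(below) else NA_integer_
  if (is.na(n_threshold))
    message("no V(n,n+1) below ", threshold,
            "; consider using all ranked genes")

  if (length(v_series) >= 2) {
    # imp[i] = V(m-1,m) - V(m,m+1) with m = ns[i] + 1: the variability
    # reduction gained by the m-gene panel over the (m-1)-gene panel
    imp <- v_series[-length(v_series)] - v_series[-1]
    big <- which(imp >= epsilon)
    n_elbow <- if (length(big)) ns[max(big)] + 2L else min(ns)
  } else n_elbow <- min(ns)

  list(n_threshold = n_threshold,
       n_elbow = n_elbow,
       n_min_variability = ns[which.min(v_series)])
}

#' @export
print.panel_size_report <- function(x, ...) {
  cat("<panel_size_report>\n")
  cat("  V(n,n+1):", paste(sprintf("%s:%.4f", names(x$v_series), x$v_series),
                           collapse = " "), "\n")
  cat(sprintf("  threshold rule (< %g): n = %s | elbow rule (eps %g): n = %d\n",
              x$threshold,
              if (is.na(x$n_threshold)) "none" else x$n_threshold,
              x$epsilon, x$n_elbow))
  cat(sprintf("  minimum step variability at n = %d\n", x$n_min_variability))
  invisible(x)
}

#' Write a panel-size report as TSV + JSON
#'
#' @param report a `panel_size_report`.
#' @param path output TSV path (columns n, v).
#' @param json_path optional JSON path for the full report.
#' @return `path`, invisibly.
#' @export
write_panel_size_report <- function(report, path, json_path = NULL) {
  utils::write.table(data.frame(n = names(report$v_series),
                                v = unname(report$v_series)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report[c("v_series", "n_threshold", "n_elbow",
                                  "n_min_variability", "threshold", "epsilon",
                                  "stable_genes")],
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
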