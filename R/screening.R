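#' Keep the n genes with the highest mean expression
#'
#' Abundance pre-filter applied before stability ranking, so that
#' candidate reference genes are reliably detectable by RT-qPCR. Ties at
#' the cut are broken lexicographically by gene id and reported.
#'
#' @param m an `expression_matrix`.
#' @param n number of genes to keep, 1 <= n <= gene count.
#' @return an `expression_matrix` with the selected genes, input order
#'   preserved.
#' @export
filter_top_n_by_mean <- function(m, n) {
  g <- gene_ids(m)
  if (n < 1 || n > length(g))
    stop("n must be between 1 and the gene count (", length(g), ")")
  mu <- rowMeans(m$values)
  ord <- order(-mu, g)
  cut_val <- mu[ord[n]]
  if (n < length(g) && mu[ord[n + 1]] == cut_val)
    message("tie at the abundance cut (mean = ", format(cut_val),
            "); broken lexicographically")
  keep <- g[sort(ord[seq_len(n)])]
  subset_matrix(m, genes = keep)
}

#' Keep genes whose minimum per-sample expression clears a floor
#'
#' Absolute-detectability filter: a gene is kept only if every sample's
#' value is at or above `floor` (log2 units). The complement of the
#' top-n filter for datasets where an absolute detection limit is known.
#'
#' @param m an `expression_matrix`.
#' @param floor log2-units threshold; `-Inf` keeps everything.
#' @return an `expression_matrix`.
#' @export
filter_by_min_expression <- function(m, floor) {
  keep <- gene_ids(m)[apply(m$values, 1, min) >= floor]
  if (!length(keep)) stop("no genes pass the expression floor ", floor)
  message(length(gene_ids(m)) - length(keep), " gene(s) below floor ",
          format(floor), " dropped")
  subset_matrix(m, genes = keep)
}

#' Per-gene MA statistics between two condition groups
#'
#' A = mean log2 expression over all samples in both groups; M_fc = mean
#' log2 fold change, group_b minus group_a. Which conditions form the two
#' groups is the caller's choice.
#'
#' @param m an `expression_matrix`.
#' @param group_a,group_b character vectors of condition labels.
#' @return data.frame with columns `gene`, `A`, `M_fc`.
#' @export
ma_statistics <- function(m, group_a, group_b) {
  known <- unique(m$condition_of)
  bad <- setdiff(c(group_a, group_b), known)
  if (length(bad)) stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  sa <- sample_ids(m)[m$condition_of %in% group_a]
  sb <- sample_ids(m)[m$condition_of %in% group_b]
  if (!length(sa) || !length(sb)) stop("both groups must contain samples")
  mean_a <- rowMeans(m$values[, sa, drop = FALSE])
  mean_b <- rowMeans(m$values[, sb, drop = FALSE])
  data.frame(gene = gene_ids(m),
             A = rowMeans(m$values[, union(sa, sb), drop = FALSE]),
             M_fc = mean_b - mean_a,
             row.names = NULL)
}

#' Build the screening report: abundance, fold change and stability per gene
#'
#' Combines the MA statistics with the stability M from a ranking over the
#' same (filtered) matrix, the substrate for the stability-vs-expression
#' diagnostics.
#'
#' @param m the filtered `expression_matrix`.
#' @param ranking a `stability_ranking` over the genes of `m`.
#' @param group_a,group_b condition groups for the fold change.
#' @param filter_config optional list recording the thresholds used.
#' @return An object of class `screen_report`: list with `per_gene`
#'   (data.frame gene, mean_expr, fold_change, stability) and
#'   `filter_config`.
#' @export
screen_report <- function(m, ranking, group_a, group_b, filter_config = list()) {
  ma <- ma_statistics(m, group_a, group_b)
  miss <- setdiff(ma$gene, names(ranking$m_at_exclusion))
  if (length(miss)) stop("ranking does not cover gene(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  per_gene <- data.frame(gene = ma$gene,
                         mean_expr = ma$A,
                         fold_change = ma$M_fc,
                         stability = unname(ranking$m_at_exclusion[ma$gene]))
  structure(list(per_gene = per_gene, filter_config = filter_config),
            class = "screen_report")
}

#' Rank-correlation trend between expression level and stability
#'
#' Tests the tendency of highly expressed genes to rank as more stable
#' (lower M). Spearman's rho is used rather than Pearson because the M
#' distribution is heavily skewed; the confidence interval uses the
#' Fisher z transform with the Fieller-Hartley-Pearson standard error
#' sqrt(1.06 / (n - 3)).
#'
#' @param report a `screen_report` with >= 4 genes.
#' @param level confidence level (default 0.95).
#' @return list with `rho`, `ci` (length-2), `n`, and `undefined` (TRUE
#'   when a constant vector makes the correlation undefined).
#' @export
stability_expression_trend <- function(report, level = 0.95) {
  pg <- report$per_gene
  if (nrow(pg) < 4) stop("need >= 4 genes for the trend")
  if (stats::sd(pg$stability) == 0 || stats::sd(pg$mean_expr) == 0)
    return(list(rho = NA_real_, ci = c(NA_real_, NA_real_), n = nrow(pg),
                undefined = TRUE))
  rho <- suppressWarnings(
    stats::cor.test(pg$mean_expr, pg$stability, method = "spearman",
                    exact = FALSE)$estimate)
  n <- nrow(pg)
  z <- atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15))
  half <- stats::qnorm(1 - (1 - level) / 2) * sqrt(1.06 / (n - 3))
  list(rho = unname(rho), ci = tanh(c(z - half, z + half)), n = n,
       undefined = FALSE)
}

#' Write a screening report as TSV plus a JSON config block
#'
#' @param report a `screen_report`.
#' @param path output TSV path.
#' @param json_path optional JSON path for the filter configuration.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path, json_path = NULL) {
  utils::write.table(report$per_gene, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report$filter_config, json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
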