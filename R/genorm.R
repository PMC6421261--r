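#' Pairwise variation between two genes
#'
#' The geNorm pairwise variation V_jk: the sample standard deviation
#' (n - 1 denominator) across samples of the log2 expression ratio of two
#' genes, i.e. of the per-sample differences of their log2 values. Two
#' perfectly proportional genes (constant log2 offset) have V = 0.
#'
#' @param x_j,x_k numeric vectors of per-sample log2 values, equal length
#'   >= 2, no missing values.
#' @return non-negative scalar.
#' @export
pairwise_variation <- function(x_j, x_k) {
  if (length(x_j) != length(x_k)) stop("x_j and x_k must have equal length")
  if (length(x_j) < 2) stop("pairwise variation needs >= 2 samples")
  if (any(!is.finite(x_j)) || any(!is.finite(x_k)))
    stop("non-finite values in input")
  stats::sd(x_j - x_k)
}

#' Gene-stability measure M for a candidate set
#'
#' For each gene j, M_j is the arithmetic mean of the pairwise variations
#' V_jk against every other gene k in the set. Lower M means more stable:
#' a gene whose log2 ratio to every other gene is near-constant across
#' samples tracks the common abundance signal. Condition labels play no
#' role; stability is assessed across all samples pooled.
#'
#' @param m an `expression_matrix` or a numeric matrix (genes x samples)
#'   with rownames, >= 3 genes and >= 2 samples.
#' @return named numeric vector of M values, one per gene.
#' @export
stability_measure <- function(m) {
  x <- as_gene_matrix(m)
  if (nrow(x) < 3)
    stop("stability measure needs >= 3 genes (M for 2 genes is their V, ",
         "computed only at the terminal ranking step)")
  if (ncol(x) < 2) stop("stability measure needs >= 2 samples")
  V <- pairwise_variation_matrix(x)
  rowSums(V) / (nrow(x) - 1)
}

# Full symmetric matrix of V_jk, via the identity
# var(x_j - x_k) = S_jj + S_kk - 2 S_jk with S the gene-gene covariance
# across samples. Tiny negative arguments from rounding are clamped to 0.
pairwise_variation_matrix <- function(x) {
  S <- stats::cov(t(x))
  d <- diag(S)
  V2 <- outer(d, d, "+") - 2 * S
  V2[V2 < 0] <- 0
  V <- sqrt(V2)
  diag(V) <- 0
  dimnames(V) <- list(rownames(x), rownames(x))
  V
}

as_gene_matrix <- function(m) {
  if (inherits(m, "expression_matrix")) m <- m$values
  if (!is.matrix(m) || !is.numeric(m)) stop("expected an expression_matrix or numeric matrix")
  if (is.null(rownames(m))) stop("matrix must have gene rownames")
  if (any(!is.finite(m))) stop("non-finite values in expression matrix")
  m
}

#' Rank genes by expression stability (iterative geNorm exclusion)
#'
#' Computes M for all candidate genes, repeatedly excludes the gene with
#' the highest M (least stable), and updates the remaining M values until
#' `min_remaining` genes are left. Ties on the maximum M are broken
#' lexicographically by gene id (reported via `message`). After excluding
#' gene g from a set of n genes, each remaining M is updated in O(1) as
#' M_j' = (M_j * (n - 1) - V_jg) / (n - 2), which makes the whole ranking
#' quadratic in the number of genes rather than cubic.
#'
#' When the pairwise-variation matrix would exceed `memory_budget` bytes,
#' the same quantities are computed in a chunked two-pass fashion that
#' never materialises the full matrix; both paths give identical results.
#'
#' @param m an `expression_matrix` or numeric matrix (genes x samples),
#'   at least `min_remaining + 1` genes.
#' @param min_remaining number of genes left unranked at the end (the
#'   terminal most-stable set), default 2.
#' @param memory_budget bytes allowed for the pairwise-variation matrix
#'   (default 1 GiB).
#' @return An object of class `stability_ranking`: list with
#'   \describe{
#'     \item{order}{gene ids from first excluded (least stable) to the
#'       terminal set (most stable last).}
#'     \item{m_at_exclusion}{named vector: M value at which each gene was
#'       excluded; the terminal `min_remaining` genes share the M of the
#'       terminal-set computation.}
#'     \item{final_pair}{the terminal most-stable gene set.}
#'     \item{mean_m_trajectory}{average M of the remaining genes after
#'       each exclusion.}
#'   }
#' @export
genorm_rank <- function(m, min_remaining = 2, memory_budget = 2^30) {
  x <- as_gene_matrix(m)
  n <- nrow(x)
  if (min_remaining < 2) stop("min_remaining must be >= 2")
  if (n < min_remaining + 1)
    stop("need at least min_remaining + 1 = ", min_remaining + 1,
         " genes to rank (got ", n, ")")
  if (ncol(x) < 2) stop("need >= 2 samples")

  use_full <- (as.double(n)^2 * 8) <= memory_budget
  s <- ncol(x)
  xc <- x - rowMeans(x)            # per-gene centering; shared by both paths
  d <- rowSums(xc^2) / (s - 1)     # per-gene variance across samples

  v_col <- function(g, rows) {
    # V_{j,g} for j in `rows`, computed from the centered data
    cv <- as.vector(xc[rows, , drop = FALSE] %*% xc[g, ]) / (s - 1)
    v2 <- d[rows] + d[g] - 2 * cv
    v2[v2 < 0] <- 0
    sqrt(v2)
  }

  if (use_full) {
    V <- pairwise_variation_matrix(x)
    M <- rowSums(V) / (n - 1)
  } else {
    # chunked first pass: accumulate row sums of V without storing it
    M <- numeric(n)
    names(M) <- rownames(x)
    chunk <- max(1L, floor(memory_budget / (8 * n)))
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(n, start + chunk - 1L)
      cv <- xc[idx, , drop = FALSE] %*% t(xc) / (s - 1)
      v2 <- outer(d[idx], d, "+") - 2 * cv
      v2[v2 < 0] <- 0
      v2[cbind(seq_along(idx), idx)] <- 0
      M[idx] <- rowSums(sqrt(v2))
    }
    M <- M / (n - 1)
  }
  names(M) <- rownames(x)

  remaining <- rownames(x)
  order_out <- character(0)
  m_at_exclusion <- numeric(0)
  trajectory <- numeric(0)

  while (length(remaining) > min_remaining) {
    k <- length(remaining)
    worst_val <- max(M[remaining])
    ties <- remaining[M[remaining] == worst_val]
    if (length(ties) > 1)
      message("tie on max M (", format(worst_val), ") among ",
              paste(sort(ties), collapse = ", "), "; excluding ",
              sort(ties)[1], " (lexicographic)")
    g <- sort(ties)[1]
    order_out <- c(order_out, g)
    m_at_exclusion[g] <- M[[g]]
    remaining <- setdiff(remaining, g)

    if (length(remaining) >= 2) {
      vg <- if (use_full) V[remaining, g] else v_col(g, remaining)
      M[remaining] <- (M[remaining] * (k - 1) - vg) / (k - 2)
    }
    trajectory <- c(trajectory, mean(M[remaining]))
  }

  # terminal set: every member carries the M of the terminal-set
  # computation, recomputed from scratch so that an exact two-gene tie
  # stays an exact tie (the incremental path leaves rounding residue)
  term_m <- if (length(remaining) == 2)
    stats::setNames(rep(pairwise_variation(x[remaining[1], ],
                                           x[remaining[2], ]), 2), remaining)
  else stability_measure(x[remaining, , drop = FALSE])
  term_m <- term_m[remaining]
  term_order <- remaining[order(-term_m, remaining)]
  order_out <- c(order_out, term_order)
  m_at_exclusion[term_order] <- term_m[term_order]

  structure(list(order = order_out,
                 m_at_exclusion = m_at_exclusion[order_out],
                 final_pair = remaining,
                 mean_m_trajectory = trajectory),
            class = "stability_ranking")
}

#' @export
print.stability_ranking <- function(x, ...) {
  n <- length(x$order)
  cat(sprintf("<stability_ranking> %d genes; most stable: %s\n", n,
              paste(rev(x$order)[seq_len(min(5, n))], collapse = ", ")))
  invisible(x)
}

#' Genes in most-stable-first order
#'
#' @param ranking a `stability_ranking`.
#' @return character vector, most stable gene first.
#' @export
stable_order <- function(ranking) rev(ranking$order)

#' Count genes below stability thresholds
#'
#' For each threshold t, counts the genes whose M at exclusion is < t.
#' Counts are non-decreasing in t.
#'
#' @param ranking a `stability_ranking`.
#' @param thresholds numeric vector.
#' @return named integer vector, one count per threshold.
#' @export
count_below_stability <- function(ranking, thresholds) {
  vapply(thresholds, function(t) sum(ranking$m_at_exclusion < t), integer(1)) |>
    stats::setNames(as.character(thresholds))
}

#' Write a stability ranking to TSV (rank 1 = most stable) and a JSON
#' report with the mean-M trajectory
#'
#' @param ranking a `stability_ranking`.
#' @param path output TSV path.
#' @param json_path optional path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, json_path = NULL) {
  genes <- stable_order(ranking)
  df <- data.frame(rank = seq_along(genes), gene = genes,
                   m_at_exclusion = unname(ranking$m_at_exclusion[genes]))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(final_pair = ranking$final_pair,
                              mean_m_trajectory = ranking$mean_m_trajectory),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
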