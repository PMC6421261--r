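#' Upper tail of the hypergeometric distribution
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the over-representation
#' p-value for observing k or more members of a K-gene set in a query of
#' n genes drawn from a background of N.
#'
#' @param k observed overlap, 0 <= k <= min(K, n).
#' @param K set size within the background.
#' @param n query size.
#' @param N background size.
#' @return p in (0, 1].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of the most stable genes
#'
#' Takes the `top_k` most stable genes from a ranking as the query and
#' tests each supplied gene set for over-representation with the
#' one-sided hypergeometric tail, against a background that should match
#' the universe the ranking was computed on (the post-filter matrix, not
#' the whole transcriptome). Set membership is intersected with the
#' background before testing; sets disjoint from the background are
#' skipped with a message. P-values are Benjamini-Hochberg adjusted
#' across the tested sets.
#'
#' @param ranking a `stability_ranking`.
#' @param top_k number of most-stable genes to use as the query.
#' @param sets a `gene_set_collection`.
#' @param background character vector of gene ids; must contain the
#'   query genes. Defaults to all ranked genes.
#' @return data.frame sorted by p with columns set, k, K, n, N, p,
#'   adjusted_p.
#' @export
enrich_top_stable <- function(ranking, top_k, sets,
                              background = ranking$order) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  genes <- stable_order(ranking)
  if (top_k < 1 || top_k > length(genes))
    stop("top_k must be in [1, ", length(genes), "]")
  query <- genes[seq_len(top_k)]
  outside <- setdiff(query, background)
  if (length(outside))
    stop("background must contain the query genes; missing: ",
         paste(utils::head(outside, 5), collapse = ", "))
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], background)
    if (!length(members)) {
      message("set '", nm, "' is disjoint from the background; skipped")
      return(NULL)
    }
    k <- length(intersect(members, query))
    data.frame(set = nm, k = k, K = length(members), n = n, N = N,
               p = hypergeometric_tail(k, length(members), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene set overlaps the background")
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}
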