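# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive (double loops, full recomputation,
# literal enumeration) and never calls the package's optimized paths.

# Naive pairwise variation: sample SD of the per-sample differences.
naive_v <- function(x_j, x_k) sd(x_j - x_k)

# Naive stability measure: double loop over all gene pairs.
naive_m <- function(x) {
  n <- nrow(x)
  M <- setNames(numeric(n), rownames(x))
  for (j in seq_len(n)) {
    acc <- 0
    for (k in seq_len(n)) if (k != j) acc <- acc + naive_v(x[j, ], x[k, ])
    M[j] <- acc / (n - 1)
  }
  M
}

# Naive O(n^3) iterative-exclusion ranking: recomputes every M from
# scratch at each step. Tie-break and terminal-set conventions mirror
# the documented contract (lexicographic on ties; terminal genes carry
# the terminal-set M, ordered by decreasing M then gene id).
naive_genorm_rank <- function(x, min_remaining = 2) {
  remaining <- rownames(x)
  order_out <- character(0)
  m_at <- numeric(0)
  traj <- numeric(0)
  while (length(remaining) > min_remaining) {
    M <- if (length(remaining) > 2) naive_m(x[remaining, , drop = FALSE])
         else setNames(rep(naive_v(x[remaining[1], ], x[remaining[2], ]), 2),
                       remaining)
    g <- sort(remaining[M == max(M)])[1]
    order_out <- c(order_out, g)
    m_at[g] <- M[[g]]
    remaining <- setdiff(remaining, g)
    M2 <- if (length(remaining) > 2) naive_m(x[remaining, , drop = FALSE])
          else setNames(rep(naive_v(x[remaining[1], ], x[remaining[2], ]), 2),
                        remaining)
    traj <- c(traj, mean(M2))
  }
  Mt <- if (length(remaining) > 2) naive_m(x[remaining, , drop = FALSE])
        else setNames(rep(naive_v(x[remaining[1], ], x[remaining[2], ]), 2),
                      remaining)
  term <- remaining[order(-Mt, remaining)]
  order_out <- c(order_out, term)
  m_at[term] <- Mt[term]
  list(order = order_out, m_at_exclusion = m_at[order_out],
       final_pair = remaining, mean_m_trajectory = traj)
}

# Literal enumeration of the hypergeometric upper tail: draw every
# n-subset of a background of size N whose first K elements are the set.
enum_hypergeom_tail <- function(k, K, n, N) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Random expression_matrix fixture with generic condition labels.
random_em <- function(n_genes, n_samples, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples, 10, sd), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  conds <- rep(c("A", "B"), length.out = n_samples)
  expression_matrix(m, setNames(conds, colnames(m)))
}

# Small Ct-table fixture from a wide spec: list(gene = c(ct reps...)).
ct_fixture <- function(reps_by_gene, sample = "s1", condition = "ctrl",
                       lod = 35) {
  rec <- do.call(rbind, lapply(names(reps_by_gene), function(g) {
    ct <- reps_by_gene[[g]]
    data.frame(gene = g, sample = sample, condition = condition,
               replicate = seq_along(ct), ct = ct)
  }))
  ct_table(rec, lod = lod)
}
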