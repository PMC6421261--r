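#' Configuration for the synthetic senescence-study generator
#'
#' Describes a multi-condition expression study with a planted
#' low-variance "ribosomal-like" stable gene set, condition-responsive
#' filler genes, and optional explicitly planted marker effects. The
#' same configuration drives both the log2 expression-matrix arm
#' ([simulate_expression()], a stand-in for a normalized microarray) and
#' the Ct arm ([simulate_ct()], a stand-in for an RT-qPCR candidate
#' validation with technical replicates).
#'
#' The generative model, all on log2 scale: value(g, s) = baseline_g +
#' effect_g(condition_s) + N(0, sd_g). Stable genes have zero effect in
#' every condition, small sd (`stable_sd`) and a baseline drawn above
#' the bulk of the distribution (`stable_baseline_boost`), mirroring the
#' high abundance of ribosomal transcripts. Filler genes get independent
#' per-condition effects N(0, `effect_sd`) (control = 0) and larger sd.
#' In the Ct arm, Ct(g, s, r) = ct_offset - value(g, s) + N(0,
#' `tech_rep_sd`), with `n_tech_reps` technical replicates and readings
#' beyond `lod` cycles censored.
#'
#' @param n_genes total genes (stable + markers + fillers).
#' @param n_stable planted stable genes, named `RIBO001`, `RIBO002`, ...
#' @param conditions named integer vector: biological replicates per
#'   condition label.
#' @param baseline_mean,baseline_sd log2 baseline abundance distribution.
#' @param stable_baseline_boost added to `baseline_mean` for stable
#'   genes (drawn with sd 1).
#' @param stable_sd,unstable_sd per-gene biological noise sd (log2).
#' @param effect_sd sd of the random per-condition effects of filler
#'   genes (log2).
#' @param effects named list: gene id -> named numeric vector of
#'   per-condition log2 shifts (unlisted conditions default to 0). These
#'   genes are created in addition to stable and filler genes.
#' @param n_low planted low-abundance genes (named `LOWE01`, ...) whose
#'   baseline sits 2 cycles beyond the LOD (log2 baseline =
#'   `ct_offset - lod - 2`), so every technical replicate in the Ct arm
#'   is censored; they exercise the detectability pathway.
#' @param tech_rep_sd technical replicate noise (cycles).
#' @param n_tech_reps technical replicates per well (default 3).
#' @param lod limit of detection (cycles, default 35).
#' @param ct_offset cycles corresponding to log2 quantity 0.
#' @param seed integer RNG seed; fixed seed gives identical output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500,
                       n_stable = 20,
                       conditions = c(control = 3, quiescent = 3,
                                      etoposide = 3, xray = 3,
                                      replicative = 3),
                       baseline_mean = 10,
                       baseline_sd = 3,
                       stable_baseline_boost = 3,
                       stable_sd = 0.05,
                       unstable_sd = 0.5,
                       effect_sd = 1,
                       effects = list(),
                       n_low = 0,
                       tech_rep_sd = 0.15,
                       n_tech_reps = 3,
                       lod = 35,
                       ct_offset = 32,
                       seed = 1) {
  cfg <- list(n_genes = n_genes, n_stable = n_stable, conditions = conditions,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              stable_baseline_boost = stable_baseline_boost,
              stable_sd = stable_sd, unstable_sd = unstable_sd,
              effect_sd = effect_sd, effects = effects, n_low = n_low,
              tech_rep_sd = tech_rep_sd, n_tech_reps = n_tech_reps,
              lod = lod, ct_offset = ct_offset, seed = seed)
  bad <- character(0)
  if (!is.numeric(n_genes) || n_genes < 3) bad <- c(bad, "n_genes")
  if (!is.numeric(n_stable) || n_stable < 0 || n_stable > n_genes)
    bad <- c(bad, "n_stable")
  if (!length(conditions) || is.null(names(conditions)) ||
      any(conditions < 1)) bad <- c(bad, "conditions")
  for (f in c("baseline_sd", "stable_sd", "unstable_sd", "effect_sd",
              "tech_rep_sd"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) bad <- c(bad, f)
  if (!is.numeric(lod) || lod <= 0) bad <- c(bad, "lod")
  if (!is.numeric(n_tech_reps) || n_tech_reps < 1) bad <- c(bad, "n_tech_reps")
  if (!is.numeric(seed) || seed != round(seed)) bad <- c(bad, "seed")
  if (!is.numeric(n_low) || n_low < 0) bad <- c(bad, "n_low")
  if (length(effects)) {
    if (is.null(names(effects))) bad <- c(bad, "effects")
    else if (any(vapply(effects, function(e)
      is.null(names(e)) || !all(names(e) %in% names(conditions)), TRUE)))
      bad <- c(bad, "effects")
  }
  if (n_stable + length(effects) + n_low > n_genes) bad <- c(bad, "n_genes")
  if (length(bad))
    stop("invalid simulation config field(s): ",
         paste(unique(bad), collapse = ", "))
  structure(cfg, class = "sim_config")
}

#' Default configuration for the qPCR candidate-validation arm
#'
#' 28 candidate genes: 5 planted stable ribosomal-like genes, three
#' classical housekeeping genes with planted senescence/quiescence
#' responses (UBC-like down in quiescence and up in senescence, GAPDH-
#' and ACTB-like mildly senescence-responsive), two SASP markers
#' (IL6-like and IGFBP7-like, up in senescence), and 18 fillers —
#' measured over control, quiescent and senescent conditions with
#' 3 biological and 3 technical replicates.
#'
#' @param seed RNG seed (default 7).
#' @param conditions replicate layout (default control/quiescent/
#'   senescent, 3 each).
#' @return a `sim_config`.
#' @export
sim_config_ct <- function(seed = 7,
                          conditions = c(control = 3, quiescent = 3,
                                         senescent = 3)) {
  sen <- setdiff(names(conditions), c("control", "quiescent"))
  eff <- list(
    UBC_like    = c(stats::setNames(rep(1.0, length(sen)), sen),
                    if ("quiescent" %in% names(conditions))
                      c(quiescent = -1.5)),
    GAPDH_like  = stats::setNames(rep(0.8, length(sen)), sen),
    ACTB_like   = stats::setNames(rep(1.2, length(sen)), sen),
    IL6_like    = stats::setNames(rep(2.0, length(sen)), sen),
    IGFBP7_like = stats::setNames(rep(2.5, length(sen)), sen))
  sim_config(n_genes = 28, n_stable = 5, conditions = conditions,
             baseline_mean = 10, baseline_sd = 2,
             stable_baseline_boost = 2,
             stable_sd = 0.05, unstable_sd = 0.3, effect_sd = 0.5,
             effects = eff, seed = seed)
}

#' Default configuration for the matched marker-validation arm
#'
#' A paired design with four biological replicates per group (young vs
#' late-passage, i.e. replicatively senescent), matched one-to-one by
#' clone. The classical housekeeping genes carry planted senescence
#' responses of the same order as the SASP markers, so a normalization
#' factor built from them cancels most of the marker signal — the
#' scenario in which only a stable-panel NF detects the IL6-like
#' upregulation.
#'
#' @param seed RNG seed (default 11).
#' @return a `sim_config`.
#' @export
sim_config_markers <- function(seed = 11) {
  sim_config(n_genes = 16, n_stable = 5,
             conditions = c(young = 4, late_passage = 4),
             baseline_mean = 10, baseline_sd = 2,
             stable_baseline_boost = 2,
             stable_sd = 0.05, unstable_sd = 0.3, effect_sd = 0.5,
             effects = list(UBC_like    = c(late_passage = 1.8),
                            GAPDH_like  = c(late_passage = 1.5),
                            ACTB_like   = c(late_passage = 2.1),
                            IL6_like    = c(late_passage = 2.0),
                            IGFBP7_like = c(late_passage = 2.5)),
             seed = seed)
}

# Shared generative core: per-gene baselines, per-condition effects and
# the noiseless log2 signal plus its biological noise realization.
# Draw order is pinned (baselines, then filler effects by gene, then the
# noise matrix column-major) so a fixed seed is reproducible.
simulate_signal <- function(cfg) {
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  marker_ids <- names(cfg$effects)
  n_fill <- cfg$n_genes - cfg$n_stable - length(marker_ids) - cfg$n_low
  stable_ids <- if (cfg$n_stable) sprintf("RIBO%03d", seq_len(cfg$n_stable)) else character(0)
  low_ids <- if (cfg$n_low) sprintf("LOWE%02d", seq_len(cfg$n_low)) else character(0)
  filler_ids <- if (n_fill) sprintf("GENE%04d", seq_len(n_fill)) else character(0)
  genes <- c(stable_ids, marker_ids, low_ids, filler_ids)
  if (anyDuplicated(genes)) stop("effect gene names collide with generated ids")

  conds <- names(cfg$conditions)
  samples <- unlist(lapply(conds, function(cn)
    sprintf("%s_%d", cn, seq_len(cfg$conditions[[cn]]))))
  cond_of <- stats::setNames(rep(conds, times = cfg$conditions), samples)

  baseline <- c(stats::rnorm(cfg$n_stable,
                             cfg$baseline_mean + cfg$stable_baseline_boost, 1),
                stats::rnorm(length(marker_ids), cfg$baseline_mean,
                             cfg$baseline_sd),
                rep(cfg$ct_offset - cfg$lod - 2, cfg$n_low),
                stats::rnorm(n_fill, cfg$baseline_mean, cfg$baseline_sd))
  names(baseline) <- genes

  effmat <- matrix(0, cfg$n_genes, length(conds),
                   dimnames = list(genes, conds))
  for (g in filler_ids)
    effmat[g, conds != conds[1]] <-
      stats::rnorm(length(conds) - 1, 0, cfg$effect_sd)
  for (g in marker_ids)
    effmat[g, names(cfg$effects[[g]])] <- cfg$effects[[g]]

  noise_sd <- stats::setNames(
    c(rep(cfg$stable_sd, cfg$n_stable),
      rep(cfg$unstable_sd, length(marker_ids) + cfg$n_low + n_fill)), genes)

  signal <- baseline + effmat[, cond_of[samples], drop = FALSE]
  colnames(signal) <- samples
  noise <- matrix(stats::rnorm(length(genes) * length(samples)),
                  length(genes), length(samples)) * noise_sd
  values <- signal + noise

  list(values = values, cond_of = cond_of,
       truth = list(stable_set = stable_ids,
                    low_abundance_set = low_ids,
                    effects = effmat,
                    noise_sd = noise_sd,
                    baseline = baseline,
                    seed = cfg$seed))
}

#' Simulate a log2 expression matrix with planted ground truth
#'
#' @param cfg a `sim_config`.
#' @return list with `matrix` (an `expression_matrix`, scale log2) and
#'   `truth` (stable set, effect matrix, per-gene noise sds, baselines,
#'   seed).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sig <- simulate_signal(cfg)
  list(matrix = expression_matrix(sig$values, sig$cond_of, "log2"),
       truth = sig$truth)
}

#' Simulate a long-format Ct table with technical replicates
#'
#' Converts the simulated log2 quantities to quantification cycles
#' (Ct = ct_offset - log2 quantity), adds technical replicate noise, and
#' censors readings past the limit of detection. Low-abundance genes
#' (log2 baseline below `ct_offset - lod`) land beyond the LOD and
#' exercise the censoring pathway downstream.
#'
#' @param cfg a `sim_config`.
#' @return list with `ct` (a `ct_table`) and `truth` as in
#'   [simulate_expression()].
#' @export
simulate_ct <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sig <- simulate_signal(cfg)
  genes <- rownames(sig$values)
  samples <- colnames(sig$values)
  nrep <- cfg$n_tech_reps
  grid <- expand.grid(replicate = seq_len(nrep), sample = samples,
                      gene = genes, stringsAsFactors = FALSE)
  base_ct <- cfg$ct_offset - sig$values[cbind(grid$gene, grid$sample)]
  ct <- base_ct + stats::rnorm(nrow(grid), 0, cfg$tech_rep_sd)
  records <- data.frame(gene = grid$gene, sample = grid$sample,
                        condition = sig$cond_of[grid$sample],
                        replicate = grid$replicate, ct = ct,
                        stringsAsFactors = FALSE)
  list(ct = ct_table(records, lod = cfg$lod), truth = sig$truth)
}
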