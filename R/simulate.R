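# Synthetic-data generator with known ground truth. The default design
# mirrors a 14-sample study: leaves and fruits at developmental stages
# 3/4/7 and flowers at flowering, each under control and drought, one
# biological sample per cell with three technical qPCR replicates.
#
# Per-sample log2 expression of gene g in sample i:
#   x[g, i] = delta[g, group(i)] + L[i] + eps[g, i]
# with loading factors L ~ N(0, tau^2) shared by all genes of a sample and
# gene noise eps ~ N(0, sigma_g^2). Ct follows as
#   Ct[g, i] = a_g - x[g, i] * log(2) / log(E_g)
# so that one log2 expression unit is one cycle at perfect efficiency.
# A master seed spawns four fixed substreams (loading, gene noise,
# technical replicates, fragment counts) so one stage can be varied while
# the others' draws stay identical.

#' The default 14-sample organ/stage/treatment design
#'
#' Leaves (L) and fruits (G) at developmental stages 3, 4 and 7, flowers
#' (F) at flowering (stage 2), each under control (C) and drought (D):
#' fourteen samples, e.g. `C-L3`, `D-G7`, `C-F`.
#'
#' @return A [sample_metadata()] table with columns `sample_id`, `organ`,
#'   `stage`, `treatment`.
#' @export
goji_design <- function() {
  cells <- rbind(
    expand.grid(organ = "leaf", stage = c("3", "4", "7"),
                treatment = c("control", "drought"), stringsAsFactors = FALSE),
    expand.grid(organ = "flower", stage = "2",
                treatment = c("control", "drought"), stringsAsFactors = FALSE),
    expand.grid(organ = "fruit", stage = c("3", "4", "7"),
                treatment = c("control", "drought"), stringsAsFactors = FALSE))
  code <- c(leaf = "L", flower = "F", fruit = "G")
  id <- paste0(ifelse(cells$treatment == "control", "C-", "D-"),
               code[cells$organ],
               ifelse(cells$organ == "flower", "", cells$stage))
  sample_metadata(data.frame(sample_id = id, cells, stringsAsFactors = FALSE))
}

#' Simulation configuration
#'
#' Collects every generator parameter together with its ground truth. The
#' defaults describe ten candidate genes measured on the 14-sample
#' [goji_design()]: two tightly controlled genes (noise SD 0.05 log2
#' units) and eight progressively noisier ones (SD 0.4 to 1.0), no group
#' effects, sample loading SD 0.5 log2 units, three technical replicates
#' with SD 0.1 cycles, perfect amplification (E = 2), and negative-
#' binomial fragment counts around a mean of 1000 with dispersion 0.05.
#'
#' @param genes Gene ids.
#' @param baseline_ct Per-gene baseline Ct intercept (cycles).
#' @param noise_sd Per-gene biological noise SD (log2 units).
#' @param group_effects `NULL`, or a genes x groups matrix of log2 shifts;
#'   column names must be levels of `group_by` in the design.
#' @param group_by Design column the group effects act on.
#' @param design A [sample_metadata()] table (default [goji_design()]).
#' @param loading_sd SD of the per-sample loading factor (log2 units).
#' @param n_tech_reps,tech_rep_sd Technical replicates per well and their
#'   SD (cycles).
#' @param efficiencies Per-gene amplification efficiency (fold or percent).
#' @param fragment_mean Per-gene negative-binomial mean fragment count.
#' @param fragment_dispersion Per-gene NB dispersion (variance =
#'   mu + dispersion * mu^2); 0 degenerates to Poisson.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(genes = sprintf("gene%02d", 1:10),
                              baseline_ct = seq(18, 25, length.out = length(genes)),
                              noise_sd = default_noise_sd(length(genes)),
                              group_effects = NULL,
                              group_by = "treatment",
                              design = goji_design(),
                              loading_sd = 0.5,
                              n_tech_reps = 3L,
                              tech_rep_sd = 0.1,
                              efficiencies = 2.0,
                              fragment_mean = 1000,
                              fragment_dispersion = 0.05) {
  G <- length(genes)
  if (anyDuplicated(genes)) stop("gene ids must be unique", call. = FALSE)
  recycle <- function(v, what) {
    if (length(v) == 1L) v <- rep(v, G)
    if (length(v) != G) stop("`", what, "` must have length 1 or one value per gene", call. = FALSE)
    stats::setNames(v, genes)
  }
  baseline_ct <- recycle(baseline_ct, "baseline_ct")
  noise_sd <- recycle(noise_sd, "noise_sd")
  efficiencies <- as_efficiency_fold(recycle(efficiencies, "efficiencies"))
  fragment_mean <- recycle(fragment_mean, "fragment_mean")
  fragment_dispersion <- recycle(fragment_dispersion, "fragment_dispersion")
  if (any(noise_sd < 0) || loading_sd < 0 || tech_rep_sd < 0) {
    stop("noise and loading SDs must be nonnegative", call. = FALSE)
  }
  if (any(fragment_mean <= 0) || any(fragment_dispersion < 0)) {
    stop("fragment means must be positive and dispersions nonnegative", call. = FALSE)
  }
  design <- sample_metadata(design)
  if (nrow(design) < 2L) stop("design needs >= 2 samples", call. = FALSE)
  if (!group_by %in% names(design)) {
    stop("`group_by` column not present in the design", call. = FALSE)
  }
  lev <- unique(design[[group_by]])
  if (is.null(group_effects)) {
    group_effects <- matrix(0, G, length(lev), dimnames = list(genes, lev))
  } else {
    group_effects <- as.matrix(group_effects)
    if (nrow(group_effects) != G || is.null(colnames(group_effects)) ||
        !all(lev %in% colnames(group_effects))) {
      stop("`group_effects` must be genes x groups with the design's group levels", call. = FALSE)
    }
    rownames(group_effects) <- genes
    group_effects <- group_effects[, lev, drop = FALSE]
  }
  if (n_tech_reps < 1L) stop("need >= 1 technical replicate", call. = FALSE)
  structure(list(genes = genes, baseline_ct = baseline_ct,
                 noise_sd = noise_sd, group_effects = group_effects,
                 group_by = group_by, design = design,
                 loading_sd = loading_sd, n_tech_reps = as.integer(n_tech_reps),
                 tech_rep_sd = tech_rep_sd, efficiencies = efficiencies,
                 fragment_mean = fragment_mean,
                 fragment_dispersion = fragment_dispersion),
            class = "simulation_config")
}

default_noise_sd <- function(G) {
  if (G < 3L) return(rep(0.3, G))
  c(0.05, 0.05, seq(0.4, 1.0, length.out = G - 2L))
}

# fixed substream derivation: master seed -> 4 stage seeds
stage_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 4L),
                  c("loading", "noise", "replicates", "counts"))
}

sim_truth <- function(config, loading) {
  score <- config$noise_sd + rowMeans(abs(config$group_effects))
  list(loading = loading,
       noise_sd = config$noise_sd,
       group_effects = config$group_effects,
       efficiencies = config$efficiencies,
       stability_score = score,
       stability_order = names(sort(score)))
}

#' Simulate a qPCR Ct dataset with known truth
#'
#' Draws per-sample loading factors, per-gene biological noise and
#' technical-replicate noise under `config`, and returns the Ct matrix
#' (replicate means, with replicates and efficiencies attached), the
#' design metadata and the ground truth. Fully reproducible from
#' `(config, seed)`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer master seed.
#' @return List: `ct` ([ct_matrix()]), `meta` ([sample_metadata()]),
#'   `truth` (loading factors, true noise SDs, group effects, efficiencies
#'   and the implied stability ordering).
#' @export
simulate_ct_dataset <- function(config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  ss <- stage_seeds(seed)
  design <- config$design
  n <- nrow(design)
  G <- length(config$genes)
  groups <- design[[config$group_by]]

  set.seed(ss[["loading"]])
  loading <- stats::setNames(stats::rnorm(n, 0, config$loading_sd), design$sample_id)
  set.seed(ss[["noise"]])
  eps <- sapply(seq_len(n), function(i) stats::rnorm(G, 0, config$noise_sd))
  eps <- matrix(eps, G, n)

  x <- config$group_effects[, groups, drop = FALSE] +
    matrix(loading, G, n, byrow = TRUE) + eps
  cycles_per_log2 <- log(2) / log(config$efficiencies)
  ct_mean <- config$baseline_ct - x * cycles_per_log2
  dimnames(ct_mean) <- list(config$genes, design$sample_id)

  set.seed(ss[["replicates"]])
  reps <- array(stats::rnorm(G * n * config$n_tech_reps, 0, config$tech_rep_sd),
                dim = c(G, n, config$n_tech_reps))
  reps <- reps + as.vector(ct_mean)
  dimnames(reps) <- list(config$genes, design$sample_id, NULL)

  ct <- ct_matrix(replicates = reps, efficiencies = config$efficiencies)
  list(ct = ct, meta = design, truth = sim_truth(config, loading))
}

#' Simulate an RNA-Seq fragment-count table
#'
#' Counts are negative binomial with mean `fragment_mean * 2^(delta + L)`
#' (group effects and the same loading substream as the Ct generator) and
#' per-gene dispersion; dispersion 0 degenerates to Poisson.
#'
#' @inheritParams simulate_ct_dataset
#' @return List: `expr` ([expression_table()], unit `"fragments"`),
#'   `meta`, `truth`.
#' @export
simulate_fragment_counts <- function(config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  ss <- stage_seeds(seed)
  design <- config$design
  n <- nrow(design)
  G <- length(config$genes)
  groups <- design[[config$group_by]]

  set.seed(ss[["loading"]])
  loading <- stats::setNames(stats::rnorm(n, 0, config$loading_sd), design$sample_id)
  mu <- config$fragment_mean *
    2^(config$group_effects[, groups, drop = FALSE] +
         matrix(loading, G, n, byrow = TRUE))

  set.seed(ss[["counts"]])
  counts <- matrix(NA_real_, G, n, dimnames = list(config$genes, design$sample_id))
  for (g in seq_len(G)) {
    disp <- config$fragment_dispersion[g]
    counts[g, ] <- if (disp == 0) stats::rpois(n, mu[g, ])
                   else stats::rnbinom(n, mu = mu[g, ], size = 1 / disp)
  }
  list(expr = expression_table(counts, unit = "fragments"),
       meta = design, truth = sim_truth(config, loading))
}

#' Simulate a standard-curve dilution series
#'
#' Ct at relative template amount d is
#' `intercept - log10(d) / log10(E_true) + N(0, noise_sd^2)`; the default
#' series is six five-fold dilutions.
#'
#' @param e_true True amplification efficiency (fold or percent scale).
#' @param levels Number of dilution levels (>= 3).
#' @param fold Dilution factor between levels (default 5).
#' @param replicates Technical replicates per level.
#' @param noise_sd Ct noise SD (cycles).
#' @param intercept Ct of the undiluted template.
#' @param seed Optional seed (only relevant when `noise_sd > 0`).
#' @param gene Gene id label.
#' @return Data frame of class `dilution_series` with columns `gene`,
#'   `log10_amount`, `ct`.
#' @export
simulate_dilution_series <- function(e_true, levels = 6L, fold = 5,
                                     replicates = 1L, noise_sd = 0,
                                     intercept = 30, seed = NULL,
                                     gene = "gene1") {
  e_true <- as_efficiency_fold(e_true)
  if (levels < 3L) stop("need >= 3 dilution levels", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  log10_amount <- rep(log10(fold^-(seq_len(levels) - 1L)), each = replicates)
  ct <- intercept - log10_amount / log10(e_true) +
    stats::rnorm(length(log10_amount), 0, noise_sd)
  structure(data.frame(gene = gene, log10_amount = log10_amount, ct = ct,
                       stringsAsFactors = FALSE),
            e_true = e_true, class = c("dilution_series", "data.frame"))
}
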