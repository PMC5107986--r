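# Target-gene normalization against alternative reference sets, and
# ANOVA-based checks of whether the choice of normalizer changes the
# expression estimate.

gene_eff <- function(ct, genes) {
  if (is.null(ct$efficiencies)) {
    warning("no efficiencies attached; assuming E = 2.0 (100%)")
    return(stats::setNames(rep(2, length(genes)), genes))
  }
  ct$efficiencies[genes]
}

# genes x samples (x replicates) Ct values for a subset of genes
ct_slab <- function(ct, genes, use_replicates) {
  if (use_replicates) {
    if (is.null(ct$replicates)) stop("no technical replicates attached", call. = FALSE)
    ct$replicates[genes, , , drop = FALSE]
  } else {
    ct$values[genes, , drop = FALSE]
  }
}

#' Efficiency-corrected normalized expression of a target gene
#'
#' Per sample i the relative expression is
#' `E_t^(Ct_t,cal - Ct_t,i) / geomean_r E_r^(Ct_r,cal - Ct_r,i)` over the
#' reference genes r. With `calibrator` set (a sample id or a metadata
#' group of samples), that sample's value is 1 by construction. Without a
#' calibrator, each gene is anchored at its minimum Ct (the relative
#' quantity scale) and values are relative, not calibrated.
#'
#' @param ct A [ct_matrix()] with efficiencies attached (E = 2 assumed,
#'   with a warning, otherwise).
#' @param target Target gene id; must not be among `refs`.
#' @param refs Character vector of reference gene ids.
#' @param calibrator Optional sample id (or vector of sample ids whose mean
#'   Ct serves as the calibrator).
#' @param use_replicates If `TRUE`, compute one value per technical
#'   replicate (requires replicate data) instead of per sample mean.
#' @return List of class `normalized_expression`: `values` (per-sample
#'   vector, or samples x replicates matrix when `use_replicates`),
#'   `target`, `refs`, `calibrator`, `efficiency_corrected`.
#' @export
normalized_expression <- function(ct, target, refs, calibrator = NULL,
                                  use_replicates = FALSE) {
  if (target %in% refs) stop("target gene cannot be one of the references", call. = FALSE)
  genes <- c(target, refs)
  missing_g <- setdiff(genes, rownames(ct$values))
  if (length(missing_g)) stop("gene(s) not in Ct matrix: ", paste(missing_g, collapse = ", "), call. = FALSE)
  eff <- gene_eff(ct, genes)
  log_eff <- log2(eff)

  # anchor Ct per gene: calibrator mean, or the gene's minimum Ct
  if (is.null(calibrator)) {
    anchor <- apply(ct$values[genes, , drop = FALSE], 1L, min, na.rm = TRUE)
  } else {
    bad <- setdiff(calibrator, colnames(ct$values))
    if (length(bad)) stop("calibrator sample(s) not found: ", paste(bad, collapse = ", "), call. = FALSE)
    anchor <- rowMeans(ct$values[genes, calibrator, drop = FALSE])
    if (anyNA(anchor)) stop("calibrator has missing Ct for some gene(s)", call. = FALSE)
  }

  slab <- ct_slab(ct, genes, use_replicates)
  # log2 expression relative to the anchor, efficiency corrected:
  # (anchor - Ct) * log2(E), per gene
  rel <- sweep(slab, 1L, anchor) * -1          # anchor - Ct
  rel <- sweep(rel, 1L, log_eff, "*")          # (anchor - Ct) * log2 E
  if (use_replicates) {
    tgt <- rel[1L, , , drop = TRUE]
    refpart <- apply(rel[-1L, , , drop = FALSE], c(2L, 3L), mean)
    values <- 2^(tgt - refpart)
    if (is.null(dim(values))) values <- matrix(values, nrow = ncol(ct$values),
                                               dimnames = list(colnames(ct$values), NULL))
  } else {
    tgt <- rel[1L, ]
    refpart <- colMeans(rel[-1L, , drop = FALSE])
    values <- 2^(tgt - refpart)
  }
  structure(list(values = values, target = target, refs = refs,
                 calibrator = calibrator,
                 efficiency_corrected = !is.null(ct$efficiencies)),
            class = "normalized_expression")
}

#' Classical one-way ANOVA
#'
#' Fits the one-way fixed-effects decomposition via [stats::lm()] /
#' [stats::anova()] and flags significance at `alpha`. The degenerate case
#' of identical group means with zero residual variance is reported as
#' F = 0, p = 1.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector, same length; >= 2 groups, each with >= 2
#'   values.
#' @param alpha Significance level (default 0.01).
#' @return List: `f`, `p`, `df` (numerator, denominator), `significant`.
#' @export
one_way_anova <- function(values, groups, alpha = 0.01) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  counts <- table(groups)
  if (any(counts < 2L)) {
    stop("group(s) with a single value: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  sst <- sum((values - mean(values))^2)
  if (sst <= 1e-12 * max(1, sum(values^2))) {
    # all values (numerically) identical: no between-group signal
    tab <- list(Df = c(nlevels(groups) - 1L, length(values) - nlevels(groups)))
    return(list(f = 0, p = 1, df = tab$Df, significant = FALSE))
  }
  tab <- suppressWarnings(stats::anova(stats::lm(values ~ groups)))
  f <- tab$`F value`[1L]
  p <- tab$`Pr(>F)`[1L]
  if (!is.finite(f) && tab$`Sum Sq`[2L] <= 1e-12 * sst) {  # exact separation
    f <- Inf; p <- 0
  }
  list(f = f, p = p, df = tab$Df, significant = p < alpha)
}

#' Compare alternative reference-gene sets for a target
#'
#' Normalizes the target against each named reference set, mean-centres
#' each set's log2 profile (normalizers are compared up to a global scale
#' factor, since each set carries its own arbitrary anchor), and runs a
#' one-way ANOVA across reference sets within each sample group. Groups
#' where the normalizer choice changes the centred estimate at `alpha` are
#' flagged.
#'
#' With `grouping = "sample"` (default) each sample is a group and the
#' within-group replication comes from technical replicates, which must be
#' attached to `ct`. With a metadata column as `grouping`, per-sample mean
#' values are used and the samples of each metadata group provide the
#' replication.
#'
#' @param ct A [ct_matrix()].
#' @param target Target gene id.
#' @param reference_sets Named list of >= 2 character vectors of reference
#'   gene ids.
#' @param grouping `"sample"` or a metadata column name.
#' @param meta [sample_metadata()], required for metadata groupings.
#' @param calibrator Optional calibrator passed to
#'   [normalized_expression()].
#' @param alpha Significance level (default 0.01).
#' @return List of class `normalizer_comparison`: `expression` (samples x
#'   sets matrix of per-sample normalized values), `tests` (data frame
#'   `group`, `f`, `p`, `flagged`), `alpha`, `grouping`.
#' @export
compare_normalizers <- function(ct, target, reference_sets,
                                grouping = "sample", meta = NULL,
                                calibrator = NULL, alpha = 0.01) {
  if (length(reference_sets) < 2L) stop("need >= 2 reference sets", call. = FALSE)
  if (is.null(names(reference_sets))) {
    names(reference_sets) <- vapply(reference_sets, paste, "", collapse = "+")
  }
  per_sample <- grouping == "sample"
  if (per_sample && is.null(ct$replicates)) {
    stop("per-sample comparison needs technical replicates on `ct`", call. = FALSE)
  }
  samples <- colnames(ct$values)

  norm <- lapply(reference_sets, function(refs) {
    normalized_expression(ct, target, refs, calibrator = calibrator,
                          use_replicates = per_sample)
  })
  # centred log2 values per set; matrix samples x replicates, or vector
  centred <- lapply(norm, function(ne) {
    lv <- log2(ne$values)
    lv - mean(lv, na.rm = TRUE)
  })
  expr <- vapply(norm, function(ne) {
    v <- ne$values
    if (is.matrix(v)) rowMeans(v) else v
  }, numeric(length(samples)))
  expr <- matrix(expr, length(samples),
                 dimnames = list(samples, names(reference_sets)))

  if (per_sample) {
    groups <- samples
    values_for <- function(g) lapply(centred, function(cm) cm[g, ])
  } else {
    if (is.null(meta)) stop("`meta` is required for metadata groupings", call. = FALSE)
    lab <- group_labels(meta, samples, grouping)
    groups <- unique(lab)
    values_for <- function(g) lapply(centred, function(cm) cm[lab == g])
  }
  tests <- lapply(groups, function(g) {
    vals <- values_for(g)
    y <- unlist(vals, use.names = FALSE)
    f <- rep(names(reference_sets), times = lengths(vals))
    a <- one_way_anova(y, f, alpha = alpha)
    data.frame(group = g, f = a$f, p = a$p, flagged = a$significant,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  structure(list(expression = expr, tests = tests, alpha = alpha,
                 grouping = grouping),
            class = "normalizer_comparison")
}
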