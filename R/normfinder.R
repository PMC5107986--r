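# Model-based stability estimation in the NormFinder spirit: per-sample
# centring removes loading artifacts, intragroup variances are
# bias-adjusted, intergroup differences are shrunken, and the stability
# value combines both. The concrete estimator below is this package's
# normative contract (published reimplementations differ in the
# bias-correction constant):
#
#   (1) x[g, i] = log2 Q
#   (2) z[g, i] = x[g, i] - mean over genes of x[, i]
#   (3) per group: gene mean zbar and intragroup sample variance s2;
#       adjusted sigma2 = max(s2 - mean(s2 of other genes) / (G - 1), floor)
#   (4) d = zbar - mean over groups of zbar, shrunken by
#       gamma2 / (gamma2 + sigma2 / n), gamma2 = across-gene variance of d
#   (5) rho = mean over groups of (|d_shrunk| + sqrt(sigma2 / n))
#
# Lower rho = more stable. With a single group the d terms vanish and
# rho = sqrt(sigma2).

row_group_stats <- function(z, groups) {
  lev <- unique(groups)
  n_g <- vapply(lev, function(l) sum(groups == l), integer(1))
  zbar <- sapply(lev, function(l) rowMeans(z[, groups == l, drop = FALSE]))
  s2 <- sapply(lev, function(l) apply(z[, groups == l, drop = FALSE], 1L, stats::var))
  list(levels = lev, n = stats::setNames(n_g, lev),
       zbar = matrix(zbar, nrow(z), dimnames = list(rownames(z), lev)),
       s2 = matrix(s2, nrow(z), dimnames = list(rownames(z), lev)))
}

adjust_variance <- function(s2_col, floor) {
  G <- length(s2_col)
  adj <- vapply(seq_len(G), function(g) {
    s2_col[g] - mean(s2_col[-g]) / (G - 1L)
  }, numeric(1))
  pmax(adj, floor)
}

#' NormFinder stability values
#'
#' Estimates a per-gene stability value combining intragroup variation and
#' (with two or more groups) the shrunken intergroup expression difference.
#' Works on log2 relative quantities; samples with any missing value are
#' dropped listwise (the per-sample centring in step 2 needs complete gene
#' vectors).
#'
#' @param q Quantity matrix from [relative_quantities()] (a `ct_matrix` is
#'   converted automatically).
#' @param meta A [sample_metadata()] table; required when `grouping` is
#'   given.
#' @param grouping Name of the metadata column defining the groups (e.g.
#'   `"treatment"`); `NULL` runs the single-group model.
#' @param var_floor Lower bound for the bias-adjusted intragroup variance
#'   (default 1e-8), preventing negative adjusted variances.
#' @return List of class `normfinder_result`: `stability` (named rho
#'   vector, lower = more stable), `sigma2` (genes x groups adjusted
#'   intragroup variances), `d` (shrunken intergroup differences; all zero
#'   for a single group), `grouping`, `groups`, `n_dropped_samples`.
#' @export
normfinder_stability <- function(q, meta = NULL, grouping = NULL,
                                 var_floor = 1e-8) {
  q <- as_quantity_matrix(q)
  if (nrow(q) < 2L) stop("need >= 2 genes", call. = FALSE)
  x <- log2(q)
  complete <- colSums(!is.finite(x)) == 0L
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    warning("dropping ", n_dropped, " sample(s) with missing values (listwise)")
    x <- x[, complete, drop = FALSE]
  }
  if (is.null(grouping)) {
    groups <- rep("all", ncol(x))
  } else {
    if (is.null(meta)) stop("`meta` is required when `grouping` is given", call. = FALSE)
    groups <- group_labels(meta, colnames(x), grouping)
  }
  if (ncol(x) < 2L) stop("need >= 2 complete samples", call. = FALSE)
  gs <- row_group_stats(sweep(x, 2L, colMeans(x)), groups)
  if (any(gs$n < 2L)) {
    stop("every group needs >= 2 samples; too small: ",
         paste(gs$levels[gs$n < 2L], collapse = ", "), call. = FALSE)
  }
  G <- nrow(x)
  sigma2 <- apply(gs$s2, 2L, adjust_variance, floor = var_floor)
  sigma2 <- matrix(sigma2, G, dimnames = dimnames(gs$s2))
  n_groups <- length(gs$levels)
  if (n_groups == 1L) {
    d_shrunk <- matrix(0, G, 1L, dimnames = dimnames(sigma2))
    rho <- sqrt(sigma2[, 1L])
  } else {
    d <- gs$zbar - rowMeans(gs$zbar)
    se2 <- sweep(sigma2, 2L, gs$n, "/")
    d_shrunk <- d
    for (j in seq_len(n_groups)) {
      gamma2 <- stats::var(d[, j])
      d_shrunk[, j] <- d[, j] * gamma2 / (gamma2 + se2[, j])
    }
    rho <- rowMeans(abs(d_shrunk) + sqrt(se2))
  }
  structure(list(stability = stats::setNames(as.numeric(rho), rownames(x)),
                 sigma2 = sigma2, d = d_shrunk,
                 grouping = if (is.null(grouping)) "single group" else grouping,
                 groups = stats::setNames(groups, colnames(x)),
                 n_dropped_samples = n_dropped),
            class = "normfinder_result")
}

#' Single-group NormFinder stability
#'
#' Convenience wrapper for subset analyses with one condition: the
#' stability value reduces to the bias-adjusted intragroup standard
#' deviation of the centred log2 quantities.
#'
#' @inheritParams normfinder_stability
#' @return A `normfinder_result` (see [normfinder_stability()]).
#' @export
normfinder_single_group <- function(q, var_floor = 1e-8) {
  q <- as_quantity_matrix(q)
  if (nrow(q) < 3L) stop("need >= 3 genes", call. = FALSE)
  if (ncol(q) < 3L) stop("need >= 3 samples in single-group mode", call. = FALSE)
  normfinder_stability(q, var_floor = var_floor)
}
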