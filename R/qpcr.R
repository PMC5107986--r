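# Standard-curve efficiency estimation, Ct descriptive statistics, and the
# efficiency-corrected relative quantities that feed the stability
# algorithms.

#' Amplification efficiency from a standard-curve slope
#'
#' Implements `E = (10^(-1/slope) - 1) x 100%` for the regression of Ct on
#' log10 template amount. A slope of -3.3219 cycles per decade corresponds
#' to perfect doubling (100%).
#'
#' @param slope Slope of the standard curve, cycles per log10 dilution unit;
#'   must be negative.
#' @return Efficiency in percent. Values above 110% trigger a warning
#'   (implausible amplification).
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.finite(slope) || slope >= 0) {
    stop("standard-curve slope must be negative (Ct rises as template falls)",
         call. = FALSE)
  }
  e <- (10^(-1 / slope) - 1) * 100
  if (e > 110) warning(sprintf("implausible amplification efficiency %.1f%% (> 110%%)", e))
  e
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 relative template amount across a
#' dilution series. Replicate Ct values at a dilution level are supported
#' (stacked points); with balanced replication the fit equals the fit on
#' level means.
#'
#' @param series A data frame with columns `log10_amount` and `ct` (e.g.
#'   from [simulate_dilution_series()]), or a numeric vector of log10
#'   amounts when `ct` is given separately.
#' @param ct Numeric Ct vector, if `series` is a numeric vector.
#' @return List of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared` (squared Pearson correlation of fitted vs observed Ct),
#'   `efficiency_percent`, `efficiency_fold`, `valid` (FALSE when the slope
#'   is nonnegative), `n_levels`.
#' @export
fit_standard_curve <- function(series, ct = NULL) {
  if (is.data.frame(series)) {
    x <- series$log10_amount
    y <- series$ct
  } else {
    x <- as.numeric(series)
    y <- as.numeric(ct)
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 dilution points", call. = FALSE)
  n_levels <- length(unique(x))
  if (n_levels < 2L) stop("all points lie at a single dilution level", call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  valid <- slope < 0
  eff <- if (valid) efficiency_from_slope(slope) else NA_real_
  r2 <- if (stats::var(y) > 0) stats::cor(stats::fitted(fit), y)^2 else 1
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, efficiency_percent = eff,
                 efficiency_fold = if (valid) 1 + eff / 100 else NA_real_,
                 valid = valid, n_levels = n_levels),
            class = "standard_curve")
}

#' Per-gene Ct descriptive statistics
#'
#' Mean, sample SD (n-1) and CV (sd/mean) of each gene's Ct values over
#' non-missing samples. Genes with fewer than two observations are dropped
#' with a warning.
#'
#' @param ct A [ct_matrix()].
#' @return Data frame with columns `gene`, `n`, `mean`, `sd`, `cv`.
#' @export
ct_descriptives <- function(ct) {
  m <- ct$values
  n_obs <- rowSums(!is.na(m))
  if (any(n_obs < 2L)) {
    warning("excluding gene(s) with < 2 observed samples: ",
            paste(rownames(m)[n_obs < 2L], collapse = ", "))
    m <- m[n_obs >= 2L, , drop = FALSE]
    n_obs <- n_obs[n_obs >= 2L]
  }
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1L, stats::sd, na.rm = TRUE)
  data.frame(gene = rownames(m), n = as.integer(n_obs), mean = mu, sd = s,
             cv = s / mu, row.names = NULL, stringsAsFactors = FALSE)
}

#' Efficiency-corrected relative quantities
#'
#' Transforms Ct to the relative-quantity scale used by geNorm:
#' `Q[g, i] = E_g ^ (min(Ct[g, ]) - Ct[g, i])`, so the most-expressed
#' (lowest-Ct) sample of each gene has Q = 1 and all quantities lie in
#' (0, 1]. Missing Ct propagates to missing Q. The choice of the per-gene
#' minimum as anchor is a pure per-gene rescaling: geNorm M/V, NormFinder
#' and the delta-Ct score are invariant to it.
#'
#' @param ct A [ct_matrix()]. Genes without an attached efficiency are
#'   assumed perfectly efficient (E = 2.0) with a warning.
#' @return Genes x samples numeric matrix of relative quantities, with the
#'   per-gene efficiencies attached as attribute `efficiencies`.
#' @export
relative_quantities <- function(ct) {
  m <- ct$values
  eff <- ct$efficiencies
  if (is.null(eff)) {
    warning("no efficiencies attached; assuming E = 2.0 (100%) for all genes")
    eff <- stats::setNames(rep(2, nrow(m)), rownames(m))
  }
  min_ct <- apply(m, 1L, min, na.rm = TRUE)
  q <- eff ^ (min_ct - m)  # column recycling: eff and min_ct are per-gene
  dimnames(q) <- dimnames(m)
  attr(q, "efficiencies") <- eff
  q
}
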