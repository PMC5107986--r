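# BestKeeper descriptive statistics / index correlation, and the
# comparative delta-Ct method. Both operate on raw Ct values, not relative
# quantities.

#' BestKeeper descriptive statistics
#'
#' Per-gene n, geometric and arithmetic mean Ct, extrema, and two
#' dispersion variants: the sample SD (n-1) and the mean absolute deviation
#' from the arithmetic mean (the dispersion the original BestKeeper tool
#' reports). CV% is dispersion / arithmetic mean x 100 for each variant. A
#' gene is flagged stable when the configured dispersion is below 1 cycle.
#'
#' @param ct A [ct_matrix()] with positive Ct values (the geometric mean is
#'   undefined otherwise) and >= 2 samples.
#' @param dispersion Which variant drives the `stable` flag and downstream
#'   ranking: `"sd"` (default) or `"mad"`.
#' @return Data frame of class `bestkeeper_stats`: columns `gene`, `n`,
#'   `geo_mean`, `mean`, `min`, `max`, `sd`, `mad`, `cv_sd_pct`,
#'   `cv_mad_pct`, `dispersion`, `stable`.
#' @export
bestkeeper_descriptives <- function(ct, dispersion = c("sd", "mad")) {
  dispersion <- match.arg(dispersion)
  m <- ct$values
  if (ncol(m) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (any(m <= 0, na.rm = TRUE)) {
    stop("nonpositive Ct: geometric mean undefined", call. = FALSE)
  }
  one <- function(v) {
    v <- v[!is.na(v)]
    mu <- mean(v)
    s <- stats::sd(v)
    md <- mean(abs(v - mu))
    c(n = length(v), geo_mean = exp(mean(log(v))), mean = mu,
      min = min(v), max = max(v), sd = s, mad = md,
      cv_sd_pct = s / mu * 100, cv_mad_pct = md / mu * 100)
  }
  st <- t(apply(m, 1L, one))
  out <- data.frame(gene = rownames(m), st, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$dispersion <- out[[dispersion]]
  out$stable <- out$dispersion < 1
  structure(out, dispersion_variant = dispersion,
            class = c("bestkeeper_stats", "data.frame"))
}

#' BestKeeper index and per-gene correlations
#'
#' The BestKeeper index is the per-sample geometric mean of the candidate
#' genes' Ct values. Every gene of the matrix is then correlated with the
#' index (Pearson r, two-sided p from the exact t distribution with n-2 df,
#' via [stats::cor.test()]). Zero-variance genes get missing r and p,
#' not 0.
#'
#' @param ct A [ct_matrix()].
#' @param genes Subset of >= 2 gene ids the index is built from (default
#'   all genes); correlations are reported for every gene in `ct`.
#' @return List of class `bestkeeper_index`: `index` (named per-sample
#'   vector) and `correlations` (data frame `gene`, `r`, `p`).
#' @export
bestkeeper_index <- function(ct, genes = NULL) {
  m <- ct$values
  if (is.null(genes)) genes <- rownames(m)
  if (length(genes) < 2L) stop("need >= 2 genes for the index", call. = FALSE)
  if (any(m[genes, ] <= 0, na.rm = TRUE)) {
    stop("nonpositive Ct: geometric mean undefined", call. = FALSE)
  }
  idx <- exp(colMeans(log(m[genes, , drop = FALSE])))
  cors <- lapply(rownames(m), function(g) {
    v <- m[g, ]
    ok <- !is.na(v) & !is.na(idx)
    if (sum(ok) < 3L || stats::sd(v[ok]) == 0 || stats::sd(idx[ok]) == 0) {
      return(c(r = NA_real_, p = NA_real_))
    }
    ht <- stats::cor.test(v[ok], idx[ok], method = "pearson")
    c(r = unname(ht$estimate), p = ht$p.value)
  })
  cors <- do.call(rbind, cors)
  structure(list(index = idx,
                 correlations = data.frame(gene = rownames(m), cors,
                                           row.names = NULL,
                                           stringsAsFactors = FALSE)),
            class = "bestkeeper_index")
}

#' Comparative delta-Ct stability
#'
#' For every gene pair (g, k) the sample SD of `Ct_g - Ct_k` across samples
#' is computed; a gene's score is the mean of its pairwise SDs against all
#' other genes. With perfect amplification (E = 2 for every gene) this
#' score is algebraically identical to the geNorm first-round M value.
#' Pairs with fewer than two common samples are dropped from a gene's mean
#' with a warning.
#'
#' @param ct A [ct_matrix()] with >= 3 genes.
#' @return List of class `delta_ct_result`: `scores` (named per-gene mean
#'   pairwise SD) and `pairwise_sd` (symmetric matrix, zero diagonal).
#' @export
delta_ct_stability <- function(ct) {
  m <- ct$values
  G <- nrow(m)
  if (G < 3L) stop("need >= 3 genes", call. = FALSE)
  V <- matrix(NA_real_, G, G, dimnames = list(rownames(m), rownames(m)))
  diag(V) <- 0
  dropped <- FALSE
  for (g in seq_len(G - 1L)) {
    for (k in seq.int(g + 1L, G)) {
      d <- m[g, ] - m[k, ]
      d <- d[!is.na(d)]
      if (length(d) < 2L) dropped <- TRUE else V[g, k] <- V[k, g] <- stats::sd(d)
    }
  }
  if (dropped) warning("pair(s) with < 2 common samples dropped from the mean")
  scores <- vapply(seq_len(G), function(g) mean(V[g, -g], na.rm = TRUE), numeric(1))
  structure(list(scores = stats::setNames(scores, rownames(m)), pairwise_sd = V),
            class = "delta_ct_result")
}
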