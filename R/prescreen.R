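# RNA-Seq prescreen: candidate reference genes are transcripts with high
# mean abundance and low coefficient of variation across samples.

#' Per-transcript abundance statistics
#'
#' Arithmetic mean, sample standard deviation (n-1 denominator) and
#' coefficient of variation (sd/mean) across samples. A transcript with zero
#' mean has an undefined CV (`NA`); it is not an error here and fails the
#' screen downstream with reason "zero mean".
#'
#' @param table An [expression_table()] (or plain matrix, transcripts in
#'   rows) with at least two sample columns.
#' @return Data frame with columns `transcript`, `mean`, `sd`, `cv`.
#' @export
abundance_stats <- function(table) {
  m <- if (inherits(table, "expression_table")) unclass(table) else as.matrix(table)
  if (ncol(m) < 2L) stop("need >= 2 samples to estimate a standard deviation", call. = FALSE)
  mu <- rowMeans(m)
  s <- apply(m, 1L, stats::sd)
  cv <- ifelse(mu > 0, s / mu, NA_real_)
  data.frame(transcript = rownames(m), mean = mu, sd = s, cv = cv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen candidate reference genes by abundance and CV thresholds
#'
#' A transcript passes when `mean > min_mean` and `cv < max_cv` (both strict
#' inequalities; boundary-equal values fail). Output rows are ordered by
#' ascending CV, the most uniform transcripts first.
#'
#' @param stats Data frame with columns `mean` and `cv` and an id column
#'   (`transcript` or `gene`, else the first column), e.g. from
#'   [abundance_stats()] or a published per-gene summary table.
#' @param min_mean Minimum mean abundance (exclusive). Default 500 raw
#'   fragments.
#' @param max_cv Maximum coefficient of variation (exclusive). Default 0.3.
#' @return Data frame of class `candidate_set` with columns `transcript`,
#'   `mean`, `sd` (if available), `cv`, `pass`, `reason`, ordered by
#'   ascending CV; thresholds stored as attributes.
#' @export
screen_candidates <- function(stats, min_mean = 500, max_cv = 0.3) {
  if (min_mean <= 0 || max_cv <= 0) stop("thresholds must be positive", call. = FALSE)
  stats <- as.data.frame(stats, stringsAsFactors = FALSE)
  if (!all(c("mean", "cv") %in% names(stats))) {
    stop("`stats` needs columns `mean` and `cv`", call. = FALSE)
  }
  id_col <- intersect(c("transcript", "gene"), names(stats))
  id <- if (length(id_col)) as.character(stats[[id_col[1L]]]) else as.character(stats[[1L]])
  mu <- stats$mean
  cv <- stats$cv
  zero <- mu == 0 | is.na(cv)
  ok_mean <- !zero & mu > min_mean
  ok_cv <- !zero & cv < max_cv
  pass <- ok_mean & ok_cv
  reason <- character(length(mu))
  reason[zero] <- "zero mean"
  both <- !zero & !ok_mean & !ok_cv
  reason[both] <- sprintf("mean <= %g; cv >= %g", min_mean, max_cv)
  reason[!zero & !ok_mean & ok_cv] <- sprintf("mean <= %g", min_mean)
  reason[!zero & ok_mean & !ok_cv] <- sprintf("cv >= %g", max_cv)
  reason[pass] <- ""
  out <- data.frame(transcript = id, mean = mu,
                    sd = if ("sd" %in% names(stats)) stats$sd else NA_real_,
                    cv = cv, pass = pass, reason = reason,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$cv, out$transcript, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, min_mean = min_mean, max_cv = max_cv,
            class = c("candidate_set", "data.frame"))
}
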