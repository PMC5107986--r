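# Accessors for the published per-gene summary tables shipped with the
# package (18 candidate reference genes + the LbMYB1 target from the goji
# study: RNA-Seq abundance summaries and qPCR amplicon characteristics).

#' Published RNA-Seq abundance summary of the goji candidate genes
#'
#' Per-transcript mean raw fragments, SD and CV over the 14 goji samples,
#' as published, plus an `is_target` flag marking the LbMYB1 target gene.
#' Suitable as direct input to [screen_candidates()].
#'
#' @return Data frame with columns `transcript`, `gene`, `mean`, `sd`,
#'   `cv`, `is_target`.
#' @export
goji_abundance_summary <- function() {
  path <- system.file("extdata", "goji_candidate_abundance.tsv",
                      package = "refstab", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$is_target <- as.logical(df$is_target)
  df
}

#' Published qPCR summary of the goji candidate genes
#'
#' Per-gene amplification efficiency (percent), standard-curve R-squared,
#' and mean/SD/CV of Ct over the 14 goji samples, as published.
#'
#' @return Data frame with columns `gene`, `efficiency_percent`,
#'   `r_squared`, `mean_ct`, `sd`, `cv`, `is_target`.
#' @export
goji_qpcr_summary <- function() {
  path <- system.file("extdata", "goji_qpcr_summary.tsv",
                      package = "refstab", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$is_target <- as.logical(df$is_target)
  df
}
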