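# Tabular input/output. Delimiter auto-detected between comma and tab;
# decimal separator is always ".". Genes are rows, samples are columns
# (a transpose flag handles the other orientation).

detect_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) >=
      lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))) "\t" else ","
}

read_id_table <- function(path, sep = NULL) {
  sep <- detect_sep(path, sep)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("table needs an id column plus at least one data column", call. = FALSE)
  df
}

# parse character columns to numeric with an error naming the offending cell;
# empty strings and the `na` tokens become NA
parse_numeric_matrix <- function(df, na = c("", "NA"), what = "value") {
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicated id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  cols <- names(df)[-1L]
  m <- matrix(NA_real_, nrow(df), length(cols), dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    raw <- trimws(df[[j + 1L]])
    miss <- raw %in% na
    num <- suppressWarnings(as.numeric(raw))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("non-numeric %s '%s' at row '%s', column '%s'",
                   what, raw[i], ids[i], cols[j]), call. = FALSE)
    }
    m[, j] <- num
  }
  m
}

#' Read a Ct table
#'
#' Reads a CSV/TSV file with gene ids in the first column and sample ids in
#' the header. An optional per-gene efficiency column (percent or fold scale)
#' is pulled out of the table; alternatively pass `efficiencies` directly.
#' Empty cells and `"NA"` are recorded as missing, never as zero.
#'
#' @param path Path to a CSV or TSV file.
#' @param sep Field separator; `NULL` (default) auto-detects "," vs tab.
#' @param transpose If `TRUE` the file has samples in rows and genes in
#'   columns and is transposed after reading.
#' @param efficiency_col Name of an optional efficiency column in the file.
#' @param efficiencies Optional per-gene efficiencies overriding the file.
#' @return A [ct_matrix()].
#' @export
read_ct_table <- function(path, sep = NULL, transpose = FALSE,
                          efficiency_col = "efficiency", efficiencies = NULL) {
  df <- read_id_table(path, sep)
  eff <- NULL
  if (efficiency_col %in% names(df)) {
    eff <- stats::setNames(suppressWarnings(as.numeric(df[[efficiency_col]])), df[[1L]])
    if (anyNA(eff)) stop("non-numeric efficiency in column ", efficiency_col, call. = FALSE)
    df[[efficiency_col]] <- NULL
  }
  m <- parse_numeric_matrix(df, what = "Ct")
  if (transpose) m <- t(m)
  if (!is.null(efficiencies)) eff <- efficiencies
  ct_matrix(m, efficiencies = eff)
}

#' Read an RNA-Seq abundance table
#'
#' Same dialect rules as [read_ct_table()]: transcript ids in the first
#' column, samples in the header. Negative values are rejected.
#'
#' @inheritParams read_ct_table
#' @param unit Abundance unit tag, `"fragments"` or `"fpkm"`.
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path, sep = NULL, transpose = FALSE,
                                  unit = c("fragments", "fpkm")) {
  m <- parse_numeric_matrix(read_id_table(path, sep), what = "abundance")
  if (transpose) m <- t(m)
  expression_table(m, unit = match.arg(unit))
}

#' Read a sample metadata table
#'
#' CSV/TSV with a `sample_id` column plus grouping columns (e.g. organ,
#' stage, treatment). Empty grouping cells are an error.
#'
#' @inheritParams read_ct_table
#' @return A [sample_metadata()] data.frame.
#' @export
read_sample_metadata <- function(path, sep = NULL) {
  sep <- detect_sep(path, sep)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) names(df)[1L] <- "sample_id"
  sample_metadata(df)
}

#' Write a Ct matrix or expression table to TSV
#'
#' Full-precision round-trip companion to the readers: values are written
#' with 17 significant digits so `write_ct_table()` then [read_ct_table()]
#' reproduces the matrix exactly.
#'
#' @param x A `ct_matrix` or `expression_table`.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path, sep = "\t") {
  m <- if (inherits(x, "ct_matrix")) x$values else unclass(x)
  df <- data.frame(gene = rownames(m), format(m, digits = 17, trim = TRUE,
                                              scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[j + 1L]][is.na(m[, j])] <- ""  # missing stays empty
  if (inherits(x, "ct_matrix") && !is.null(x$efficiencies)) {
    df$efficiency <- format(x$efficiencies, digits = 17, trim = TRUE)
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# recursively sort list names so serialized JSON is byte-stable
sort_names_rec <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (!is.null(names(x)) && any(nzchar(names(x)))) x <- x[order(names(x))]
    x <- lapply(x, sort_names_rec)
  }
  x
}

#' Write a stability report bundle
#'
#' Writes a machine-readable TSV (one row per gene: per-algorithm scores,
#' geometric-mean rank, final rank) plus a structured JSON summary with the
#' per-algorithm results, consensus, chosen gene pair and the V(n/n+1)
#' series. Output is byte-identical across reruns on identical input (keys
#' sorted, fixed formatting).
#'
#' @param evaluation A `stability_evaluation` from [evaluate_stability()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; files `<prefix>.tsv` and `<prefix>.json`.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_report <- function(evaluation, dir, prefix = "stability_report") {
  if (!inherits(evaluation, "stability_evaluation")) {
    stop("`evaluation` must come from evaluate_stability()", call. = FALSE)
  }
  if (length(evaluation$results) == 0L) stop("no algorithm results to report", call. = FALSE)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create report directory: ", dir, call. = FALSE)
  }
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  json <- file.path(dir, paste0(prefix, ".json"))
  utils::write.table(evaluation$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  payload <- sort_names_rec(unclass_evaluation(evaluation))
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(tsv = tsv, json = json))
}

# flatten a stability_evaluation into plain lists for JSON
unclass_evaluation <- function(ev) {
  res <- lapply(ev$results, function(r) {
    list(algorithm = attr(r, "algorithm"),
         scores = as.list(stats::setNames(r$score, r$gene)),
         ranks = as.list(stats::setNames(r$rank, r$gene)))
  })
  out <- list(algorithms = res,
              consensus = list(
                comprehensive_value = as.list(ev$consensus$comprehensive_value),
                final_order = ev$consensus$final_order))
  if (!is.null(ev$genorm)) {
    out$genorm <- list(
      best_pair = ev$genorm$ranking$best_pair,
      best_pair_m = ev$genorm$ranking$best_pair_m,
      exclusion_order = ev$genorm$ranking$exclusion_order,
      v_series = as.list(ev$genorm$v$v),
      optimal_n = ev$genorm$v$optimal_n,
      threshold_met = ev$genorm$v$threshold_met)
  }
  out
}
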