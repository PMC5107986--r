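# Shared data containers for the pipeline. Plain S3 over base matrices and
# data.frames: every downstream algorithm consumes genes-in-rows matrices.

#' Convert amplification efficiencies to the fold scale
#'
#' Efficiencies may be given on the fold-per-cycle scale (2.0 = perfect
#' doubling) or as percentages (100 = doubling). Values above 2.2 are
#' interpreted as percentages and converted to fold via `1 + E/100`; the
#' result must lie in (1, 2.2].
#'
#' @param e Numeric vector of efficiencies (fold or percent).
#' @return Numeric vector on the fold scale.
#' @export
as_efficiency_fold <- function(e) {
  e <- as.numeric(e)
  pct <- !is.na(e) & e > 2.2
  e[pct] <- 1 + e[pct] / 100
  bad <- !is.na(e) & (e <= 1 | e > 2.2)
  if (any(bad)) {
    stop("amplification efficiency outside (1.0, 2.2] after conversion: ",
         paste(format(e[bad]), collapse = ", "), call. = FALSE)
  }
  e
}

#' Quantification-cycle (Ct) matrix
#'
#' Bundles a genes x samples matrix of Ct values with per-gene amplification
#' efficiencies and, optionally, the individual technical-replicate values
#' the per-well means were computed from.
#'
#' @param values Numeric matrix with gene rownames and sample colnames.
#'   Missing measurements are `NA`; Ct values must be positive. May be `NULL`
#'   if `replicates` is given, in which case replicate means are used.
#' @param efficiencies Per-gene amplification efficiency, fold scale or
#'   percent (see [as_efficiency_fold()]). Length 1 (recycled), unnamed of
#'   length `nrow(values)`, or named by gene. `NULL` leaves efficiencies
#'   unset; downstream code then assumes 2.0 with a warning.
#' @param replicates Optional genes x samples x replicates numeric array of
#'   technical-replicate Ct values (dimnames on the first two margins must
#'   match `values`).
#' @return An object of class `ct_matrix`: a list with elements `values`,
#'   `efficiencies` and `replicates`.
#' @export
ct_matrix <- function(values = NULL, efficiencies = NULL, replicates = NULL) {
  if (is.null(values)) {
    if (is.null(replicates)) stop("supply `values` or `replicates`", call. = FALSE)
    values <- apply(replicates, c(1, 2), function(v) {
      v <- v[is.finite(v)]
      if (length(v)) mean(v) else NA_real_
    })
  }
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("Ct matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup)) stop("duplicated gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup)) stop("duplicated sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  values[!is.finite(values)] <- NA_real_
  if (any(values <= 0, na.rm = TRUE)) {
    stop("Ct values must be positive cycles (or NA for missing)", call. = FALSE)
  }
  genes <- rownames(values)
  if (!is.null(efficiencies)) {
    if (!is.null(names(efficiencies))) {
      missing_e <- setdiff(genes, names(efficiencies))
      if (length(missing_e)) {
        stop("no efficiency for gene(s): ", paste(missing_e, collapse = ", "), call. = FALSE)
      }
      efficiencies <- efficiencies[genes]
    } else if (length(efficiencies) == 1L) {
      efficiencies <- rep(efficiencies, length(genes))
    } else if (length(efficiencies) != length(genes)) {
      stop("`efficiencies` must have length 1 or one value per gene", call. = FALSE)
    }
    efficiencies <- stats::setNames(as_efficiency_fold(efficiencies), genes)
  }
  if (!is.null(replicates)) {
    replicates <- unclass(replicates)
    if (length(dim(replicates)) != 3L ||
        !identical(dim(replicates)[1:2], dim(values))) {
      stop("`replicates` must be a genes x samples x replicates array", call. = FALSE)
    }
    dimnames(replicates)[1:2] <- dimnames(values)
  }
  structure(list(values = values, efficiencies = efficiencies,
                 replicates = replicates),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("<ct_matrix> %d genes x %d samples", nrow(x$values), ncol(x$values)))
  if (!is.null(x$replicates)) cat(sprintf(", %d technical replicates", dim(x$replicates)[3]))
  cat("\n")
  if (is.null(x$efficiencies)) {
    cat("efficiencies: unset (2.0 assumed downstream)\n")
  } else {
    cat(sprintf("efficiencies: %.3f-%.3f (fold scale)\n",
                min(x$efficiencies), max(x$efficiencies)))
  }
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$values)

#' RNA-Seq abundance table
#'
#' @param values Nonnegative numeric matrix, transcripts in rows (rownames)
#'   and samples in columns (colnames).
#' @param unit Abundance unit, `"fragments"` (raw fragment counts) or
#'   `"fpkm"`.
#' @return Numeric matrix of class `expression_table` with attribute `unit`.
#' @export
expression_table <- function(values, unit = c("fragments", "fpkm")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression table needs transcript rownames and sample colnames", call. = FALSE)
  }
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup)) stop("duplicated transcript id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup)) stop("duplicated sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  if (any(values < 0, na.rm = TRUE)) stop("abundance values must be nonnegative", call. = FALSE)
  structure(values, unit = unit, class = c("expression_table", class(values)))
}

#' Sample metadata table
#'
#' Maps each sample to its grouping labels (organ, developmental stage,
#' treatment, plus any extra columns). All grouping cells must be non-empty.
#'
#' @param df A data.frame with a `sample_id` column and one or more grouping
#'   columns (character or factor).
#' @return A `sample_metadata` data.frame.
#' @export
sample_metadata <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata needs a `sample_id` column", call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicated sample id(s) in metadata: ", paste(dup, collapse = ", "), call. = FALSE)
  if (ncol(df) < 2L) stop("metadata needs at least one grouping column", call. = FALSE)
  for (col in setdiff(names(df), "sample_id")) {
    v <- as.character(df[[col]])
    empty <- is.na(v) | !nzchar(trimws(v))
    if (any(empty)) {
      stop(sprintf("empty `%s` label for sample(s): %s", col,
                   paste(df$sample_id[empty], collapse = ", ")), call. = FALSE)
    }
    df[[col]] <- v
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Check that every sample of a matrix is described by the metadata
#'
#' @param meta A [sample_metadata()] table.
#' @param x A `ct_matrix`, `expression_table`, matrix, or character vector of
#'   sample ids.
#' @return Invisibly `TRUE`; errors naming any sample absent from `meta`.
#' @export
validate_samples <- function(meta, x) {
  ids <- if (inherits(x, "ct_matrix")) colnames(x$values)
         else if (is.matrix(x)) colnames(x)
         else as.character(x)
  missing_ids <- setdiff(ids, meta$sample_id)
  if (length(missing_ids)) {
    stop("sample(s) missing from metadata: ", paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# internal: group labels for the columns of a matrix, in column order
group_labels <- function(meta, sample_ids, grouping) {
  if (!grouping %in% names(meta)) {
    stop(sprintf("grouping column `%s` not found in metadata", grouping), call. = FALSE)
  }
  validate_samples(meta, sample_ids)
  meta[[grouping]][match(sample_ids, meta$sample_id)]
}

#' Per-gene stability scores from one algorithm
#'
#' Light container tying scores and ranks to the algorithm that produced
#' them. All four algorithms in this package are lower-is-more-stable.
#'
#' @param algorithm One of `"genorm"`, `"normfinder"`, `"bestkeeper"`,
#'   `"delta_ct"`.
#' @param scores Named numeric vector of per-gene scores.
#' @param lower_is_stabler Direction flag; `TRUE` for all shipped algorithms.
#' @param subset Free-form description of the sample subset analysed.
#' @return A `stability_result` data.frame with columns `gene`, `score`,
#'   `rank` and attributes `algorithm`, `lower_is_stabler`, `subset`.
#' @export
stability_result <- function(algorithm, scores, lower_is_stabler = TRUE,
                             subset = "all samples") {
  if (is.null(names(scores))) stop("`scores` must be named by gene", call. = FALSE)
  res <- data.frame(gene = names(scores), score = as.numeric(scores),
                    rank = rank_genes(scores, lower_is_stabler),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, algorithm = algorithm, lower_is_stabler = lower_is_stabler,
            subset = subset, class = c("stability_result", "data.frame"))
}
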