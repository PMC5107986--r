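# RefFinder-style integration: per-algorithm ranks are combined by the
# plain geometric mean of ranks (the undocumented internal weighting of the
# RefFinder web tool is deliberately not reproduced).

#' Rank genes by a stability score
#'
#' Average ranks (ties share the mean of their positions), 1 = most stable.
#' Missing scores rank after all finite scores, with a warning.
#'
#' @param scores Named numeric vector of per-gene scores.
#' @param lower_is_stabler `TRUE` (default) when a smaller score means a
#'   more stable gene.
#' @return Named numeric vector of ranks.
#' @export
rank_genes <- function(scores, lower_is_stabler = TRUE) {
  s <- as.numeric(scores)
  if (anyNA(s)) {
    warning("missing score(s); affected gene(s) ranked last: ",
            paste(names(scores)[is.na(s)], collapse = ", "))
  }
  if (!lower_is_stabler) s <- -s
  s[is.na(s)] <- Inf
  stats::setNames(rank(s, ties.method = "average"), names(scores))
}

#' Comprehensive (geometric-mean) ranking across algorithms
#'
#' Combines two or more per-gene rank vectors into a comprehensive
#' stability value: the geometric mean of each gene's ranks. The value lies
#' in [1, G]; it equals 1 only for a gene ranked first by every algorithm
#' and G only for a gene ranked last by every algorithm. The final ordering
#' is ascending in the value, ties broken by gene id.
#'
#' @param rank_lists Named list of >= 2 named rank vectors over the same
#'   gene set (e.g. from [rank_genes()]).
#' @return List of class `consensus_result`: `ranks_by_method` (genes x
#'   algorithms matrix), `comprehensive_value` (named vector),
#'   `final_order` (gene ids, most stable first), `final_rank` (average
#'   ranks of the comprehensive values).
#' @export
comprehensive_rank <- function(rank_lists) {
  if (length(rank_lists) < 2L) stop("need >= 2 rank lists", call. = FALSE)
  genes <- sort(names(rank_lists[[1L]]))
  for (i in seq_along(rank_lists)) {
    other <- sort(names(rank_lists[[i]]))
    if (!identical(genes, other)) {
      diff <- c(setdiff(genes, other), setdiff(other, genes))
      stop("rank lists disagree on the gene set; differing gene(s): ",
           paste(unique(diff), collapse = ", "), call. = FALSE)
    }
  }
  R <- vapply(rank_lists, function(r) r[genes], numeric(length(genes)))
  R <- matrix(R, length(genes),
              dimnames = list(genes, names(rank_lists)))
  value <- exp(rowMeans(log(R)))
  ord <- order(value, genes)
  structure(list(ranks_by_method = R,
                 comprehensive_value = value,
                 final_order = genes[ord],
                 final_rank = stats::setNames(rank(value, ties.method = "average"),
                                              genes)),
            class = "consensus_result")
}

#' Agreement sets between algorithms
#'
#' Intersection of each algorithm's k most stable genes, and of each
#' algorithm's k least stable genes.
#'
#' @param rank_lists Named list of named rank vectors over the same genes.
#' @param k Set size, 1 <= k <= number of genes.
#' @return List with character vectors `top` and `bottom`.
#' @export
method_agreement <- function(rank_lists, k) {
  G <- length(rank_lists[[1L]])
  if (k < 1L || k > G) stop("`k` must be between 1 and the number of genes", call. = FALSE)
  pick <- function(r, decreasing) {
    names(r)[order(r, names(r), decreasing = decreasing)][seq_len(k)]
  }
  list(top = Reduce(intersect, lapply(rank_lists, pick, decreasing = FALSE)),
       bottom = Reduce(intersect, lapply(rank_lists, pick, decreasing = TRUE)))
}

#' Run the full stability evaluation
#'
#' Convenience pipeline: relative quantities, the four stability algorithms
#' and the geometric-mean consensus in one call.
#'
#' @param ct A [ct_matrix()].
#' @param meta Optional [sample_metadata()]; enables the grouped NormFinder
#'   model.
#' @param grouping Metadata column for NormFinder groups (default
#'   `"treatment"`); ignored (single-group model) when `meta` is `NULL`.
#' @param algorithms Subset (>= 2) of `"genorm"`, `"normfinder"`,
#'   `"bestkeeper"`, `"delta_ct"`.
#' @param dispersion BestKeeper dispersion variant, `"sd"` or `"mad"`.
#' @param v_threshold geNorm pairwise-variation cutoff (default 0.15).
#' @return List of class `stability_evaluation`: `results` (named list of
#'   [stability_result()]s), `consensus`, `genorm` (ranking + V series, if
#'   run), `normfinder`, `bestkeeper`, `delta_ct`, and `table`, a per-gene
#'   data frame with columns `gene`, `genorm_M`, `normfinder`,
#'   `bestkeeper_SD`, `deltact`, `geomean_rank`, `final_rank`.
#' @export
evaluate_stability <- function(ct, meta = NULL, grouping = "treatment",
                               algorithms = c("genorm", "normfinder",
                                              "bestkeeper", "delta_ct"),
                               dispersion = c("sd", "mad"),
                               v_threshold = 0.15) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  dispersion <- match.arg(dispersion)
  if (length(algorithms) < 2L) stop("need >= 2 algorithms for a consensus", call. = FALSE)
  q <- relative_quantities(ct)
  genes <- rownames(ct$values)
  out <- list(results = list())
  scores <- list()
  ranks <- list()

  if ("genorm" %in% algorithms) {
    gr <- genorm_ranking(q)
    pv <- pairwise_v(q, gr, threshold = v_threshold)
    out$genorm <- list(ranking = gr, v = pv)
    scores$genorm <- gr$m_final
    ranks$genorm <- gr$ranks
    out$results$genorm <- stability_result("genorm", gr$m_final)
    out$results$genorm$rank <- unname(gr$ranks[out$results$genorm$gene])
  }
  if ("normfinder" %in% algorithms) {
    nf <- if (is.null(meta)) normfinder_stability(q)
          else normfinder_stability(q, meta, grouping)
    out$normfinder <- nf
    scores$normfinder <- nf$stability
    out$results$normfinder <- stability_result("normfinder", nf$stability)
    ranks$normfinder <- stats::setNames(out$results$normfinder$rank,
                                        out$results$normfinder$gene)
  }
  if ("bestkeeper" %in% algorithms) {
    bk <- bestkeeper_descriptives(ct, dispersion = dispersion)
    out$bestkeeper <- list(stats = bk, index = bestkeeper_index(ct))
    s <- stats::setNames(bk$dispersion, bk$gene)
    scores$bestkeeper <- s
    out$results$bestkeeper <- stability_result("bestkeeper", s)
    ranks$bestkeeper <- stats::setNames(out$results$bestkeeper$rank,
                                        out$results$bestkeeper$gene)
  }
  if ("delta_ct" %in% algorithms) {
    dc <- delta_ct_stability(ct)
    out$delta_ct <- dc
    scores$delta_ct <- dc$scores
    out$results$delta_ct <- stability_result("delta_ct", dc$scores)
    ranks$delta_ct <- stats::setNames(out$results$delta_ct$rank,
                                      out$results$delta_ct$gene)
  }

  out$consensus <- comprehensive_rank(ranks)
  pick <- function(nm) {
    if (nm %in% names(scores)) unname(scores[[nm]][genes]) else NA_real_
  }
  out$table <- data.frame(
    gene = genes,
    genorm_M = pick("genorm"),
    normfinder = pick("normfinder"),
    bestkeeper_SD = pick("bestkeeper"),
    deltact = pick("delta_ct"),
    geomean_rank = unname(out$consensus$comprehensive_value[genes]),
    final_rank = unname(out$consensus$final_rank[genes]),
    row.names = NULL, stringsAsFactors = FALSE)
  out$table <- out$table[order(out$table$final_rank, out$table$gene), ]
  rownames(out$table) <- NULL
  class(out) <- "stability_evaluation"
  out
}

#' @export
print.stability_evaluation <- function(x, ...) {
  cat("<stability_evaluation>\n")
  print(x$table, digits = 4)
  if (!is.null(x$genorm)) {
    cat(sprintf("geNorm best pair: %s (M = %.4g); optimal n = %d%s\n",
                paste(x$genorm$ranking$best_pair, collapse = " + "),
                x$genorm$ranking$best_pair_m, x$genorm$v$optimal_n,
                if (x$genorm$v$threshold_met) "" else " (V threshold never met)"))
  }
  invisible(x)
}
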