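# geNorm: expression-stability measure M, iterative-exclusion ranking,
# normalization factors and pairwise variation V(n/n+1). All log-ratios are
# base 2. Samples missing a value for one gene of a pair are dropped
# pairwise, not listwise.

as_quantity_matrix <- function(q) {
  if (inherits(q, "ct_matrix")) q <- relative_quantities(q)
  q <- as.matrix(q)
  if (is.null(rownames(q))) stop("quantity matrix needs gene rownames", call. = FALSE)
  q
}

#' Pairwise variation between two genes
#'
#' The sample standard deviation (n-1) of `log2(Q_g / Q_k)` across samples:
#' the building block of the geNorm M value. Symmetric in its arguments and
#' invariant to rescaling either gene's quantities by a constant.
#'
#' @param q Quantity matrix from [relative_quantities()] (a `ct_matrix` is
#'   converted automatically).
#' @param g,k Gene ids (or row indices); must differ.
#' @return The pairwise variation V_gk (log2 units).
#' @export
pairwise_gene_variation <- function(q, g, k) {
  q <- as_quantity_matrix(q)
  if (identical(g, k)) stop("`g` and `k` must be different genes", call. = FALSE)
  r <- log2(q[g, ]) - log2(q[k, ])
  r <- r[is.finite(r)]
  if (length(r) < 2L) stop("fewer than 2 common non-missing samples for the pair", call. = FALSE)
  stats::sd(r)
}

# full symmetric matrix of pairwise log2-ratio SDs
pairwise_sd_matrix <- function(logq) {
  G <- nrow(logq)
  V <- matrix(0, G, G, dimnames = list(rownames(logq), rownames(logq)))
  for (g in seq_len(G - 1L)) {
    for (k in seq.int(g + 1L, G)) {
      r <- logq[g, ] - logq[k, ]
      r <- r[is.finite(r)]
      if (length(r) < 2L) {
        stop(sprintf("fewer than 2 common samples for pair %s / %s",
                     rownames(logq)[g], rownames(logq)[k]), call. = FALSE)
      }
      V[g, k] <- V[k, g] <- stats::sd(r)
    }
  }
  V
}

#' geNorm expression-stability values M
#'
#' `M_g` is the arithmetic mean of the pairwise variations `V_gk` of gene g
#' against every other gene in the subset. Higher M = less stable. With
#' exactly two genes both M values equal their mutual V.
#'
#' @inheritParams pairwise_gene_variation
#' @param genes Subset of gene ids (default all rows).
#' @return Named numeric vector of M values.
#' @export
m_values <- function(q, genes = NULL) {
  q <- as_quantity_matrix(q)
  if (!is.null(genes)) q <- q[genes, , drop = FALSE]
  if (nrow(q) < 2L) stop("need >= 2 genes to compute M", call. = FALSE)
  V <- pairwise_sd_matrix(log2(q))
  rowSums(V) / (nrow(V) - 1L)
}

#' geNorm stepwise-exclusion ranking
#'
#' Repeatedly computes M over the remaining genes and removes the gene with
#' the highest M until two genes remain; those two are the best pair and are
#' reported with their mutual V as a shared M. Ties at the maximum M are
#' broken by excluding the lexicographically last gene id (recorded in the
#' result). Genes whose final M exceeds `m_cutoff` are flagged unusable.
#'
#' @inheritParams pairwise_gene_variation
#' @param m_cutoff Usability cutoff on M (default 1.5, the conventional
#'   geNorm threshold).
#' @return List of class `genorm_result`: `m_final` (per-gene M at its
#'   exclusion step; the best pair shares one value), `exclusion_order`,
#'   `best_pair`, `best_pair_m`, `m_trace` (per-step M vectors), `ranks`
#'   (1 = most stable; the pair is tied at 1.5), `unusable`, `tie_breaks`.
#' @export
genorm_ranking <- function(q, m_cutoff = 1.5) {
  q <- as_quantity_matrix(q)
  if (nrow(q) < 3L) stop("need >= 3 genes for stepwise exclusion", call. = FALSE)
  remaining <- rownames(q)
  exclusion_order <- character(0)
  m_final <- stats::setNames(numeric(nrow(q)), rownames(q))
  m_trace <- list()
  tie_breaks <- character(0)
  while (length(remaining) > 2L) {
    M <- m_values(q, remaining)
    m_trace[[length(m_trace) + 1L]] <- M
    worst_set <- names(M)[M == max(M)]
    worst <- sort(worst_set)[length(worst_set)]  # lexicographically last
    if (length(worst_set) > 1L) tie_breaks <- c(tie_breaks, worst)
    m_final[worst] <- M[worst]
    exclusion_order <- c(exclusion_order, worst)
    remaining <- setdiff(remaining, worst)
  }
  best_pair <- sort(remaining)
  pair_m <- pairwise_gene_variation(q, best_pair[1L], best_pair[2L])
  m_final[best_pair] <- pair_m
  m_trace[[length(m_trace) + 1L]] <- stats::setNames(rep(pair_m, 2L), best_pair)
  # rank: best pair tied at 1.5, then reverse order of exclusion
  ranks <- stats::setNames(numeric(length(m_final)), names(m_final))
  ranks[best_pair] <- 1.5
  if (length(exclusion_order)) {
    ranks[rev(exclusion_order)] <- seq.int(3L, length.out = length(exclusion_order))
  }
  structure(list(m_final = m_final, exclusion_order = exclusion_order,
                 best_pair = best_pair, best_pair_m = pair_m,
                 m_trace = m_trace, ranks = ranks,
                 unusable = names(m_final)[m_final > m_cutoff],
                 m_cutoff = m_cutoff, tie_breaks = tie_breaks),
            class = "genorm_result")
}

#' Normalization factor over a reference-gene subset
#'
#' Per-sample geometric mean of the relative quantities of the chosen
#' genes. A sample missing any gene of the subset gets a missing NF.
#'
#' @inheritParams pairwise_gene_variation
#' @param genes Non-empty subset of gene ids.
#' @return Named numeric vector of per-sample normalization factors.
#' @export
normalization_factor <- function(q, genes) {
  q <- as_quantity_matrix(q)
  if (length(genes) == 0L) stop("reference subset is empty", call. = FALSE)
  exp(colMeans(log(q[genes, , drop = FALSE])))
}

#' geNorm pairwise variation V(n/n+1) and optimal gene number
#'
#' For n = 2 .. G-1, V(n/n+1) is the sample SD across samples of
#' `log2(NF_n / NF_(n+1))`, where NF_n is the normalization factor built
#' from the n most stable genes of the geNorm ranking. The optimal number
#' of reference genes is the smallest n with V(n/n+1) below `threshold`;
#' when the threshold is never met, `optimal_n` is G and `threshold_met`
#' is `FALSE`.
#'
#' @inheritParams pairwise_gene_variation
#' @param ranking A [genorm_ranking()] result on the same genes; computed
#'   when `NULL`.
#' @param threshold Pairwise-variation cutoff (default 0.15).
#' @return List: `v` (named vector `V2/3`, `V3/4`, ...), `optimal_n`,
#'   `threshold_met`, `recommended` (the optimal top-n gene set), `order`
#'   (stability-ordered gene ids).
#' @export
pairwise_v <- function(q, ranking = NULL, threshold = 0.15) {
  q <- as_quantity_matrix(q)
  if (nrow(q) < 3L) stop("need >= 3 genes for pairwise variation", call. = FALSE)
  if (is.null(ranking)) ranking <- genorm_ranking(q)
  stability_order <- c(ranking$best_pair, rev(ranking$exclusion_order))
  G <- length(stability_order)
  v <- stats::setNames(numeric(G - 2L),
                       sprintf("V%d/%d", 2:(G - 1L), 3:G))
  for (n in 2:(G - 1L)) {
    nf_n <- normalization_factor(q, stability_order[1:n])
    nf_n1 <- normalization_factor(q, stability_order[1:(n + 1L)])
    r <- log2(nf_n / nf_n1)
    v[n - 1L] <- stats::sd(r[is.finite(r)])
  }
  hit <- which(v < threshold)
  threshold_met <- length(hit) > 0L
  optimal_n <- if (threshold_met) as.integer(hit[[1L]]) + 1L else G
  list(v = v, optimal_n = optimal_n, threshold_met = threshold_met,
       recommended = stability_order[seq_len(optimal_n)],
       order = stability_order, threshold = threshold)
}
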