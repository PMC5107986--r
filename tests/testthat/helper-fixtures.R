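# Small in-code fixtures shared across the suite.

# ct_matrix from a genes x samples matrix of Ct values
mk_ct <- function(m, efficiencies = 2, replicates = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  ct_matrix(m, efficiencies = efficiencies, replicates = replicates)
}

# the three-gene hand instance: log2 quantities A = (0,1,2), B = (0,1,2),
# C = (0,0,0)
abc_q <- function() {
  matrix(2^c(0, 1, 2,
             0, 1, 2,
             0, 0, 0),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
}

# random positive quantity matrix derived from random Ct rows at E = 2
rand_q <- function(seed, G = 5, n = 8) {
  set.seed(seed)
  ct <- matrix(stats::runif(G * n, 18, 28), G, n,
               dimnames = list(sprintf("g%02d", 1:G), sprintf("s%02d", 1:n)))
  relative_quantities(mk_ct(ct))
}

rand_ct <- function(seed, G = 5, n = 8) {
  set.seed(seed)
  mk_ct(matrix(stats::runif(G * n, 18, 28), G, n,
               dimnames = list(sprintf("g%02d", 1:G), sprintf("s%02d", 1:n))))
}

# brute-force geNorm M: literal double loop over pairs
brute_force_m <- function(q) {
  lq <- log2(q)
  G <- nrow(lq)
  M <- numeric(G)
  for (g in seq_len(G)) {
    vs <- c()
    for (k in seq_len(G)) {
      if (k != g) vs <- c(vs, stats::sd(lq[g, ] - lq[k, ]))
    }
    M[g] <- mean(vs)
  }
  stats::setNames(M, rownames(q))
}
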