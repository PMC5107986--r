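test_that("two genes in one group come out tied, per hand example", {
  q <- 2^rbind(A = c(10, 10), B = c(10, 11))
  colnames(q) <- c("s1", "s2")
  res <- normfinder_stability(q)
  # centred residuals are +/-0.25 for both genes: identical variance,
  # identical (floored) adjusted variance, tied stability
  expect_equal(res$stability[["A"]], res$stability[["B"]])
  expect_equal(unname(rank_genes(res$stability)), c(1.5, 1.5))
})

test_that("identical genes land on the variance floor with zero group effects", {
  q <- matrix(2^c(3, 5, 4, 6), 4, 4, byrow = TRUE,
              dimnames = list(letters[1:4], sprintf("s%d", 1:4)))
  meta <- sample_metadata(data.frame(sample_id = sprintf("s%d", 1:4),
                                     treatment = rep(c("control", "drought"), 2)))
  res <- normfinder_stability(q, meta, "treatment")
  expect_true(all(res$sigma2 == 1e-8))
  expect_true(all(res$d == 0))
  expect_equal(max(res$stability) - min(res$stability), 0)
})

test_that("group-centring constraint holds: per-group d sums to zero", {
  sim <- simulate_ct_dataset(simulation_config(), 5)
  res <- normfinder_stability(relative_quantities(sim$ct), sim$meta, "treatment")
  d_raw <- res$d  # shrunken, but shrinkage is per-gene so check near-zero sums
  expect_lt(max(abs(colSums(res$d))), 0.05)
})

test_that("adding a per-sample constant to all genes changes nothing", {
  q <- rand_q(17, G = 5, n = 10)
  meta <- sample_metadata(data.frame(sample_id = colnames(q),
                                     treatment = rep(c("c", "d"), 5)))
  base <- normfinder_stability(q, meta, "treatment")
  loading <- 2^stats::runif(ncol(q), -2, 2)
  shifted <- sweep(q, 2, loading, "*")
  res <- normfinder_stability(shifted, meta, "treatment")
  expect_equal(res$stability, base$stability, tolerance = 1e-12)
})

test_that("a gene with an injected group shift is ranked least stable", {
  delta <- matrix(0, 6, 2, dimnames = list(NULL, c("control", "drought")))
  delta[1, ] <- c(0, 1)  # gene g01 moves one log2 unit under drought
  cfg <- simulation_config(genes = sprintf("g%02d", 1:6),
                           noise_sd = rep(0.1, 6), group_effects = delta)
  hits <- 0L
  for (seed in 1:50) {
    sim <- simulate_ct_dataset(cfg, seed)
    res <- normfinder_stability(relative_quantities(sim$ct), sim$meta, "treatment")
    hits <- hits + (names(which.max(res$stability)) == "g01")
  }
  expect_gte(hits, 49L)
})

test_that("single-group mode flags the noisiest gene and tracks true noise", {
  # with very few genes the per-sample centring mixes everybody's noise
  # into everybody's residuals and the bias adjustment floors the quiet
  # genes, so the robust single-gene claim is "noisiest ranked last"
  design <- sample_metadata(data.frame(sample_id = sprintf("s%02d", 1:50),
                                       treatment = "control"))
  cfg <- simulation_config(genes = c("lo", "mid", "hi"),
                           noise_sd = c(0.05, 0.2, 0.8),
                           design = design, loading_sd = 0.3)
  hits <- 0L
  for (seed in 1:50) {
    sim <- simulate_ct_dataset(cfg, seed)
    res <- normfinder_single_group(relative_quantities(sim$ct))
    hits <- hits + (names(which.max(res$stability)) == "hi")
  }
  expect_gte(hits, 49L)
  # with a richer gene panel the full ordering is recoverable: Spearman
  # correlation with the true noise SDs averages >= 0.9
  cfg10 <- simulation_config(genes = sprintf("g%02d", 1:10),
                             noise_sd = seq(0.05, 1.0, length.out = 10),
                             design = design, loading_sd = 0.3)
  rho <- vapply(1:30, function(seed) {
    sim <- simulate_ct_dataset(cfg10, seed)
    res <- normfinder_single_group(relative_quantities(sim$ct))
    stats::cor(res$stability, seq(0.05, 1.0, length.out = 10),
               method = "spearman")
  }, numeric(1))
  expect_gte(mean(rho), 0.9)
})

test_that("single-group mode equals the grouped model with one merged group", {
  q <- rand_q(9, G = 5, n = 12)
  meta <- sample_metadata(data.frame(sample_id = colnames(q), batch = "one"))
  merged <- normfinder_stability(q, meta, "batch")
  single <- normfinder_single_group(q)
  expect_equal(single$stability, merged$stability, tolerance = 1e-12)
  expect_true(all(single$d == 0))
})

test_that("preconditions are enforced", {
  q <- rand_q(2, G = 4, n = 6)
  meta <- sample_metadata(data.frame(
    sample_id = colnames(q),
    treatment = c("a", "a", "a", "a", "a", "b")))
  expect_error(normfinder_stability(q, meta, "treatment"), ">= 2 samples")
  expect_error(normfinder_stability(q, meta, "nope"), "nope")
  expect_error(normfinder_single_group(q[, 1:2]), ">= 3 samples")
  expect_error(normfinder_single_group(q[1:2, ]), ">= 3 genes")
})
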