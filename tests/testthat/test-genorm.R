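test_that("pairwise variation matches hand computations and is symmetric", {
  q <- abc_q()
  expect_equal(pairwise_gene_variation(q, "A", "B"), 0)
  expect_equal(pairwise_gene_variation(q, "A", "C"), 1)  # sd of (0,1,2)
  expect_equal(pairwise_gene_variation(q, "C", "A"),
               pairwise_gene_variation(q, "A", "C"))
  # scaling one gene's quantities leaves V unchanged
  q2 <- q; q2["A", ] <- q2["A", ] * 7
  expect_equal(pairwise_gene_variation(q2, "A", "C"), 1, tolerance = 1e-12)
  expect_error(pairwise_gene_variation(q, "A", "A"), "different")
})

test_that("M values equal the mean pairwise variation, per hand example", {
  expect_equal(m_values(abc_q()), c(A = 0.5, B = 0.5, C = 1.0))
  same <- matrix(2^c(0, 1, 2), 3, 3, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  expect_equal(unname(m_values(same)), rep(0, 3))
  # sample permutation leaves M unchanged
  q <- rand_q(21)
  expect_equal(m_values(q), m_values(q[, sample(ncol(q))]))
  expect_error(m_values(abc_q()[1, , drop = FALSE]), ">= 2 genes")
})

test_that("M matches a brute-force double loop on random instances", {
  for (seed in 1:100) {
    q <- rand_q(seed, G = sample(3:8, 1), n = sample(4:10, 1))
    expect_equal(m_values(q), brute_force_m(q), tolerance = 1e-12)
  }
})

test_that("stepwise exclusion ranks the hand instance correctly", {
  res <- genorm_ranking(abc_q())
  expect_identical(res$exclusion_order, "C")
  expect_identical(res$best_pair, c("A", "B"))
  expect_equal(res$best_pair_m, 0)
  expect_equal(res$m_final, c(A = 0, B = 0, C = 1.0))
  expect_equal(res$ranks, c(A = 1.5, B = 1.5, C = 3))
})

test_that("ties and identical genes resolve deterministically", {
  four <- matrix(1, 4, 3, dimnames = list(c("d", "b", "a", "c"),
                                          c("s1", "s2", "s3")))
  r1 <- genorm_ranking(four)
  r2 <- genorm_ranking(four[sample(4), ])
  expect_identical(r1$exclusion_order, c("d", "c"))  # lexicographically last first
  expect_identical(r1$exclusion_order, r2$exclusion_order)
  expect_equal(unname(r1$m_final), rep(0, 4))
  expect_true(all(c("d", "c") %in% r1$tie_breaks))
})

test_that("a high-noise gene is excluded first in almost every simulation", {
  cfg <- simulation_config(genes = sprintf("g%02d", 1:6),
                           noise_sd = c(1.0, rep(0.05, 5)))
  hits <- 0L
  for (seed in 1:50) {
    sim <- simulate_ct_dataset(cfg, seed)
    hits <- hits + (genorm_ranking(relative_quantities(sim$ct))$exclusion_order[1] == "g01")
  }
  expect_gte(hits, 49L)
})

test_that("normalization factors are per-sample geometric means", {
  q <- abc_q()
  expect_equal(normalization_factor(q, "A"), q["A", ])
  two <- rbind(x = c(1, 2, 4), y = c(1, 2, 4))
  colnames(two) <- c("s1", "s2", "s3")
  expect_equal(unname(normalization_factor(two, c("x", "y"))), c(1, 2, 4))
  expect_equal(unname(normalization_factor(q, c("A", "C"))), 2^c(0, 0.5, 1))
  # missing quantity for a subset gene makes that sample's NF missing
  qm <- q; qm["A", 2] <- NA
  expect_true(is.na(normalization_factor(qm, c("A", "B"))["s2"]))
  expect_error(normalization_factor(q, character(0)), "empty")
})

test_that("pairwise variation series matches the hand instance", {
  q <- abc_q()
  pv <- pairwise_v(q)
  expect_equal(unname(pv$v["V2/3"]), 1 / 3, tolerance = 1e-12)
  expect_false(pv$threshold_met)
  expect_equal(pv$optimal_n, 3)
  # identical genes: V = 0 everywhere, two genes suffice
  same <- matrix(2^c(0, 1, 2), 4, 3, byrow = TRUE,
                 dimnames = list(letters[1:4], c("s1", "s2", "s3")))
  pv0 <- pairwise_v(same)
  expect_equal(unname(pv0$v), rep(0, 2))
  expect_true(pv0$threshold_met)
  expect_equal(pv0$optimal_n, 2)
})

test_that("an appended duplicate of the most stable gene joins the best pair", {
  # the duplicate has zero pairwise variation with its twin, so the two
  # become the best pair and V(2/3) collapses to a single pairwise SD / 3
  for (seed in 1:20) {
    q <- rand_q(seed, G = 5, n = 10)
    top <- pairwise_v(q)$order[1]
    qdup <- rbind(q, dup00 = q[top, ])
    pvdup <- pairwise_v(qdup)
    expect_setequal(pvdup$order[1:2], c(top, "dup00"))
    third <- pvdup$order[3]
    expect_equal(pvdup$v[["V2/3"]],
                 pairwise_gene_variation(qdup, top, third) / 3,
                 tolerance = 1e-12)
  }
})

test_that("exclusion order is invariant to gene relabeling and sample order", {
  q <- rand_q(33, G = 6, n = 9)
  r1 <- genorm_ranking(q)
  r2 <- genorm_ranking(q[sample(nrow(q)), sample(ncol(q))])
  expect_identical(r1$exclusion_order, r2$exclusion_order)
  expect_identical(r1$best_pair, r2$best_pair)
})
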