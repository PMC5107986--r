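test_that("normalized expression follows the efficiency-corrected ratio", {
  # E = 2 everywhere; calibrator s1. Target rises by 2 cycles in s2
  # (fold 2^-2), reference by 1 cycle (fold 2^-1): ratio 0.5
  m <- rbind(tgt = c(20, 22), ref = c(20, 21))
  colnames(m) <- c("s1", "s2")
  ne <- normalized_expression(mk_ct(m), "tgt", "ref", calibrator = "s1")
  expect_equal(unname(ne$values), c(1, 0.5))
  # a target identical to its reference normalizes to 1 everywhere
  m2 <- rbind(tgt = c(20, 23, 18), refA = c(20, 23, 18), refB = c(21, 24, 19))
  colnames(m2) <- sprintf("s%d", 1:3)
  ne2 <- normalized_expression(mk_ct(m2), "tgt", "refA", calibrator = "s1")
  expect_equal(unname(ne2$values), rep(1, 3))
  expect_error(normalized_expression(mk_ct(m2), "tgt", c("tgt", "refA")),
               "cannot be one of the references")
})

test_that("duplicate references collapse and pairs factor as geometric means", {
  ct <- rand_ct(31, G = 4, n = 8)
  genes <- rownames(ct$values)
  tgt <- genes[1]
  # two references with identical Ct rows act like one of them
  ct2 <- ct
  ct2$values <- rbind(ct$values, copy01 = ct$values[genes[2], ])
  ct2$efficiencies <- c(ct$efficiencies, copy01 = ct$efficiencies[[genes[2]]])
  a <- normalized_expression(ct2, tgt, genes[2], calibrator = "s01")
  b <- normalized_expression(ct2, tgt, c(genes[2], "copy01"), calibrator = "s01")
  expect_equal(a$values, b$values, tolerance = 1e-12)
  # pair {A, B} = geometric mean of single-reference normalizations
  pa <- normalized_expression(ct, tgt, genes[3], calibrator = "s01")
  pb <- normalized_expression(ct, tgt, genes[4], calibrator = "s01")
  pab <- normalized_expression(ct, tgt, genes[3:4], calibrator = "s01")
  expect_equal(pab$values, sqrt(pa$values * pb$values), tolerance = 1e-12)
})

test_that("a perfectly constant reference reproduces raw fold changes", {
  m <- rbind(tgt = c(20, 21, 19), flat = c(22, 22, 22))
  colnames(m) <- sprintf("s%d", 1:3)
  ne <- normalized_expression(mk_ct(m), "tgt", "flat", calibrator = "s1")
  expect_equal(unname(ne$values), 2^(20 - c(20, 21, 19)))
})

test_that("one-way ANOVA matches the hand table and degenerate contracts", {
  a <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("x", "y"), each = 3))
  expect_equal(a$f, 13.5)
  expect_equal(a$p, stats::pf(13.5, 1, 4, lower.tail = FALSE))
  same <- one_way_anova(rep(2, 6), rep(c("x", "y"), each = 3))
  expect_equal(same$f, 0)
  expect_equal(same$p, 1)
  expect_error(one_way_anova(1:3, c("x", "x", "y")), "single value")
  expect_error(one_way_anova(1:3, c("x", "x", "x")), ">= 2 groups")
})

test_that("label shuffling yields approximately uniform p-values", {
  set.seed(1234)
  p <- replicate(400, {
    y <- stats::rnorm(12)
    one_way_anova(y, sample(rep(c("a", "b"), 6)))$p
  })
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("identical reference sets are never flagged", {
  sim <- simulate_ct_dataset(simulation_config(), 11)
  cmp <- compare_normalizers(sim$ct, "gene10",
                             list(a = c("gene01", "gene02"),
                                  b = c("gene01", "gene02")))
  expect_true(all(cmp$tests$f < 1e-9))  # zero between-set signal
  expect_true(all(cmp$tests$p > 0.999))
  expect_true(all(!cmp$tests$flagged))
  expect_equal(nrow(cmp$tests), 14)
})

test_that("a reference carrying a treatment effect gets drought samples flagged", {
  delta <- matrix(0, 6, 2, dimnames = list(NULL, c("control", "drought")))
  delta[3, ] <- c(0, 1)  # g03 is the bad reference
  cfg <- simulation_config(genes = sprintf("g%02d", 1:6),
                           noise_sd = rep(0, 6), group_effects = delta,
                           tech_rep_sd = 0.15)
  hits <- 0L
  for (seed in 1:50) {
    sim <- simulate_ct_dataset(cfg, seed)
    cmp <- compare_normalizers(sim$ct, "g06",
                               list(good = c("g01", "g02"), bad = "g03"),
                               grouping = "treatment", meta = sim$meta)
    hits <- hits + cmp$tests$flagged[cmp$tests$group == "drought"]
  }
  expect_gte(hits, 48L)  # >= 95%
})

test_that("equally stable reference sets stay below the nominal error rate", {
  cfg <- simulation_config(genes = sprintf("g%02d", 1:6),
                           noise_sd = rep(0, 6), tech_rep_sd = 0.15)
  n_flag <- 0L; n_tot <- 0L
  for (seed in 1:50) {
    sim <- simulate_ct_dataset(cfg, seed)
    cmp <- compare_normalizers(sim$ct, "g06",
                               list(a = c("g01", "g02"), b = c("g03", "g04")))
    n_flag <- n_flag + sum(cmp$tests$flagged)
    n_tot <- n_tot + nrow(cmp$tests)
  }
  expect_lte(n_flag / n_tot, 0.05)
})
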