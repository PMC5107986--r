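test_that("the default design matches the 14-sample layout", {
  d <- goji_design()
  expect_equal(nrow(d), 14)
  expect_setequal(d$organ, c("leaf", "flower", "fruit"))
  expect_setequal(d$treatment, c("control", "drought"))
  expect_true(all(c("C-L3", "D-G7", "C-F", "D-F") %in% d$sample_id))
})

test_that("generation is deterministic given (config, seed)", {
  cfg <- simulation_config()
  a <- simulate_ct_dataset(cfg, 123)
  b <- simulate_ct_dataset(cfg, 123)
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$ct$replicates, b$ct$replicates)
  c1 <- simulate_fragment_counts(cfg, 9)
  c2 <- simulate_fragment_counts(cfg, 9)
  expect_identical(unclass(c1$expr), unclass(c2$expr))
  expect_false(identical(a$ct$values, simulate_ct_dataset(cfg, 124)$ct$values))
})

test_that("a noise-free configuration gives constant rows and zero scores", {
  cfg <- simulation_config(noise_sd = 0, loading_sd = 0, tech_rep_sd = 0)
  sim <- simulate_ct_dataset(cfg, 1)
  expect_equal(unname(apply(sim$ct$values, 1, stats::sd)), rep(0, 10))
  expect_equal(unname(m_values(relative_quantities(sim$ct))), rep(0, 10))
  expect_equal(unname(delta_ct_stability(sim$ct)$scores), rep(0, 10))
})

test_that("loading noise cancels in ratio statistics but not in BestKeeper", {
  cfg0 <- simulation_config(loading_sd = 0)
  cfg1 <- simulation_config(loading_sd = 1.0)
  s0 <- simulate_ct_dataset(cfg0, 77)
  s1 <- simulate_ct_dataset(cfg1, 77)  # same substreams, only loading differs
  q0 <- relative_quantities(s0$ct)
  q1 <- relative_quantities(s1$ct)
  expect_equal(m_values(q0), m_values(q1), tolerance = 1e-9)
  expect_equal(delta_ct_stability(s0$ct)$scores,
               delta_ct_stability(s1$ct)$scores, tolerance = 1e-9)
  expect_equal(normfinder_stability(q0, s0$meta, "treatment")$stability,
               normfinder_stability(q1, s1$meta, "treatment")$stability,
               tolerance = 1e-9)
  bk0 <- bestkeeper_descriptives(s0$ct)
  bk1 <- bestkeeper_descriptives(s1$ct)
  expect_true(mean(bk1$sd) > mean(bk0$sd))
})

test_that("Poisson counts at high depth pass the screen, overdispersed fail", {
  cfg <- simulation_config(genes = "t1", fragment_mean = 10000,
                           fragment_dispersion = 0, loading_sd = 0)
  low_cv <- vapply(1:40, function(seed) {
    abundance_stats(simulate_fragment_counts(cfg, seed)$expr)$cv
  }, numeric(1))
  expect_gte(mean(low_cv < 0.05), 0.95)  # Poisson CV ~ 1/sqrt(10000)
  over <- simulation_config(genes = "t1", fragment_mean = 10000,
                            fragment_dispersion = 1, loading_sd = 0)
  hi_cv <- vapply(1:40, function(seed) {
    abundance_stats(simulate_fragment_counts(over, seed)$expr)$cv
  }, numeric(1))
  expect_gt(mean(hi_cv > 0.3), 0.8)  # NB with size 1: CV ~ 1
})

test_that("noisy dilution series still centre on the true efficiency", {
  fits <- vapply(1:200, function(seed) {
    ser <- simulate_dilution_series(1.9, noise_sd = 0.1, seed = seed)
    fit_standard_curve(ser)$efficiency_fold
  }, numeric(1))
  expect_lt(abs(mean(fits) - 1.9) / 1.9, 0.01)
})

test_that("invalid configurations fail before any sampling", {
  expect_error(simulation_config(noise_sd = -1), "nonnegative")
  expect_error(simulation_config(efficiencies = 0.9), "outside")
  expect_error(simulation_config(fragment_mean = 0), "positive")
  expect_error(simulation_config(group_by = "nope"), "group_by")
  expect_error(simulate_dilution_series(1.0), "outside")
})

test_that("the truth ordering puts low-noise genes first", {
  cfg <- simulation_config()
  sim <- simulate_ct_dataset(cfg, 3)
  expect_identical(sim$truth$stability_order[1:2], c("gene01", "gene02"))
  # a strong group effect demotes a quiet gene in the truth ordering
  delta <- matrix(0, 10, 2, dimnames = list(NULL, c("control", "drought")))
  delta[1, "drought"] <- 3
  cfg2 <- simulation_config(group_effects = delta)
  sim2 <- simulate_ct_dataset(cfg2, 3)
  expect_false(sim2$truth$stability_order[1] == "gene01")
})
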