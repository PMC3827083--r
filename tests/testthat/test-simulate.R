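test_that("identical seeds give bit-identical simulations", {
  cfg <- simulation_config(n_mirnas = 40, seed = 3L)
  s1 <- simulate_two_platforms(cfg)
  s2 <- simulate_two_platforms(cfg)
  expect_identical(s1$platform_a$values, s2$platform_a$values)
  expect_identical(s1$platform_b$values, s2$platform_b$values)
  expect_identical(s1$truth, s2$truth)
  q1 <- simulate_qpcr(cfg, s1$truth)
  q2 <- simulate_qpcr(cfg, s2$truth)
  expect_identical(q1$ct, q2$ct)
  # a different seed changes the draw
  s3 <- simulate_two_platforms(simulation_config(n_mirnas = 40, seed = 4L))
  expect_false(identical(s1$platform_a$values, s3$platform_a$values))
})

test_that("a noiseless null simulation has exactly zero log2 ratios", {
  cfg <- simulation_config(n_mirnas = 30, noise_sd = 0, platform_bias = NULL,
                           seed = 5L)
  sim <- simulate_two_platforms(cfg)
  de <- de_table(sim$platform_a, c("M_cRaf", "M_WT"))
  expect_equal(de$log2_ratio, rep(0, 30))
  expect_equal(de$p, rep(1, 30))
})

test_that("planted effects are recovered within three standard errors", {
  planted <- data.frame(mirna = sprintf("sim-miR-%04d", 1:10), log2fc = 2)
  cfg <- simulation_config(n_mirnas = 200, noise_sd = 0.3,
                           planted_effects = planted, platform_bias = NULL,
                           seed = 6L)
  sim <- simulate_two_platforms(cfg)
  x <- log2(sim$platform_a$values)
  case <- sim$platform_a$samples$group == "M_cRaf"
  ctrl <- sim$platform_a$samples$group == "M_WT"
  se <- 0.3 * sqrt(2 / 6)
  for (m in planted$mirna) {
    est <- mean(x[m, case]) - mean(x[m, ctrl])
    expect_lt(abs(est - 2), 3 * se)
  }
})

test_that("gender-restricted effects only touch the matching gender", {
  planted <- data.frame(mirna = "sim-miR-0001", log2fc = 2, gender = "M")
  cfg <- simulation_config(n_mirnas = 20, noise_sd = 0, platform_bias = NULL,
                           planted_effects = planted, seed = 7L)
  sim <- simulate_two_platforms(cfg)
  de_m <- de_table(sim$platform_a, c("M_cRaf", "M_WT"))
  de_f <- de_table(sim$platform_a, c("F_cRaf", "F_WT"))
  expect_equal(de_m$log2_ratio[de_m$mirna == "sim-miR-0001"], 2)
  expect_equal(de_f$log2_ratio[de_f$mirna == "sim-miR-0001"], 0)
  expect_equal(sim$truth$log2fc_M[1], 2)
  expect_equal(sim$truth$log2fc_F[1], 0)
})

test_that("planting on an unknown miRNA is an error", {
  cfg <- simulation_config(n_mirnas = 10, seed = 1L,
                           planted_effects = data.frame(mirna = "nope", log2fc = 2))
  expect_error(simulate_two_platforms(cfg), "unknown miRNA: nope")
})

test_that("the spot-level platform has the configured layout and negatives", {
  cfg <- simulation_config(n_mirnas = 50, n_replicate_spots = 20,
                           negative_rate = 0.05, seed = 8L)
  sim <- simulate_two_platforms(cfg)
  expect_equal(nrow(sim$platform_b$values), 50 * 20)
  expect_equal(table(sim$platform_b$feature)[["sim-miR-0001"]], 20L)
  neg_frac <- mean(sim$platform_b$values < 0)
  expect_gt(neg_frac, 0.02)
  expect_lt(neg_frac, 0.10)
  # no negatives when the rate is zero
  sim0 <- simulate_two_platforms(simulation_config(n_mirnas = 20,
                                                   negative_rate = 0, seed = 8L))
  expect_true(all(sim0$platform_b$values >= 0))
})

test_that("noiseless qPCR recovers planted fold changes exactly", {
  planted <- data.frame(mirna = c("sim-miR-0001", "sim-miR-0002"),
                        log2fc = c(2, 0))
  cfg <- simulation_config(n_mirnas = 10, noise_sd = 0, qpcr_noise_sd = 0,
                           platform_bias = NULL, planted_effects = planted,
                           seed = 9L)
  sim <- simulate_two_platforms(cfg)
  ct <- simulate_qpcr(cfg, sim$truth)
  res <- ddct_fold_change(ct, c("M_cRaf", "M_WT"))
  expect_equal(res$ddct[res$assay == "sim-miR-0001"], -2)
  expect_equal(res$log2fc[res$assay == "sim-miR-0001"], 2)
  expect_equal(res$fold_change[res$assay == "sim-miR-0001"], 4)
  expect_equal(res$log2fc[res$assay == "sim-miR-0002"], 0)
  expect_equal(res$log2fc[res$assay == "U6"], 0)
})

test_that("noisy qPCR recovers planted fold changes within three SE", {
  planted <- data.frame(mirna = "sim-miR-0001", log2fc = 2)
  cfg <- simulation_config(n_mirnas = 10, noise_sd = 0, qpcr_noise_sd = 0.2,
                           platform_bias = NULL, planted_effects = planted,
                           seed = 10L)
  sim <- simulate_two_platforms(cfg)
  ct <- simulate_qpcr(cfg, sim$truth)
  res <- ddct_fold_change(ct, c("F_cRaf", "F_WT"))
  # dCt variance = 2 * 0.2^2 (target + reference noise), n = 6 per group
  se <- sqrt(2 * (2 * 0.2^2) / 6)
  expect_lt(abs(res$log2fc[res$assay == "sim-miR-0001"] - 2), 3 * se)
})

test_that("low-GC miRNAs are preferentially lost on the GC-biased platform", {
  cfg <- simulation_config(n_mirnas = 2000, seed = 11L)
  sim <- simulate_two_platforms(cfg)
  tr <- sim$truth
  b_only <- tr$detectable_b & !tr$detectable_a
  common <- tr$detectable_a & tr$detectable_b
  expect_gt(sum(b_only), 30)
  tt <- t.test(tr$gc[b_only], tr$gc[common], alternative = "less")
  expect_lt(tt$p.value, 0.001)
})
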