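test_that("welch_t matches the closed form and its corner cases", {
  w <- welch_t(c(10, 12, 14), c(20, 22, 24))
  expect_equal(w$t, -10 / sqrt(4 / 3 + 4 / 3))
  expect_equal(w$t, -6.123724, tolerance = 1e-6)
  expect_equal(w$df, 4)
  expect_equal(w$p, 0.003602, tolerance = 1e-4)

  same <- welch_t(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  degen <- welch_t(c(2, 2), c(1, 1))
  expect_equal(degen$t, Inf)
  expect_equal(degen$p, 0)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("welch_t agrees with stats::t.test on random instances", {
  set.seed(31)
  for (i in 1:100) {
    a <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    ref <- t.test(a, b)
    w <- welch_t(a, b)
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("swapping groups negates t and the log2 ratio, preserving p", {
  set.seed(32)
  a <- rnorm(6, 5); b <- rnorm(6, 7)
  w1 <- welch_t(a, b); w2 <- welch_t(b, a)
  expect_equal(w1$t, -w2$t)
  expect_equal(w1$p, w2$p)
  vals <- matrix(rlnorm(10 * 12, 5, 1), 10, 12,
                 dimnames = list(sprintf("m%d", 1:10), sprintf("s%d", 1:12)))
  meta <- data.frame(sample = colnames(vals), group = rep(c("case", "ctrl"), each = 6))
  m <- expr_matrix(vals, meta)
  d1 <- de_table(m, c("case", "ctrl"))
  d2 <- de_table(m, c("ctrl", "case"))
  expect_equal(d1$log2_ratio, -d2$log2_ratio)
  expect_equal(d1$p, d2$p)
})

test_that("de_table is invariant to sample order and errors on empty groups", {
  set.seed(33)
  vals <- matrix(rlnorm(8 * 12, 5, 1), 8, 12,
                 dimnames = list(sprintf("m%d", 1:8), sprintf("s%d", 1:12)))
  meta <- data.frame(sample = colnames(vals), group = rep(c("case", "ctrl"), 6))
  m <- expr_matrix(vals, meta)
  perm <- sample(ncol(vals))
  mp <- expr_matrix(vals[, perm], meta[perm, ])
  expect_equal(de_table(m, c("case", "ctrl")), de_table(mp, c("case", "ctrl")))
  expect_error(de_table(m, c("case", "missing_group")), "no samples")
})

test_that("the compound filter applies its three gates independently", {
  de <- data.frame(
    mirna = paste0("m", 1:5),
    t = 0, df = 10,
    #              pass   pass   p-fail fc-fail mean-fail
    p          = c(0.001, 0.010, 0.500, 0.001, 0.001),
    log2_ratio = c(2.0,   -1.8,  2.5,   1.0,   3.0),
    mean_all   = c(100,   90,    80,    70,    1),
    stringsAsFactors = FALSE)
  de$p_adj <- p.adjust(de$p, "BH")
  class(de) <- c("de_result", class(de))
  # 50th percentile of mean_all (type 7) is 80: m1, m2 pass all gates
  sig <- filter_significant(de)
  expect_equal(sig$mirna, c("m1", "m2"))
  expect_equal(attr(sig, "filter")$mean_cut, 80)

  all_null <- de; all_null$p <- 1
  expect_equal(nrow(filter_significant(all_null)), 0)
  # the linear fold-change gate can replace the log2 gate
  sig_fc <- filter_significant(de, min_abs_fc = 3)
  expect_equal(sig_fc$mirna, c("m1", "m2"))
})

test_that("type-I error of the per-feature test is calibrated on a null matrix", {
  cfg <- simulation_config(n_mirnas = 800, noise_sd = 0.3,
                           platform_bias = NULL, seed = 34L)
  sim <- simulate_two_platforms(cfg)
  de <- de_table(sim$platform_a, c("F_cRaf", "F_WT"))
  rate <- mean(de$p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("array and qPCR arms agree exactly on a noiseless simulation", {
  planted <- data.frame(mirna = sprintf("sim-miR-%04d", 1:3),
                        log2fc = c(2, -1.5, 3))
  cfg <- simulation_config(n_mirnas = 12, noise_sd = 0, qpcr_noise_sd = 0,
                           platform_bias = NULL, planted_effects = planted,
                           seed = 35L)
  sim <- simulate_two_platforms(cfg)
  de <- de_table(sim$platform_a, c("M_cRaf", "M_WT"))
  q <- ddct_fold_change(simulate_qpcr(cfg, sim$truth), c("M_cRaf", "M_WT"))
  shared <- intersect(de$mirna, q$assay)
  expect_equal(length(shared), 7)  # 3 planted + 4 control assays
  expect_equal(setNames(de$log2_ratio, de$mirna)[shared],
               setNames(q$log2fc, q$assay)[shared])
})

test_that("ddct_fold_change normalizes to the reference and tests Welch", {
  samples <- data.frame(sample = sprintf("s%d", 1:6),
                        group = rep(c("case", "ctrl"), each = 3))
  ct <- rbind(
    data.frame(sample = samples$sample, assay = "miR-x",
               ct = c(20, 20, 20, 22, 22, 22)),
    data.frame(sample = samples$sample, assay = "U6",
               ct = rep(15, 6)))
  res <- ddct_fold_change(ct, c("case", "ctrl"), samples = samples)
  x <- res[res$assay == "miR-x", ]
  expect_equal(x$ddct, -2)
  expect_equal(x$log2fc, 2)
  expect_equal(x$fold_change, 4)
  expect_equal(res$log2fc[res$assay == "U6"], 0)

  # missing reference Ct for a sample is an error
  ct_bad <- ct[!(ct$assay == "U6" & ct$sample == "s3"), ]
  expect_error(ddct_fold_change(ct_bad, c("case", "ctrl"), samples = samples),
               "missing reference Ct.*s3")
})
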