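test_that("Bland-Altman bias and limits match hand-computed toys", {
  # identical sessions
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
  # differences {1, -1}: SD = sqrt(2)
  ba <- bland_altman(c(0, 1), c(1, 0))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)
  # constant offset, zero variance
  bac <- bland_altman(c(1, 2, 3), c(1, 2, 3) + 0.5)
  expect_equal(bac$bias, 0.5)
  expect_equal(bac$loa_low, 0.5)
  expect_equal(bac$loa_high, 0.5)
  expect_error(bland_altman(1, 2), "2 complete pairs")
})

test_that("bias flips sign under session swap; limit width is invariant", {
  set.seed(5)
  t1 <- rnorm(10, 10); t2 <- rnorm(10, 10.5)
  a <- bland_altman(t1, t2); b <- bland_altman(t2, t1)
  expect_equal(a$bias, -b$bias)
  expect_equal(a$loa_high - a$loa_low, b$loa_high - b$loa_low)
})

test_that("wsCV matches the hand-worked example and its limiting value", {
  # pairs (10, 12), (10, 8): mean 10, differences {2, -2}, SD 2*sqrt(2)
  expect_equal(wscv(c(10, 10), c(12, 8)), 100 * 2 * sqrt(2) / 10,
               tolerance = 1e-12)
  expect_equal(round(wscv(c(10, 10), c(12, 8)), 2), 28.28)
  expect_equal(wscv(c(4, 5, 6), c(4, 5, 6)), 0)
  # large-n convergence to 100 * sd_d / mu
  set.seed(12)
  n <- 1e4; mu <- 10; sd_d <- 0.8
  t1 <- rnorm(n, mu, 0.2)
  t2 <- t1 + rnorm(n, 0, sd_d)
  expect_equal(wscv(t1, t2), 100 * sd_d / mu, tolerance = 0.5)
  expect_error(wscv(c(-1, 1), c(1, -1)), "zero mean")
  # classical variant divides by sqrt(2)
  expect_equal(wscv(c(10, 10), c(12, 8), classical = TRUE),
               wscv(c(10, 10), c(12, 8)) / sqrt(2))
})

test_that("MDD matches hand arithmetic and the limits-of-agreement
           identity", {
  expect_equal(mdd(c(10, 10), c(12, 8)), 1.96 * 2 * sqrt(2),
               tolerance = 1e-12)
  expect_equal(mdd(c(10, 10), c(12, 8)), 5.543, tolerance = 1e-3)
  expect_equal(mdd(c(3, 4), c(3, 4)), 0)
  set.seed(6)
  t1 <- rnorm(12, 5); t2 <- rnorm(12, 5)
  ba <- bland_altman(t1, t2)
  expect_equal(mdd(t1, t2), (ba$loa_high - ba$loa_low) / 2,
               tolerance = 1e-12)
})

test_that("wsCV and MDD are scale equivariant", {
  set.seed(7)
  t1 <- runif(8, 8, 12); t2 <- runif(8, 8, 12); k <- 3.7
  expect_equal(wscv(k * t1, k * t2), wscv(t1, t2), tolerance = 1e-12)
  expect_equal(mdd(k * t1, k * t2), k * mdd(t1, t2), tolerance = 1e-12)
})

test_that("per-muscle wsCV aggregation reproduces published summary rows", {
  ref <- thigh_wscv_reference()
  ivm <- ref[ref$mode == "ivim", ]
  std <- ref[ref$mode == "standard", ]
  expect_equal(nrow(ivm), 14L)
  s_md_ivim <- summarize_wscv(ivm$md)
  expect_equal(s_md_ivim$mean_1dp, 4.5)
  expect_equal(s_md_ivim$sd_1dp, 1.4)
  expect_equal(summarize_wscv(std$md)$mean_1dp, 5.6)
  expect_equal(summarize_wscv(ivm$l1)$mean_1dp, 5.3)
  expect_equal(summarize_wscv(std$l1)$mean_1dp, 7.5)
  expect_equal(summarize_wscv(ivm$l3)$mean_1dp, 5.7)
  expect_equal(summarize_wscv(std$fa)$mean_1dp, 13.9)
  expect_equal(summarize_wscv(rep(4.2, 14)), list(mean = 4.2, sd = 0,
                                                  mean_1dp = 4.2, sd_1dp = 0))
})

test_that("paired mode comparison matches t-distribution oracles", {
  # symmetric differences: t = 0, p = 1
  r <- compare_wscv_modes(c(2, 1, 2, 1), c(1, 2, 1, 2))
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  # differences {1, 2, 3}: t = 2 / (1/sqrt(3)) = 3.464, df 2
  r2 <- compare_wscv_modes(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r2$t, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(r2$p_value, 2 * pt(-2 / (1 / sqrt(3)), df = 2),
               tolerance = 1e-9)
  expect_equal(round(r2$p_value, 4), 0.0742)
  # identical inputs are degenerate, flagged
  r3 <- compare_wscv_modes(c(1, 2, 3), c(1, 2, 3))
  expect_true(r3$degenerate)
  expect_true(is.na(r3$p_value))
})

test_that("repeatability table and summary wire the statistics together", {
  lab <- muscle_label_map()
  set.seed(20)
  recs <- expand.grid(subject = 1:8, session = 1:2, code = lab$code,
                      mode = c("standard", "ivim"),
                      stringsAsFactors = FALSE)
  base <- 1.7 + 0.05 * as.integer(factor(recs$code))
  recs$md <- base + rnorm(nrow(recs), 0, 0.02)
  recs$l1 <- recs$md * 1.2; recs$l2 <- recs$md; recs$l3 <- recs$md * 0.8
  recs$fa <- 0.2 + rnorm(nrow(recs), 0, 0.01)
  recs$snr <- 45
  recs <- apply_snr_exclusion(recs)
  tab <- repeatability_table(recs)
  expect_setequal(unique(tab$parameter), c("l1", "l2", "l3", "md", "fa"))
  expect_equal(nrow(tab), 14 * 5 * 2)
  expect_true(all(tab$n_pairs == 8))
  expect_true(all(tab$loa_low <= tab$bias & tab$bias <= tab$loa_high))
  expect_true(all(tab$wscv >= 0) && all(tab$mdd >= 0))
  summ <- wscv_summary(tab)
  expect_equal(nrow(summ), 5 * 2)
  expect_true(all(c("wscv_mean", "wscv_sd", "p_vs_other") %in% names(summ)))
  # excluding one muscle pair reduces its n_pairs
  recs2 <- recs
  recs2$snr[recs2$subject == 1 & recs2$code == "BFL" &
              recs2$session == 2] <- 10
  recs2 <- apply_snr_exclusion(recs2)
  tab2 <- repeatability_table(recs2)
  expect_equal(unique(tab2$n_pairs[tab2$code == "BFL"]), 7)
})

test_that("Bland-Altman plot builds without error", {
  lab <- muscle_label_map()
  set.seed(21)
  recs <- expand.grid(subject = 1:5, session = 1:2, code = lab$code,
                      mode = "ivim", stringsAsFactors = FALSE)
  recs$md <- 1.7 + rnorm(nrow(recs), 0, 0.05)
  recs$l1 <- recs$md; recs$l2 <- recs$md; recs$l3 <- recs$md
  recs$fa <- 0.2
  recs$snr <- 45
  recs <- apply_snr_exclusion(recs)
  p <- bland_altman_plot(recs, mode = "ivim", parameters = c("md", "l1"))
  expect_s3_class(p, "ggplot")
})
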