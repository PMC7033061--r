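test_that("shell averaging groups by exact b and takes arithmetic means", {
  sc <- paper_scheme(1)
  ones <- rep(1, 56)
  sh <- shell_average(ones, sc)
  expect_length(sh$b, 10)
  expect_equal(sh$s, rep(1, 10))
  # a two-volume shell {3, 5} averages to 4
  sc2 <- gradient_scheme(c(0, 200, 200),
                         cbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(shell_average(c(7, 3, 5), sc2)$s, c(7, 4))
})

test_that("IVIM fit recovers known parameters from a noiseless decay", {
  sc <- paper_scheme(1)
  b <- sort(unique(sc$bvalues))
  truth <- c(s0 = 1, f = 0.05, d = 0.0015, dp = 0.05)
  s <- truth["s0"] * (truth["f"] * exp(-b * truth["dp"]) +
                        (1 - truth["f"]) * exp(-b * truth["d"]))
  fit <- fit_ivim(b, s)
  expect_true(fit$converged)
  expect_equal(fit$s0, truth[["s0"]], tolerance = 1e-4)
  expect_equal(fit$f, truth[["f"]], tolerance = 1e-4)
  expect_equal(fit$d, truth[["d"]], tolerance = 1e-4)
  expect_equal(fit$dp, truth[["dp"]], tolerance = 1e-4)
})

test_that("IVIM fit on purely mono-exponential data returns f ~ 0", {
  b <- sort(unique(paper_scheme(1)$bvalues))
  s <- exp(-b * 0.0017)
  fit <- fit_ivim(b, s)
  expect_lt(fit$f, 1e-6)
  expect_equal(fit$d, 0.0017, tolerance = 1e-3)
})

test_that("IVIM fit median D stays within 2% of truth under 1% noise", {
  b <- sort(unique(paper_scheme(1)$bvalues))
  truth_d <- 0.0016
  s0 <- 1; f <- 0.06; dp <- 0.04
  set.seed(77)
  ds <- replicate(200, {
    s <- s0 * (f * exp(-b * dp) + (1 - f) * exp(-b * truth_d))
    fit_ivim(b, pmax(s + rnorm(length(b), 0, 0.01), 1e-4))$d
  })
  expect_lt(abs(median(ds) / truth_d - 1), 0.02)
})

test_that("perfusion subtraction is exact algebra on the forward model", {
  sc <- paper_scheme(2)
  tv <- tensor_voxel(diag(c(2.1, 1.5, 1.2) * 1e-3))
  iv <- ivim_params(10, 0.08, 0.0015, 0.05)
  s <- predict_signal(tv, iv, sc)
  corrected <- subtract_perfusion(s, sc, iv)
  tissue <- predict_signal(tv, ivim_params(10, 0, 0.0015, 0.05), sc) *
    (1 - iv$f)
  expect_equal(corrected, tissue, tolerance = 1e-10)
  # b = 0 volume loses exactly S0 * f
  expect_equal(s[sc$bvalues == 0] - corrected[sc$bvalues == 0],
               10 * 0.08, tolerance = 1e-12)
  # f = 0 leaves the signal untouched (no floor applied here)
  iv0 <- ivim_params(10, 0, 0.0015, 0.05)
  expect_identical(subtract_perfusion(s, sc, iv0), s)
})

test_that("iWLLS recovers a diagonal tensor exactly from noiseless data", {
  sc <- paper_scheme(1)
  tv <- tensor_voxel(diag(c(2.0, 1.5, 1.2) * 1e-3))
  s <- predict_signal(tv, ivim_params(100, 0, 0.0015, 0.05), sc)
  fit <- iwlls_fit(s, sc)
  expect_lt(max(abs(fit$d - tv$d)), 1e-9)
  expect_equal(fit$s0, 100, tolerance = 1e-9)
})

test_that("iWLLS equals a brute-force weighted normal-equations oracle", {
  sc <- paper_scheme(4)
  B <- cbind(1,
             -sc$bvalues * sc$directions[1, ]^2,
             -sc$bvalues * sc$directions[2, ]^2,
             -sc$bvalues * sc$directions[3, ]^2,
             -2 * sc$bvalues * sc$directions[1, ] * sc$directions[2, ],
             -2 * sc$bvalues * sc$directions[1, ] * sc$directions[3, ],
             -2 * sc$bvalues * sc$directions[2, ] * sc$directions[3, ])
  set.seed(55)
  for (i in 1:20) {
    # random SPD tensor with muscle-scale eigenvalues
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    ev <- sort(runif(3, 0.9e-3, 2.3e-3), decreasing = TRUE)
    D <- q %*% diag(ev) %*% t(q)
    tv <- tensor_voxel(D)
    s <- predict_signal(tv, ivim_params(50, 0, ev[2], 0.05), sc)
    # oracle: explicit normal equations weighted by the true signal squared
    w <- s^2
    beta <- solve(t(B) %*% (B * w), t(B) %*% (w * log(s)))
    fit <- iwlls_fit(s, sc)
    expect_lt(max(abs(fit$d - beta[2:7])), 1e-6)
  }
})

test_that("iWLLS with equal weights reduces to the OLS solution", {
  sc <- paper_scheme(3)
  tv <- tensor_voxel(diag(c(1.9, 1.4, 1.1) * 1e-3))
  s <- predict_signal(tv, ivim_params(1, 0, 0.0014, 0.05), sc)
  B <- muscledti:::tensor_design(sc)
  ols <- qr.coef(qr(B), log(s))
  fit <- iwlls_fit(s, sc, max_iter = 0L)
  expect_equal(unname(fit$d), unname(ols[2:7]), tolerance = 1e-12)
})

test_that("degenerate schemes are rejected by name", {
  b <- c(0, rep(100, 8))
  dirs <- cbind(c(0, 0, 0), matrix(c(1, 0, 0), 3, 8))
  sc <- gradient_scheme(b, dirs)
  expect_error(iwlls_fit(exp(-b * 1e-3), sc), "degenerate")
})

test_that("iWLLS MD is nearly unbiased at SNR 40 under Rician noise", {
  sc <- paper_scheme(1)
  tv <- tensor_voxel(diag(c(2.0, 1.5, 1.3) * 1e-3))
  truth <- mean(c(2.0, 1.5, 1.3) * 1e-3)
  s <- predict_signal(tv, ivim_params(100, 0, 0.0015, 0.05), sc)
  set.seed(88)
  mds <- replicate(500, {
    noisy <- sqrt((s + rnorm(56, 0, 2.5))^2 + rnorm(56, 0, 2.5)^2)
    ev <- eigensystem(iwlls_fit(noisy, sc))$values
    md(ev[1], ev[2], ev[3])
  })
  expect_lt(abs(median(mds) / truth - 1), 0.01)
})

test_that("eigensystem sorts descending and is rotation invariant", {
  e <- eigensystem(tensor_voxel(diag(c(3, 2, 1))))
  expect_equal(e$values, c(3, 2, 1))
  set.seed(9)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  D <- q %*% diag(c(3, 2, 1)) %*% t(q)
  expect_equal(eigensystem(tensor_voxel(D))$values, c(3, 2, 1),
               tolerance = 1e-10)
  expect_equal(eigensystem(tensor_voxel(diag(1, 3)))$values, c(1, 1, 1))
})

test_that("MD and FA reproduce published per-muscle worked values", {
  # BFL, standard model
  expect_equal(round(md(2.23, 1.70, 1.47), 2), 1.80)
  expect_equal(round(fa(2.23, 1.70, 1.47), 2), 0.21)
  # SMR standard; VIL perfusion-corrected
  expect_equal(round(md(2.08, 1.68, 1.48), 2), 1.75)
  expect_equal(round(md(2.05, 1.65, 1.39), 2), 1.70)
  # limits
  expect_equal(fa(5, 5, 5), 0)
  expect_equal(fa(3, 0, 0), 1)
  expect_equal(md(4, 4, 4), 4)
  expect_equal(fa(0, 0, 0), 0)
})

test_that("MD is rotation invariant and FA scale invariant", {
  set.seed(10)
  for (i in 1:10) {
    ev <- sort(runif(3, 0.5, 3), decreasing = TRUE)
    k <- runif(1, 0.1, 10)
    expect_equal(fa(ev[1], ev[2], ev[3]),
                 fa(k * ev[1], k * ev[2], k * ev[3]), tolerance = 1e-12)
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    D <- q %*% diag(ev) %*% t(q)
    e2 <- eigensystem(tensor_voxel(D))$values
    expect_equal(md(e2[1], e2[2], e2[3]), mean(ev), tolerance = 1e-10)
  }
})

test_that("pipeline modes agree on a perfusion-free voxel and diverge with
           perfusion", {
  sc <- paper_scheme(1)
  tv <- tensor_voxel(diag(c(2.0, 1.5, 1.2) * 1e-3))
  m <- array(TRUE, c(1, 1, 1))
  s0v <- predict_signal(tv, ivim_params(100, 0, 0.0015, 0.05), sc)
  ds0 <- one_voxel_dataset(s0v, sc)
  r_std <- fit_pipeline(ds0, "standard", mask = m)
  r_iv <- fit_pipeline(ds0, "ivim_corrected", mask = m)
  expect_equal(r_iv$md[1], r_std$md[1], tolerance = 5e-3)
  sfv <- predict_signal(tv, ivim_params(100, 0.08, 0.0015, 0.05), sc)
  dsf <- one_voxel_dataset(sfv, sc)
  expect_gt(fit_pipeline(dsf, "standard", mask = m)$md[1],
            fit_pipeline(dsf, "ivim_corrected", mask = m)$md[1])
})
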