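test_that("sampling is deterministic given a seed", {
  m <- model_pmf(well_depth = 10)
  s1 <- sample_window(m, 6, n = 500, seed = 11)
  s2 <- sample_window(m, 6, n = 500, seed = 11)
  expect_identical(s1, s2)
  s3 <- sample_window(m, 6, n = 500, seed = 12)
  expect_false(identical(s1$xi, s3$xi))
  a1 <- sample_window(m, 6, n = 500, seed = 11, mode = "ar1", ar1_corr = 0.8)
  a2 <- sample_window(m, 6, n = 500, seed = 11, mode = "ar1", ar1_corr = 0.8)
  expect_identical(a1, a2)
})

test_that("sample mean sits at the biased minimum for a deep quadratic well", {
  # Laplace: for G + w locally quadratic the sample mean approximates the
  # argmin within ~3 standard errors
  m <- model_pmf(well_depth = 15)
  n <- 20000
  s <- sample_window(m, bias_center = 6, bias_constant = 10,
                     temperature = 310, n = n, seed = 3)
  xs <- seq(4, 8, by = 1e-4)
  tot <- model_pmf_value(m, xs) +
    0.5 * 10 * (xs - 6)^2
  argmin <- xs[which.min(tot)]
  se <- sd(s$xi) / sqrt(n)
  expect_lt(abs(mean(s$xi) - argmin), 3 * se + 1e-3)
})

test_that("empirical CDF of many draws matches the target CDF", {
  m <- model_pmf(well_depth = 8)
  temp <- 310; c0 <- 10; k <- 10
  s <- sample_window(m, c0, k, temp, n = 1e5, seed = 21)
  # independent tabulation of the target CDF by numeric integration
  rt <- 1.987204e-3 * temp
  xs <- seq(c0 - 6, c0 + 6, length.out = 40001)
  dens <- exp(-(model_pmf_value(m, xs) + 0.5 * k * (xs - c0)^2) / rt)
  cdf <- cumsum((dens[-1] + dens[-length(dens)]) / 2 * diff(xs))
  cdf <- c(0, cdf / max(cdf))
  target_cdf <- approxfun(xs, cdf, rule = 2)
  d_ks <- max(abs(ecdf(s$xi)(s$xi) - target_cdf(s$xi)))
  expect_lt(d_ks, 0.01)
})

test_that("AR(1) mode preserves the marginal and imposes autocorrelation", {
  m <- model_pmf(well_depth = 8)
  iid <- sample_window(m, 8, n = 8000, seed = 5)
  ar <- sample_window(m, 8, n = 8000, seed = 6, mode = "ar1", ar1_corr = 0.7)
  ks <- suppressWarnings(ks.test(iid$xi, ar$xi))
  expect_gt(ks$p.value, 1e-3)
  rho <- cor(ar$xi[-1], ar$xi[-nrow(ar)])
  expect_equal(rho, 0.7, tolerance = 0.1)
  rho_iid <- cor(iid$xi[-1], iid$xi[-nrow(iid)])
  expect_lt(abs(rho_iid), 0.05)
})

test_that("degenerate densities are refused", {
  # a near-delta target: gigantic spring constant pins all mass in one cell
  m <- flat_model()
  expect_error(sample_window(m, 10, bias_constant = 1e9, n = 10, seed = 1),
               "degenerate")
})

test_that("simulate_windows lays out the requested windows", {
  truth <- ground_truth(-60, -160)
  w <- simulate_windows(truth, 310, centers = seq(0, 5, 0.5),
                        n_per_window = 50, seed = 4)
  expect_equal(nrow(w), 11L)
  expect_equal(w$temperature, rep(310, 11))
  expect_true(all(vapply(w$values, length, integer(1)) == 50L))
  expect_true(all(unlist(w$values) >= 0))
  expect_s3_class(attr(w, "model"), "model_pmf")
})
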