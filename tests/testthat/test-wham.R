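test_that("single unbiased window collapses to -RT log(p-hat) exactly", {
  set.seed(5)
  x <- runif(5000, 1, 9)
  w <- tibble::tibble(
    bias_center = 5, bias_constant = 0, temperature = 310, values = list(x)
  )
  grid <- histogram_grid(0, 10, 50)
  h <- build_histograms(w, grid)
  prof <- solve_wham(h, reference = "none")
  rt <- 1.987204e-3 * 310
  phat <- h$counts[1, ] / sum(h$counts[1, ])
  expected <- ifelse(phat > 0, -rt * log(phat), Inf)
  fin <- is.finite(expected)
  diff <- prof$pmf[fin] - expected[fin]
  expect_lt(max(abs(diff - mean(diff))), 1e-12)
  expect_lte(prof$iterations, 2L)
})

test_that("probabilities are normalized and empty bins get +Inf PMF", {
  w <- small_windows(n = 400, xi_hi = 12)
  grid <- histogram_grid(0, 20, 120) # bins beyond 13 A unsampled
  prof <- solve_wham(build_histograms(w, grid), tol = 1e-5)
  expect_equal(sum(prof$prob), 1, tolerance = 1e-12)
  empty <- colSums(build_histograms(w, grid)$counts) == 0
  expect_true(any(empty))
  expect_true(all(is.infinite(prof$pmf[empty])))
  expect_true(all(is.finite(prof$pmf[!empty])))
  td <- tidy(prof)
  expect_named(td, c("xi", "pmf", "prob"))
  expect_equal(nrow(td), 120L)
})

test_that("PMF is invariant to a constant added to all biases", {
  w <- small_windows(n = 800, xi_hi = 14)
  h <- build_histograms(w, histogram_grid(0, 15, 100))
  p0 <- solve_wham(h, tol = 1e-8)
  p1 <- solve_wham(h, tol = 1e-8,
                   bias_offsets = rep(7.3, nrow(w)))
  expect_lt(max_aligned_diff(p0$pmf, p1$pmf), 1e-8)
})

test_that("PMF is invariant to window order", {
  w <- small_windows(n = 800, xi_hi = 14)
  grid <- histogram_grid(0, 15, 100)
  p0 <- solve_wham(build_histograms(w, grid), tol = 1e-8)
  perm <- withr::with_seed(1, sample(nrow(w)))
  p1 <- solve_wham(build_histograms(w[perm, ], grid), tol = 1e-8)
  expect_lt(max_aligned_diff(p0$pmf, p1$pmf), 1e-9)
})

test_that("solver warns and flags non-convergence at the iteration cap", {
  w <- small_windows(n = 500, xi_hi = 12)
  h <- build_histograms(w, histogram_grid(0, 13, 80))
  expect_warning(prof <- solve_wham(h, tol = 1e-10, max_iter = 5),
                 "did not converge")
  expect_false(prof$converged)
  expect_equal(prof$iterations, 5L)
})

test_that("package solver agrees with the independent log-space oracle", {
  w <- small_windows(n = 1000, xi_hi = 15)
  grid <- histogram_grid(0, 16, 90)
  h <- build_histograms(w, grid)
  mine <- solve_wham(h, tol = 1e-10)
  ref <- reference_wham(
    h$counts, h$totals, h$meta$bias_center, h$meta$bias_constant,
    grid$centers, 310
  )
  expect_lt(max_aligned_diff(mine$pmf, ref$pmf), 1e-6)
})

test_that("bootstrap errors are well-formed and seeded deterministically", {
  w <- small_windows(n = 1000, xi_hi = 15)
  grid <- histogram_grid(0, 16, 80)
  b1 <- bootstrap_pmf(w, grid, tol = 1e-6, n_boot = 8, seed = 77)
  b2 <- bootstrap_pmf(w, grid, tol = 1e-6, n_boot = 8, seed = 77)
  expect_identical(b1$err, b2$err)
  expect_identical(b1$boot$delta_g, b2$boot$delta_g)
  fin <- is.finite(b1$pmf)
  expect_length(b1$err, grid$n_bins)
  expect_true(all(b1$err[fin] >= 0, na.rm = TRUE))
  expect_true(all(is.na(b1$err[!fin])))
  expect_equal(b1$rel_err, b1$err / abs(extract_delta_g(b1)$delta_g))
  expect_gt(b1$boot$delta_g_se, 0)
  expect_error(bootstrap_pmf(w, grid, n_boot = 1), "n_boot")
})

test_that("bin scan is deterministic, tags errors with M and flags M < 100", {
  w <- small_windows(n = 1000, xi_hi = 15)
  scan1 <- bin_convergence_scan(w, bin_counts = c(2, 100, 150), tol = 1e-5,
                                xi_range = c(0, 16))
  scan2 <- bin_convergence_scan(w, bin_counts = c(2, 100, 150), tol = 1e-5,
                                xi_range = c(0, 16))
  expect_identical(scan1$delta_g, scan2$delta_g)
  expect_identical(scan1$below_plateau, c(TRUE, FALSE, FALSE))
  expect_true(is.finite(attr(scan1, "plateau_spread")))
  # M = 2 runs but cannot resolve a minimum and a barrier meaningfully;
  # it is flagged rather than refused
  expect_equal(scan1$n_bins[1], 2L)
  expect_error(bin_convergence_scan(w, bin_counts = c(1, 100)), "bin_counts")
})
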