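test_that("binning is half-open with a closed last bin and counts drops", {
  w <- tibble::tibble(
    bias_center = 2, bias_constant = 10, temperature = 310,
    values = list(c(1.0, 1.2, 3.9))
  )
  h <- build_histograms(w, histogram_grid(0, 4, 4))
  expect_equal(as.vector(h$counts), c(0L, 2L, 0L, 1L))
  expect_equal(h$totals, 3L)
  expect_equal(h$n_dropped, 0L)

  # edge cases: lower edge in, upper edge in (closed last bin), outside dropped
  w$values <- list(c(0, 1, 4, 4.5))
  h2 <- build_histograms(w, histogram_grid(0, 4, 4))
  expect_equal(as.vector(h2$counts), c(1L, 1L, 0L, 1L))
  expect_equal(h2$n_dropped, 1L)
})

test_that("burn-in discards the leading fraction and can empty a window", {
  w <- tibble::tibble(
    bias_center = 1, bias_constant = 10, temperature = 310,
    values = list(c(rep(0.5, 5), rep(2.5, 5)))
  )
  h <- build_histograms(w, histogram_grid(0, 4, 4), burn_in = 0.5)
  expect_equal(sum(h$counts), 5L)
  expect_equal(as.vector(h$counts), c(0L, 0L, 5L, 0L))
  expect_error(
    build_histograms(w, histogram_grid(0, 4, 4), burn_in = 0.99),
    NA
  ) # 1 sample left
  expect_error(build_histograms(w, burn_in = 1), "burn_in")
})

test_that("temperature mismatch across windows is rejected", {
  w <- tibble::tibble(
    bias_center = c(1, 2), bias_constant = 10, temperature = c(300, 310),
    values = list(1, 2)
  )
  expect_error(build_histograms(w, histogram_grid(0, 4, 4)), "temperature")
})

test_that("histogram of many draws matches the known biased density", {
  # flat surface + harmonic bias (half factor) => gaussian, sd = sqrt(RT/K)
  set.seed(101)
  k <- 10; temp <- 310; c0 <- 10
  sigma <- sqrt(1.987204e-3 * temp / k)
  x <- rnorm(1e5, c0, sigma)
  w <- tibble::tibble(
    bias_center = c0, bias_constant = k, temperature = temp,
    values = list(x[x >= 0])
  )
  grid <- histogram_grid(c0 - 5 * sigma, c0 + 5 * sigma, 40)
  h <- build_histograms(w, grid)
  p_exp <- diff(pnorm(grid$edges, c0, sigma))
  p_exp <- p_exp / sum(p_exp)
  keep <- p_exp * h$totals >= 5 # chi-square validity
  gof <- chisq.test(h$counts[1, keep], p = p_exp[keep] / sum(p_exp[keep]))
  expect_gt(gof$p.value, 1e-3)
})

test_that("overlap is 1 for identical, 0 for disjoint, symmetric, in [0,1]", {
  grid <- histogram_grid(0, 10, 20)
  mk <- function(vals1, vals2, centers = c(3, 7)) {
    build_histograms(tibble::tibble(
      bias_center = centers, bias_constant = 10, temperature = 310,
      values = list(vals1, vals2)
    ), grid)
  }
  same <- rep(c(3, 3.6, 4.2), 10)
  ov_id <- adjacent_overlap(mk(same, same))
  expect_equal(ov_id$overlap, 1.0)
  ov_dis <- adjacent_overlap(mk(rep(2, 10), rep(8, 10)))
  expect_equal(ov_dis$overlap, 0.0)
  a <- runif(200, 2, 5); b <- runif(200, 4, 8)
  o1 <- adjacent_overlap(mk(a, b))$overlap
  o2 <- adjacent_overlap(mk(b, a, centers = c(7, 3)))$overlap
  expect_equal(o1, o2)
  expect_true(o1 >= 0 && o1 <= 1)
  expect_error(adjacent_overlap(mk(rep(2, 5), rep(20, 5))), "no in-grid")
})

test_that("overlap of two offset gaussians matches the analytic coefficient", {
  # unit-mass gaussian histograms built from exact bin masses: overlap equals
  # 2*Phi(-d/(2*sigma)) = 0.3173105 for d = 0.5, sigma = 0.25, up to binning
  sigma <- 0.25; d <- 0.5; c1 <- 8; c2 <- 8.5
  grid <- histogram_grid(5, 11.5, 1300) # 5 mA bins
  m1 <- diff(pnorm(grid$edges, c1, sigma))
  m2 <- diff(pnorm(grid$edges, c2, sigma))
  counts <- rbind(round(1e7 * m1), round(1e7 * m2))
  h <- whamtherm:::.new_wham_histograms(
    counts, rowSums(counts), grid,
    tibble::tibble(bias_center = c(c1, c2), bias_constant = 10,
                   temperature = 310),
    310
  )
  ov <- adjacent_overlap(h)
  expect_equal(ov$overlap, 2 * pnorm(-1), tolerance = 2e-3)
  expect_identical(ov$pass, ov$overlap >= 0.2)
  expect_equal(attr(ov, "threshold"), 0.2)
  expect_identical(attr(ov, "all_pass"), all(ov$pass))
  expect_equal(attr(ov, "min_overlap"), min(ov$overlap))
})
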