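test_that("delta G extraction follows the min-then-barrier rule", {
  prof <- tibble::tibble(
    xi = c(1, 2, 6, 20, 40, 44),
    pmf = c(30, 5, -10, 2, 1.5, 1.4)
  )
  dg <- extract_delta_g(prof)
  expect_equal(dg$delta_g, -12)
  expect_equal(dg$xi_min, 6)
  expect_equal(dg$xi_max, 20)
  # the repulsive wall (30 kcal/mol at 1 A) must never be picked as the max
  expect_true(dg$xi_max > dg$xi_min)

  shifted <- dplyr::mutate(prof, pmf = pmf + 5)
  expect_equal(extract_delta_g(shifted)$delta_g, dg$delta_g)

  monotone <- tibble::tibble(xi = 1:5, pmf = c(5, 4, 3, 2, 1))
  expect_error(extract_delta_g(monotone), "coordinate range")
  expect_error(extract_delta_g(tibble::tibble(xi = 1, pmf = 0)), "finite bins")
})

test_that("extraction on the analytic model hits the well near 6 A", {
  truth <- ground_truth(-60, -160)
  m <- thermo_model_pmf(truth, 310)
  xs <- seq(0, 48, by = 0.01)
  dg <- extract_delta_g(tibble::tibble(xi = xs, pmf = model_pmf_value(m, xs)))
  expect_lt(abs(dg$xi_min - 6), 0.5)
  expect_equal(dg$delta_g, truth$delta_h - 310 * truth$delta_s / 1000,
               tolerance = 1e-6)
})

test_that("van't Hoff fit is exact on noise-free linear input", {
  temps <- seq(273, 333, 10)
  fit <- fit_gibbs_temperature(
    tibble::tibble(temperature = temps, delta_g = -60 + 0.160 * temps)
  )
  expect_equal(fit$delta_h, -60, tolerance = 1e-12)
  expect_equal(fit$delta_s, -160, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$dg37, -60 + 0.160 * 310.15, tolerance = 1e-12)
  # internal consistency: dG37 = dH - 310.15 dS / 1000 (dS in cal/(mol K))
  expect_equal(fit$dg37, fit$delta_h - 310.15 * fit$delta_s / 1000,
               tolerance = 1e-9)
  g <- glance(fit)
  expect_equal(g$r.squared, 1)
  expect_false(g$corrected)
  td <- tidy(fit)
  expect_equal(td$estimate, c(-60, -160), tolerance = 1e-10)

  expect_error(fit_gibbs_temperature(
    tibble::tibble(temperature = 310, delta_g = -12)
  ), "2 distinct")
  expect_error(fit_gibbs_temperature(
    tibble::tibble(temperature = c(310, 310), delta_g = c(-12, -11))
  ), "2 distinct")
})

test_that("melting temperature matches the frozen closed-form value", {
  # 1000*(-60) / (-160 + 1.987204 * ln(1e-5 / 4)) - 273.15, evaluated
  # independently beforehand
  expect_equal(melting_temperature(-60, -160, ct = 1e-5), 50.0677294877,
               tolerance = 1e-9)
  # at Ct = 4 M the log term vanishes: Tm(K) = 1000 dH / dS
  expect_equal(melting_temperature(-60, -160, ct = 4),
               1000 * (-60) / (-160) - 273.15, tolerance = 1e-9)
  # self-complementary uses m = 1
  expect_equal(melting_temperature(-60, -160, ct = 4, self_complementary = TRUE),
               1000 * (-60) / (-160 + 1.987204 * log(4)) - 273.15,
               tolerance = 1e-9)
})

test_that("Tm is strictly increasing in Ct for a stable duplex", {
  cts <- 10^seq(-7, -3, 0.5)
  tms <- vapply(cts, function(ct) melting_temperature(-60, -160, ct), numeric(1))
  expect_true(all(diff(tms) > 0))
  # and doubling Ct increases Tm
  expect_gt(melting_temperature(-60, -160, 2e-5),
            melting_temperature(-60, -160, 1e-5))
})

test_that("Tm error paths: zero denominator and never-melting duplex", {
  # denominator zero: dS = -R ln(Ct/4)
  ds0 <- -1.987204 * log(1e-5 / 4)
  expect_error(melting_temperature(-60, ds0, ct = 1e-5), "zero")
  expect_error(melting_temperature(60, -160, ct = 1e-5), "never melts")
})
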