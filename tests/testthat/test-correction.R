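make_params <- function(dh, ds, ids = seq_along(dh)) {
  tibble::tibble(
    duplex_id = paste0("d", ids),
    delta_h = dh,
    delta_s = ds
  )
}

test_that("identity and constructed-line calibrations are recovered exactly", {
  calc <- make_params(c(-40, -60, -80, -100), c(-110, -160, -210, -260))
  id <- calibrate_linear_correction(calc, calc)
  expect_equal(id$delta_h$slope, 1, tolerance = 1e-12)
  expect_equal(id$delta_h$intercept, 0, tolerance = 1e-10)
  expect_equal(id$delta_s$r_squared, 1, tolerance = 1e-12)

  exp_tab <- dplyr::mutate(calc, delta_h = 0.5 * delta_h + 3,
                           delta_s = 0.5 * delta_s + 3)
  half <- calibrate_linear_correction(calc, exp_tab)
  expect_equal(half$delta_h$slope, 0.5, tolerance = 1e-12)
  expect_equal(half$delta_h$intercept, 3, tolerance = 1e-10)
  expect_equal(half$delta_s$slope, 0.5, tolerance = 1e-12)
  td <- tidy(half)
  expect_equal(td$slope, c(0.5, 0.5))
  expect_equal(td$n, c(4, 4))

  expect_error(calibrate_linear_correction(calc[1:2, ], exp_tab[1:2, ]),
               "at least 3")
  expect_error(calibrate_linear_correction(calc, exp_tab[1:3, ]), "number")
  wrong <- dplyr::mutate(exp_tab, duplex_id = paste0("x", 1:4))
  expect_error(calibrate_linear_correction(calc, wrong), "ids")
})

test_that("affine distortion with noise is recovered within 2 SE", {
  withr::with_seed(2024, {
    n <- 30
    true <- make_params(runif(n, -120, -30), runif(n, -320, -90))
    distorted <- dplyr::mutate(
      true,
      delta_h = (delta_h - 5) / 0.5 + rnorm(n, sd = 3),
      delta_s = (delta_s - 8) / 0.5 + rnorm(n, sd = 8)
    )
    # experimental = 0.5 * calculated + 5 (dH), + 8 (dS), plus noise
    model <- calibrate_linear_correction(distorted, true)
    fit_h <- lm(true$delta_h ~ distorted$delta_h)
    se_h <- sqrt(diag(vcov(fit_h)))
    expect_lt(abs(model$delta_h$slope - 0.5), 2 * se_h[2])
    expect_lt(abs(model$delta_h$intercept - 5), 2 * se_h[1])
    fit_s <- lm(true$delta_s ~ distorted$delta_s)
    se_s <- sqrt(diag(vcov(fit_s)))
    expect_lt(abs(model$delta_s$slope - 0.5), 2 * se_s[2])
    expect_lt(abs(model$delta_s$intercept - 8), 2 * se_s[1])

    # applying the fitted correction recovers the true enthalpies within the
    # residual scatter of the calibration fit
    corrected <- apply_correction(distorted, model)
    rmse <- sqrt(mean((corrected$delta_h - true$delta_h)^2))
    expect_lt(rmse, 2 * summary(fit_h)$sigma)
  })
})

test_that("apply_correction recomputes derived quantities and sets the flag", {
  params <- make_params(c(-50, -70, -90), c(-140, -190, -240))
  id <- calibrate_linear_correction(params, params)
  out <- apply_correction(params, id)
  expect_equal(out$delta_h, params$delta_h, tolerance = 1e-9)
  expect_equal(out$delta_s, params$delta_s, tolerance = 1e-9)
  expect_true(all(out$corrected))
  # dG37 and Tm always derive from the corrected dH/dS pair
  expect_equal(out$dg37, out$delta_h - 310.15 * out$delta_s / 1000,
               tolerance = 1e-9)
  expect_equal(out$tm, melting_temperature(out$delta_h, out$delta_s),
               tolerance = 1e-9)
  expect_error(apply_correction(out, id), "twice")
})

test_that("error summary: zero on identity, 10 percent on a 1.1 factor", {
  p <- make_params(c(-50, -70, -90), c(-140, -190, -240))
  p$dg37 <- p$delta_h - 310.15 * p$delta_s / 1000
  p$tm <- melting_temperature(p$delta_h, p$delta_s)
  s_id <- summarize_errors(p, p)
  expect_equal(s_id$error, rep(0, 4))
  expect_equal(s_id$r_squared, rep(1, 4))

  pred <- dplyr::mutate(p, delta_h = 1.1 * delta_h, delta_s = 1.1 * delta_s,
                        dg37 = 1.1 * dg37, tm = tm + 2)
  s <- summarize_errors(pred, p)
  expect_equal(s$error[s$parameter == "delta_h"], 10, tolerance = 1e-9)
  expect_equal(s$error[s$parameter == "dg37"], 10, tolerance = 1e-9)
  expect_equal(s$error[s$parameter == "tm"], 2, tolerance = 1e-9)
  expect_equal(s$metric[s$parameter == "tm"], "mae_c")

  withzero <- p
  withzero$dg37[1] <- 0
  expect_warning(summarize_errors(p, withzero), "zero experimental")
})

test_that("multiplicative noise yields the folded-normal expected MAPE", {
  # |N(0, 0.1)| has mean 0.1 * sqrt(2/pi) = 7.9788 % relative error
  withr::with_seed(7, {
    n <- 4000
    exp_tab <- make_params(runif(n, -120, -30), runif(n, -320, -90))
    pred <- dplyr::mutate(
      exp_tab,
      delta_h = delta_h * (1 + rnorm(n, sd = 0.1)),
      delta_s = delta_s * (1 + rnorm(n, sd = 0.1))
    )
    s <- summarize_errors(pred, exp_tab)
    expect_equal(s$error[s$parameter == "delta_h"], 7.978846, tolerance = 0.05)
    expect_equal(s$error[s$parameter == "delta_s"], 7.978846, tolerance = 0.05)
  })
})
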