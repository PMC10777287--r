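#' Formation free energy from a PMF profile
#'
#' The Gibbs free energy of duplex formation at the profile's temperature is
#' the drop from the dissociation barrier down into the bound well:
#' `ΔG°(T) = PMF(ξ_min) − PMF(ξ_max)`, negative for a stable duplex.  The
#' minimum is the global finite minimum of the profile (the bound state,
#' typically near 6 A for a relaxed duplex); the maximum search is restricted
#' to coordinates beyond the minimum, so the repulsive wall at short
#' separations — where the profile also rises — is never mistaken for the
#' dissociation barrier.
#'
#' @param profile A `pmf_profile`, or any data frame with `xi` and `pmf`
#'   columns (e.g. an analytic model profile).
#' @return A one-row tibble: `delta_g` (kcal/mol), `xi_min`, `xi_max` (A),
#'   `pmf_min`, `pmf_max` (kcal/mol).
#' @export
#' @examples
#' prof <- tibble::tibble(xi = c(2, 6, 20, 40), pmf = c(5, -10, 2, 1.5))
#' extract_delta_g(prof)  # -10 - 2 = -12 kcal/mol
extract_delta_g <- function(profile) {
  if (inherits(profile, "pmf_profile")) {
    xi <- profile$grid$centers
    pmf <- profile$pmf
  } else if (is.data.frame(profile) && all(c("xi", "pmf") %in% names(profile))) {
    xi <- profile$xi
    pmf <- profile$pmf
  } else {
    abort("`profile` must be a pmf_profile or a data frame with xi and pmf.")
  }
  fin <- is.finite(pmf)
  if (sum(fin) < 2L) abort("profile needs at least 2 finite bins.")
  i_min <- which(fin)[which.min(pmf[fin])]
  beyond <- which(fin & seq_along(pmf) > i_min)
  if (!length(beyond)) {
    abort(paste(
      "no finite PMF values beyond the minimum: the profile is monotone up to",
      "its end. Extend the reaction-coordinate range so the dissociation",
      "barrier and plateau are sampled (45 A suffices for short duplexes,",
      "60 A for 14-16 bp)."
    ))
  }
  i_max <- beyond[which.max(pmf[beyond])]
  tibble(
    delta_g = pmf[i_min] - pmf[i_max],
    xi_min = xi[i_min],
    xi_max = xi[i_max],
    pmf_min = pmf[i_min],
    pmf_max = pmf[i_max]
  )
}

#' Melting temperature of a bimolecular duplex
#'
#' Two-state model: the melting temperature is where half of the strands are
#' duplexed, `Tm(K) = 1000 ΔH° / (ΔS° + R ln(Ct / m))`, with `ΔH°` in
#' kcal/mol, `ΔS°` in cal/(mol K), total strand concentration `Ct` in mol/L,
#' and molecularity factor `m = 4` for a duplex of two distinct strands
#' (`m = 1` for a self-complementary one).  Returned in degrees Celsius.
#'
#' @param delta_h Formation enthalpy ΔH°, kcal/mol (negative for a stable
#'   duplex).  Vectorised.
#' @param delta_s Formation entropy ΔS°, cal/(mol K).  Vectorised.
#' @param ct Total oligonucleotide concentration, mol/L; 10 μM by default,
#'   a typical experimental value.
#' @param self_complementary If `TRUE` use m = 1 instead of m = 4.
#' @return Melting temperature(s) in degrees C.
#' @export
#' @examples
#' melting_temperature(-60, -160)
melting_temperature <- function(delta_h, delta_s, ct = 1e-5,
                                self_complementary = FALSE) {
  .stopifnot_scalar_num(ct, "ct", positive = TRUE)
  if (length(delta_h) != length(delta_s)) {
    abort("`delta_h` and `delta_s` must have equal length.")
  }
  m <- if (isTRUE(self_complementary)) 1 else 4
  denom <- delta_s + .R_CAL * log(ct / m)
  if (any(abs(denom) < 1e-9)) {
    abort("denominator ΔS° + R ln(Ct/m) is (near) zero; Tm is undefined.")
  }
  tm_k <- 1000 * delta_h / denom
  bad <- delta_h > 0 & delta_s < 0
  if (any(bad)) {
    abort("ΔH° > 0 with ΔS° < 0: the duplex never melts under the two-state model.")
  }
  if (any(tm_k <= 0)) {
    abort("computed Tm is not a physical temperature; check the parameter signs.")
  }
  tm_k - 273.15
}

#' Van't Hoff decomposition of ΔG°(T)
#'
#' Fits the two-state linear model `ΔG°(T) = ΔH° − T ΔS°` by ordinary least
#' squares to formation free energies computed at several temperatures.  The
#' intercept is the enthalpy (kcal/mol) and minus the slope the entropy
#' (converted to cal/(mol K)); `ΔG°37` is the fitted line evaluated at
#' 310.15 K, and the melting temperature follows from the fitted parameters
#' via [melting_temperature()].
#'
#' @param series Tibble with columns `temperature` (K) and `delta_g`
#'   (kcal/mol); an optional `delta_g_err` column is carried along.  At least
#'   two distinct temperatures are required.
#' @inheritParams melting_temperature
#' @param duplex_id Optional label stored with the fit.
#' @return A `vanthoff_fit` object.  Use [tidy()] for parameter estimates
#'   with standard errors, [glance()] for fit summary, [thermo_params()] for
#'   the one-row parameter table.
#' @export
#' @examples
#' ts <- tibble::tibble(
#'   temperature = seq(273, 333, 10),
#'   delta_g = -60 + 0.160 * seq(273, 333, 10)
#' )
#' thermo_params(fit_gibbs_temperature(ts))
fit_gibbs_temperature <- function(series, ct = 1e-5, self_complementary = FALSE,
                                  duplex_id = NA_character_) {
  if (!is.data.frame(series) ||
      !all(c("temperature", "delta_g") %in% names(series))) {
    abort("`series` must have columns `temperature` and `delta_g`.")
  }
  series <- as_tibble(series)
  if (any(series$temperature <= 0)) abort("temperatures must be positive (K).")
  if (length(unique(series$temperature)) < 2L) {
    abort("need at least 2 distinct temperatures to fit ΔG°(T).")
  }
  fit <- lm(delta_g ~ temperature, data = series)
  cf <- coef(fit)
  ## vcov warns on zero-residual input; SEs are legitimately 0 there
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  delta_h <- unname(cf[1])                      # kcal/mol
  delta_s <- -unname(cf[2]) * 1000              # cal/(mol K)
  r2 <- cor(series$temperature, series$delta_g)^2
  dg37 <- delta_h - .T37_K * delta_s / 1000
  tm <- melting_temperature(delta_h, delta_s, ct, self_complementary)

  structure(
    list(
      duplex_id = duplex_id,
      delta_h = delta_h,
      delta_s = delta_s,
      dg37 = dg37,
      tm = tm,
      r_squared = r2,
      se_delta_h = unname(se[1]),
      se_delta_s = unname(se[2]) * 1000,
      ct = ct,
      self_complementary = isTRUE(self_complementary),
      corrected = FALSE,
      data = series,
      lm = fit
    ),
    class = "vanthoff_fit"
  )
}

#' @export
print.vanthoff_fit <- function(x, ...) {
  cat("<vanthoff_fit>", if (!is.na(x$duplex_id)) x$duplex_id else "", "\n")
  cat(sprintf("  ΔH° = %.2f kcal/mol,  ΔS° = %.1f cal/(mol K)\n",
              x$delta_h, x$delta_s))
  cat(sprintf("  ΔG°37 = %.2f kcal/mol,  Tm = %.1f °C,  R² = %.4f  (%d temperatures)\n",
              x$dg37, x$tm, x$r_squared, nrow(x$data)))
  if (x$corrected) cat("  linear correction applied\n")
  invisible(x)
}

#' @rdname fit_gibbs_temperature
#' @param x A `vanthoff_fit`.
#' @param ... Unused.
#' @method tidy vanthoff_fit
#' @export
tidy.vanthoff_fit <- function(x, ...) {
  tibble(
    term = c("delta_h", "delta_s"),
    estimate = c(x$delta_h, x$delta_s),
    std.error = c(x$se_delta_h, x$se_delta_s),
    unit = c("kcal/mol", "cal/(mol K)")
  )
}

#' @rdname fit_gibbs_temperature
#' @method glance vanthoff_fit
#' @export
glance.vanthoff_fit <- function(x, ...) {
  tibble(
    r.squared = x$r_squared,
    dg37 = x$dg37,
    tm = x$tm,
    n_temperatures = nrow(x$data),
    corrected = x$corrected
  )
}

#' One-row thermodynamic parameter table
#'
#' @param fit A `vanthoff_fit` (or a list of them).
#' @return A tibble with columns `duplex_id`, `delta_h` (kcal/mol), `delta_s`
#'   (cal/(mol K)), `dg37` (kcal/mol), `tm` (°C), `r_squared`, `corrected`.
#' @export
thermo_params <- function(fit) {
  if (inherits(fit, "vanthoff_fit")) fit <- list(fit)
  purrr::map_dfr(fit, function(f) {
    tibble(
      duplex_id = f$duplex_id,
      delta_h = f$delta_h,
      delta_s = f$delta_s,
      dg37 = f$dg37,
      tm = f$tm,
      r_squared = f$r_squared,
      corrected = f$corrected
    )
  })
}
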