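.validate_params_table <- function(x, name, need = c("delta_h", "delta_s")) {
  if (!is.data.frame(x)) abort(sprintf("`%s` must be a data frame.", name))
  x <- as_tibble(x)
  if (!"duplex_id" %in% names(x)) {
    abort(sprintf("`%s` needs a `duplex_id` column.", name))
  }
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(sprintf("`%s` lacks column(s): %s.", name,
                  paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(x$duplex_id)) {
    abort(sprintf("`%s` has duplicated duplex ids.", name))
  }
  x
}

#' Linear calibration of calculated thermodynamic parameters
#'
#' Simulation-derived enthalpies and entropies correlate linearly with
#' experimental ones but with a slope well below unity and a substantial
#' intercept, so a per-parameter affine map can be calibrated on duplexes
#' with known experimental values and then applied to new calculations.  For
#' ΔH° and ΔS° independently this fits `experimental = a * calculated + b`
#' by ordinary least squares.
#'
#' @param calc,exp Tibbles of parameters for the same duplexes, matched by
#'   `duplex_id`, each with columns `duplex_id`, `delta_h` (kcal/mol) and
#'   `delta_s` (cal/(mol K)).  At least 3 matched pairs are required.
#' @return A `thermo_correction` object; [tidy()] gives one row per parameter
#'   with `slope`, `intercept`, `r_squared`, `n`.
#' @seealso [apply_correction()]
#' @export
calibrate_linear_correction <- function(calc, exp) {
  calc <- .validate_params_table(calc, "calc")
  exp <- .validate_params_table(exp, "exp")
  if (nrow(calc) != nrow(exp)) {
    abort("`calc` and `exp` must have the same number of duplexes.")
  }
  if (!setequal(calc$duplex_id, exp$duplex_id)) {
    abort("`calc` and `exp` duplex ids do not match.")
  }
  joined <- dplyr::inner_join(
    dplyr::select(calc, "duplex_id", calc_h = "delta_h", calc_s = "delta_s"),
    dplyr::select(exp, "duplex_id", exp_h = "delta_h", exp_s = "delta_s"),
    by = "duplex_id"
  )
  if (nrow(joined) < 3L) abort("need at least 3 matched pairs to calibrate.")

  fit_one <- function(x, y) {
    f <- lm(y ~ x)
    cf <- coef(f)
    list(slope = unname(cf[2]), intercept = unname(cf[1]),
         r_squared = cor(x, y)^2, n = length(x))
  }
  h <- fit_one(joined$calc_h, joined$exp_h)
  s <- fit_one(joined$calc_s, joined$exp_s)
  if (!is.finite(h$slope) || h$slope == 0 || !is.finite(s$slope) || s$slope == 0) {
    abort("degenerate calibration: a fitted slope is zero or non-finite.")
  }
  structure(
    list(delta_h = h, delta_s = s, n = nrow(joined)),
    class = "thermo_correction"
  )
}

#' @export
print.thermo_correction <- function(x, ...) {
  cat(sprintf(
    "<thermo_correction> %d duplexes\n  ΔH°: exp = %.3f calc %+.2f (R² = %.3f)\n  ΔS°: exp = %.3f calc %+.2f (R² = %.3f)\n",
    x$n, x$delta_h$slope, x$delta_h$intercept, x$delta_h$r_squared,
    x$delta_s$slope, x$delta_s$intercept, x$delta_s$r_squared
  ))
  invisible(x)
}

#' @rdname calibrate_linear_correction
#' @param x A `thermo_correction`.
#' @param ... Unused.
#' @method tidy thermo_correction
#' @export
tidy.thermo_correction <- function(x, ...) {
  tibble(
    parameter = c("delta_h", "delta_s"),
    slope = c(x$delta_h$slope, x$delta_s$slope),
    intercept = c(x$delta_h$intercept, x$delta_s$intercept),
    r_squared = c(x$delta_h$r_squared, x$delta_s$r_squared),
    n = x$n
  )
}

#' Apply a linear correction to calculated parameters
#'
#' Maps ΔH° and ΔS° through their calibrated affine corrections and
#' recomputes ΔG°37 and Tm from the corrected pair (they are derived
#' quantities and are never corrected independently).  Refuses to correct
#' parameters twice.
#'
#' @param params A parameter tibble (see [thermo_params()]) with columns
#'   `duplex_id`, `delta_h`, `delta_s`; a `corrected` column, if present,
#'   must be all `FALSE`.
#' @param model A [calibrate_linear_correction()] result.
#' @inheritParams melting_temperature
#' @return The tibble with corrected `delta_h`, `delta_s`, recomputed `dg37`
#'   and `tm`, and `corrected = TRUE`.
#' @export
apply_correction <- function(params, model, ct = 1e-5,
                             self_complementary = FALSE) {
  params <- .validate_params_table(params, "params")
  if (!inherits(model, "thermo_correction")) {
    abort("`model` must come from calibrate_linear_correction().")
  }
  if ("corrected" %in% names(params) && any(params$corrected)) {
    abort("parameters are already corrected; refusing to correct twice.")
  }
  out <- params
  out$delta_h <- model$delta_h$slope * params$delta_h + model$delta_h$intercept
  out$delta_s <- model$delta_s$slope * params$delta_s + model$delta_s$intercept
  out$dg37 <- out$delta_h - .T37_K * out$delta_s / 1000
  out$tm <- melting_temperature(out$delta_h, out$delta_s, ct, self_complementary)
  out$corrected <- TRUE
  out
}

#' Error summary against experimental parameters
#'
#' Compares predicted and experimental thermodynamic parameters pairwise:
#' mean absolute percentage error for ΔH°, ΔS° and ΔG°37, mean absolute
#' error in degrees C for Tm, and the squared Pearson correlation for each.
#' Pairs whose experimental value is zero are excluded from a percentage
#' error with a warning.
#'
#' @param pred,exp Parameter tibbles matched by `duplex_id` with columns
#'   among `delta_h`, `delta_s`, `dg37`, `tm`.
#' @return A tibble with one row per parameter: `parameter`, `error`
#'   (`mape_pct` or `mae_c` per the `metric` column), `r_squared`, `n`.
#' @export
summarize_errors <- function(pred, exp) {
  pred <- .validate_params_table(pred, "pred", need = character())
  exp <- .validate_params_table(exp, "exp", need = character())
  pars <- intersect(intersect(names(pred), names(exp)),
                    c("delta_h", "delta_s", "dg37", "tm"))
  if (!length(pars)) abort("no shared parameter columns to compare.")
  joined <- dplyr::inner_join(pred, exp, by = "duplex_id",
                              suffix = c("_pred", "_exp"))
  if (!nrow(joined)) abort("no matched duplex ids between `pred` and `exp`.")

  purrr::map_dfr(pars, function(p) {
    x <- joined[[paste0(p, "_pred")]]
    y <- joined[[paste0(p, "_exp")]]
    if (p == "tm") {
      err <- mean(abs(x - y))
      metric <- "mae_c"
      n <- length(x)
    } else {
      keep <- y != 0
      if (!all(keep)) {
        warn(sprintf("%s: %d pair(s) with zero experimental value excluded.",
                     p, sum(!keep)))
      }
      err <- mean(abs((x[keep] - y[keep]) / y[keep])) * 100
      metric <- "mape_pct"
      n <- sum(keep)
    }
    r2 <- if (length(unique(y)) > 1 && length(unique(x)) > 1) cor(x, y)^2 else NA_real_
    tibble(parameter = p, metric = metric, error = err, r_squared = r2, n = n)
  })
}
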