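#' Analytic model free-energy surface for a dissociating duplex
#'
#' A closed-form potential of mean force along the strand-separation
#' coordinate with the qualitative shape of a real duplex profile: a steep
#' repulsive wall at short separations, a single bound-state well near 6 A, a
#' rise to a dissociation barrier, and a gently declining plateau beyond it.
#' The form is
#'
#' \deqn{G(\xi) = W e^{-\xi/\lambda}
#'   - d\, e^{-(\xi - c)^2 / 2\sigma^2}
#'   + h\, e^{-(\xi - b)^2 / 2\sigma_b^2}
#'   + s\,(\xi - b)\,\Phi\!\big((\xi - b)/\tau\big)}
#'
#' with wall height \eqn{W} and decay \eqn{\lambda}, well amplitude \eqn{d},
#' center \eqn{c} and width \eqn{\sigma}, barrier bump height \eqn{h},
#' position \eqn{b} and width \eqn{\sigma_b}, and plateau slope \eqn{s}
#' switched on smoothly past the barrier (\eqn{\Phi} is the standard normal
#' CDF, \eqn{\tau} the switch width).  It is smooth and finite for all
#' \eqn{\xi \ge 0} and has exactly one local minimum between the wall and the
#' barrier for any meaningful well amplitude.
#'
#' @param well_depth Well (Gaussian) amplitude `d`, kcal/mol, > 0 for a bound
#'   duplex.
#' @param well_center Bound-state position `c`, A (~6 for a relaxed duplex).
#' @param well_width Well width `sigma`, A.
#' @param wall_height,wall_decay Repulsive wall scale `W` (kcal/mol) and
#'   decay length `lambda` (A).
#' @param barrier_position,barrier_height,barrier_width Dissociation barrier
#'   bump `b` (A), `h` (kcal/mol), `sigma_b` (A).
#' @param plateau_slope Slope `s` of the post-barrier decline, kcal/(mol A);
#'   small and negative ("diminishes slightly").
#' @param switch_width Width `tau` of the smooth plateau switch, A.
#' @return An object of class `model_pmf`.
#' @seealso [model_pmf_value()], [thermo_model_pmf()], [model_delta_g()]
#' @export
#' @examples
#' m <- model_pmf(well_depth = 12)
#' model_pmf_value(m, c(0, 6, 13, 40))
model_pmf <- function(well_depth, well_center = 6, well_width = 1.8,
                      wall_height = 80, wall_decay = 0.8,
                      barrier_position = 13, barrier_height = 1.0,
                      barrier_width = 2.5, plateau_slope = -0.01,
                      switch_width = 2) {
  for (nm in c("well_center", "well_width", "wall_decay", "barrier_width",
               "switch_width")) {
    .stopifnot_scalar_num(get(nm), nm, positive = TRUE)
  }
  .stopifnot_scalar_num(well_depth, "well_depth")
  .stopifnot_scalar_num(wall_height, "wall_height")
  .stopifnot_scalar_num(barrier_height, "barrier_height")
  .stopifnot_scalar_num(plateau_slope, "plateau_slope")
  if (well_center >= barrier_position) {
    abort("`well_center` must lie below `barrier_position`.")
  }
  structure(
    list(
      well_depth = well_depth, well_center = well_center,
      well_width = well_width, wall_height = wall_height,
      wall_decay = wall_decay, barrier_position = barrier_position,
      barrier_height = barrier_height, barrier_width = barrier_width,
      plateau_slope = plateau_slope, switch_width = switch_width
    ),
    class = "model_pmf"
  )
}

#' @export
print.model_pmf <- function(x, ...) {
  cat(sprintf(
    "<model_pmf> well %.2f kcal/mol at %.1f A, barrier bump %.2f at %.1f A\n",
    x$well_depth, x$well_center, x$barrier_height, x$barrier_position
  ))
  invisible(x)
}

#' Evaluate a model free-energy surface
#'
#' @param model A [model_pmf()].
#' @param xi Reaction-coordinate values, A (>= 0).  Vectorised.
#' @return Free energy in kcal/mol.
#' @export
model_pmf_value <- function(model, xi) {
  if (!inherits(model, "model_pmf")) abort("`model` must be a model_pmf.")
  if (any(xi < 0)) abort("`xi` must be >= 0.")
  with(model, {
    wall_height * exp(-xi / wall_decay) -
      well_depth * exp(-(xi - well_center)^2 / (2 * well_width^2)) +
      barrier_height * exp(-(xi - barrier_position)^2 / (2 * barrier_width^2)) +
      plateau_slope * (xi - barrier_position) *
        pnorm((xi - barrier_position) / switch_width)
  })
}

## analytic formation free energy of a model surface: global minimum, then
## global maximum restricted beyond it, both refined with optimize()
.model_extrema <- function(model, xi_max_search = 48) {
  xs <- seq(0, xi_max_search, by = 0.01)
  gs <- model_pmf_value(model, xs)
  i <- which.min(gs)
  lo <- xs[max(i - 2L, 1L)]
  hi <- xs[min(i + 2L, length(xs))]
  omin <- optimize(function(x) model_pmf_value(model, x), c(lo, hi))
  after <- xs > omin$minimum
  if (!any(after)) abort("no coordinate range beyond the model minimum.")
  j <- which(after)[which.max(gs[after])]
  lo <- xs[max(j - 2L, 1L)]
  hi <- xs[min(j + 2L, length(xs))]
  omax <- optimize(function(x) -model_pmf_value(model, x), c(lo, hi))
  list(
    xi_min = omin$minimum, pmf_min = omin$objective,
    xi_max = omax$minimum, pmf_max = -omax$objective
  )
}

#' Analytic formation free energy of a model surface
#'
#' Applies the same extraction rule as [extract_delta_g()] — global minimum,
#' then the maximum beyond it — to the closed-form surface, with
#' `optimize()`-refined extrema, giving the exact zero-noise ground truth.
#'
#' @inheritParams model_pmf_value
#' @param xi_max_search Upper end of the search range, A.
#' @return One-row tibble: `delta_g`, `xi_min`, `xi_max`, `pmf_min`, `pmf_max`.
#' @export
model_delta_g <- function(model, xi_max_search = 48) {
  e <- .model_extrema(model, xi_max_search)
  tibble(
    delta_g = e$pmf_min - e$pmf_max,
    xi_min = e$xi_min, xi_max = e$xi_max,
    pmf_min = e$pmf_min, pmf_max = e$pmf_max
  )
}

#' Ground-truth thermodynamics for synthetic datasets
#'
#' Fixes the enthalpy and entropy of duplex formation that a synthetic study
#' should recover; the per-temperature target free energies follow exactly
#' from `ΔG°(T) = ΔH° − T ΔS°/1000`.
#'
#' @param delta_h True formation enthalpy, kcal/mol.
#' @param delta_s True formation entropy, cal/(mol K).
#' @param temperatures Simulation temperatures, K; defaults to the 273–333 K
#'   grid in 10 K steps.
#' @return A `ground_truth` object with a `delta_g` tibble (temperature,
#'   dg_true).
#' @export
#' @examples
#' ground_truth()$delta_g
ground_truth <- function(delta_h = -60, delta_s = -160,
                         temperatures = seq(273, 333, by = 10)) {
  .stopifnot_scalar_num(delta_h, "delta_h")
  .stopifnot_scalar_num(delta_s, "delta_s")
  if (any(temperatures <= 0)) abort("temperatures must be positive (K).")
  structure(
    list(
      delta_h = delta_h,
      delta_s = delta_s,
      temperatures = temperatures,
      delta_g = tibble(
        temperature = temperatures,
        dg_true = delta_h - temperatures * delta_s / 1000
      )
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> ΔH° = %.1f kcal/mol, ΔS° = %.1f cal/(mol K), %d temperatures\n",
    x$delta_h, x$delta_s, length(x$temperatures)
  ))
  invisible(x)
}

#' Temperature-specific model surface for a ground truth
#'
#' Returns a [model_pmf()] whose well-to-barrier free-energy difference
#' equals the ground truth `ΔG°(T) = ΔH° − T ΔS°/1000` at the requested
#' temperature.  All shape parameters are held fixed across temperatures;
#' only the well amplitude is adjusted, calibrated numerically (by root
#' finding on the analytic extraction, to ~1e-10 kcal/mol) so the analytic
#' [model_delta_g()] reproduces the target exactly.
#'
#' @param truth A [ground_truth()].
#' @param temperature Temperature, K (> 0).
#' @param ... Shape parameters passed to [model_pmf()] (all but `well_depth`).
#' @return A `model_pmf` with attribute `dg_target`.  A non-negative target
#'   (unstable duplex) is allowed but flagged with a warning.
#' @export
thermo_model_pmf <- function(truth, temperature, ...) {
  if (!inherits(truth, "ground_truth")) {
    abort("`truth` must come from ground_truth().")
  }
  .stopifnot_scalar_num(temperature, "temperature", positive = TRUE)
  target <- truth$delta_h - temperature * truth$delta_s / 1000
  if (target >= 0) {
    warn(sprintf(
      "ΔG_true = %.2f kcal/mol at %.1f K: the duplex is unstable at this temperature.",
      target, temperature
    ))
  }
  make <- function(d) model_pmf(well_depth = d, ...)
  f <- function(d) model_delta_g(make(d))$delta_g - target
  ## below ~1 kcal/mol of well amplitude the declining plateau, not the well,
  ## can hold the global minimum and the surface no longer represents a bound
  ## duplex; restrict calibration to amplitudes with an interior minimum
  lo <- 1.0
  hi <- max(4, 2 * abs(target) + 4)
  if (f(lo) < 0 || f(hi) > 0) {
    abort(sprintf(
      "cannot calibrate a well for ΔG_true = %.2f kcal/mol with this shape.",
      target
    ))
  }
  d <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  model <- make(d)
  attr(model, "dg_target") <- target
  attr(model, "temperature") <- temperature
  model
}
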