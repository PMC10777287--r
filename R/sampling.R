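#' Draw umbrella-window samples from a model surface
#'
#' Samples the reaction coordinate of one biased window exactly: the target
#' marginal `p(xi) ∝ exp(-(G(xi) + w(xi)) / RT)` is tabulated on a fine grid
#' (linear-interpolated inverse CDF), where `G` is the model surface and `w`
#' the harmonic bias.  `mode = "iid"` draws independent samples; `mode =
#' "ar1"` imposes a lag-1 autocorrelation through a Gaussian copula while
#' preserving the same marginal, to emulate the correlated output of a
#' molecular-dynamics window.
#'
#' @param model A [model_pmf()].
#' @param bias_center Bias center, A.
#' @param bias_constant Harmonic constant K, kcal/(mol A^2); 0 means no bias.
#' @param temperature Temperature, K.
#' @param n Number of samples (>= 1).
#' @param seed Integer seed; the draw is deterministic given it.
#' @param mode `"iid"` or `"ar1"`.
#' @param ar1_corr Lag-1 autocorrelation in (0, 1) for `mode = "ar1"`.
#' @param half_factor Bias convention, see [solve_wham()].
#' @param xi_range Tabulation range `c(lo, hi)`; defaults to 6 A around the
#'   bias center (the bias confines the window), or the whole surface for an
#'   unbiased window.
#' @param n_grid Tabulation points; at least 1e4.
#' @return A tibble with columns `time` (sample index, ps) and `xi` (A).
#' @export
sample_window <- function(model, bias_center, bias_constant = 10,
                          temperature = 310, n = 1000, seed = NULL,
                          mode = c("iid", "ar1"), ar1_corr = 0.9,
                          half_factor = TRUE, xi_range = NULL,
                          n_grid = 12001) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1L || n < 1) abort("`n` must be >= 1.")
  n <- as.integer(n)
  .stopifnot_scalar_num(temperature, "temperature", positive = TRUE)
  if (n_grid < 1e4) abort("`n_grid` must be at least 1e4.")
  if (mode == "ar1" && (ar1_corr <= 0 || ar1_corr >= 1)) {
    abort("`ar1_corr` must lie in (0, 1).")
  }
  rt <- .rt(temperature)
  if (is.null(xi_range)) {
    xi_range <- if (bias_constant > 0) {
      c(max(0, bias_center - 6), bias_center + 6)
    } else {
      c(0, max(48, bias_center + 6))
    }
  }
  xs <- seq(xi_range[1], xi_range[2], length.out = n_grid)
  g <- model_pmf_value(model, xs) +
    .bias_energy(xs, bias_center, bias_constant, half_factor)
  u <- exp(-(g - min(g)) / rt)
  dx <- diff(xs)
  mass <- (u[-1] + u[-n_grid]) / 2 * dx
  top2 <- sum(sort(mass, decreasing = TRUE)[1:2])
  if (top2 / sum(mass) > 0.999) {
    abort("degenerate target density: essentially all mass in one grid cell.")
  }
  cdf <- c(0, cumsum(mass)) / sum(mass)
  ## strictly increasing knots for the inverse interpolation
  keep <- c(TRUE, diff(cdf) > 0)
  cdf_k <- cdf[keep]
  xs_k <- xs[keep]

  draw <- function() {
    un <- switch(mode,
      iid = runif(n),
      ar1 = {
        z <- numeric(n)
        z[1] <- rnorm(1)
        innov <- rnorm(n - 1, sd = sqrt(1 - ar1_corr^2))
        for (t in seq_len(n - 1L)) z[t + 1L] <- ar1_corr * z[t] + innov[t]
        pnorm(z)
      }
    )
    approx(cdf_k, xs_k, xout = un, rule = 2, ties = "ordered")$y
  }
  xi <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(time = as.numeric(seq_len(n)), xi = xi)
}

#' Layout of a synthetic umbrella-sampling study
#'
#' Encodes the study conditions of a simulated dataset: bias centers every
#' 0.5 A from 0 to 45 A, a 10 kcal/mol harmonic constant, and temperatures
#' 273 to 333 K in 10 K steps (the standard layout for short duplexes;
#' extend the centers to 60 A for 14-16 bp ones).
#'
#' @param centers Bias centers, A, strictly increasing.
#' @param bias_constant Harmonic constant, kcal/(mol A^2).
#' @param temperatures Simulation temperatures, K.
#' @param n_per_window Samples per window (>= 1).
#' @param seed Base integer seed; every window's draw is derived from it.
#' @param sampling_mode `"iid"` or `"ar1"`, see [sample_window()].
#' @param ar1_corr Lag-1 autocorrelation for `"ar1"`.
#' @return A `simulation_plan` object.
#' @export
simulation_plan <- function(centers = seq(0, 45, by = 0.5),
                            bias_constant = 10,
                            temperatures = seq(273, 333, by = 10),
                            n_per_window = 10000, seed = 42,
                            sampling_mode = c("iid", "ar1"),
                            ar1_corr = 0.9) {
  sampling_mode <- match.arg(sampling_mode)
  if (length(centers) < 1L || is.unsorted(centers, strictly = TRUE)) {
    abort("`centers` must be strictly increasing.")
  }
  if (any(centers < 0)) abort("`centers` must be >= 0.")
  .stopifnot_scalar_num(bias_constant, "bias_constant", positive = TRUE)
  if (any(temperatures <= 0)) abort("temperatures must be positive (K).")
  if (n_per_window < 1) abort("`n_per_window` must be >= 1.")
  structure(
    list(
      centers = centers, bias_constant = bias_constant,
      temperatures = temperatures, n_per_window = as.integer(n_per_window),
      seed = as.integer(seed), sampling_mode = sampling_mode,
      ar1_corr = ar1_corr
    ),
    class = "simulation_plan"
  )
}

#' @export
print.simulation_plan <- function(x, ...) {
  cat(sprintf(
    "<simulation_plan> %d windows (%.1f-%.1f A), K = %g, %d temperatures, n = %d/window, %s sampling, seed %d\n",
    length(x$centers), min(x$centers), max(x$centers), x$bias_constant,
    length(x$temperatures), x$n_per_window, x$sampling_mode, x$seed
  ))
  invisible(x)
}

#' Simulate all umbrella windows for one temperature
#'
#' Builds the temperature-specific model surface for the ground truth and
#' samples every window of the layout, returning the in-memory windows
#' tibble consumed by [build_histograms()].
#'
#' @param truth A [ground_truth()].
#' @param temperature Temperature, K.
#' @param centers,bias_constant,n_per_window,seed,mode,ar1_corr Window layout
#'   and sampling controls, as in [simulation_plan()].
#' @param half_factor Bias convention, see [solve_wham()].
#' @param ... Shape parameters forwarded to [thermo_model_pmf()].
#' @return A windows tibble (`bias_center`, `bias_constant`, `temperature`,
#'   `values`) with the model stored in attribute `model`.
#' @export
simulate_windows <- function(truth, temperature, centers = seq(0, 45, by = 0.5),
                             bias_constant = 10, n_per_window = 10000,
                             seed = 42, mode = c("iid", "ar1"), ar1_corr = 0.9,
                             half_factor = TRUE, ...) {
  mode <- match.arg(mode)
  model <- thermo_model_pmf(truth, temperature, ...)
  values <- purrr::imap(centers, function(c0, i) {
    sample_window(
      model, c0, bias_constant, temperature, n_per_window,
      seed = if (is.null(seed)) NULL else seed + i,
      mode = mode, ar1_corr = ar1_corr, half_factor = half_factor
    )$xi
  })
  out <- tibble(
    bias_center = centers,
    bias_constant = bias_constant,
    temperature = temperature,
    values = values
  )
  attr(out, "model") <- model
  out
}

#' Write a complete synthetic umbrella-sampling dataset to disk
#'
#' For every temperature of the plan, writes one time-series file per window
#' and a metadata index in the conventional one-window-per-line format
#' (`path center spring_constant temperature`), plus a machine-readable
#' ground-truth record.  Regeneration from the same plan, truth and seed is
#' byte-identical.
#'
#' @param plan A [simulation_plan()].
#' @param truth A [ground_truth()]; its temperatures are taken from the plan.
#' @param out_dir Output directory (created if needed).
#' @param half_factor Bias convention, see [solve_wham()].
#' @param ... Shape parameters forwarded to [thermo_model_pmf()].
#' @return A tibble with one row per temperature: `temperature`,
#'   `metadata_path`, `n_windows`; the ground-truth file path in attribute
#'   `truth_path`.
#' @export
generate_dataset <- function(plan, truth, out_dir, half_factor = TRUE, ...) {
  if (!inherits(plan, "simulation_plan")) abort("`plan` must be a simulation_plan.")
  if (!inherits(truth, "ground_truth")) abort("`truth` must be a ground_truth.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create `%s`.", out_dir))

  rows <- purrr::imap(plan$temperatures, function(temp, t_idx) {
    windows <- simulate_windows(
      truth, temp, plan$centers, plan$bias_constant, plan$n_per_window,
      seed = plan$seed + 1000L * t_idx, mode = plan$sampling_mode,
      ar1_corr = plan$ar1_corr, half_factor = half_factor, ...
    )
    meta_lines <- character(nrow(windows))
    for (i in seq_len(nrow(windows))) {
      fname <- sprintf("win_T%03d_%03d.dat", as.integer(round(temp)), i)
      fpath <- file.path(out_dir, fname)
      v <- windows$values[[i]]
      writeLines(
        c("# time_ps xi_angstrom",
          sprintf("%.1f %.6f", seq_along(v), v)),
        fpath
      )
      meta_lines[i] <- sprintf(
        "%s %.4f %.4f %.2f", fname, windows$bias_center[i],
        windows$bias_constant[i], temp
      )
    }
    meta_path <- file.path(
      out_dir, sprintf("metadata_T%03d.txt", as.integer(round(temp)))
    )
    writeLines(
      c("# umbrella-window index: series_path bias_center_A bias_constant_kcal_mol_A2 temperature_K",
        meta_lines),
      meta_path
    )
    tibble(temperature = temp, metadata_path = meta_path,
           n_windows = nrow(windows))
  })

  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(
    list(
      delta_h_kcal_mol = truth$delta_h,
      delta_s_cal_mol_K = truth$delta_s,
      delta_g = truth$delta_g,
      plan = list(
        centers = plan$centers, bias_constant = plan$bias_constant,
        temperatures = plan$temperatures, n_per_window = plan$n_per_window,
        seed = plan$seed, sampling_mode = plan$sampling_mode,
        ar1_corr = plan$ar1_corr, half_factor = isTRUE(half_factor)
      )
    ),
    truth_path, auto_unbox = TRUE, digits = NA
  )
  out <- dplyr::bind_rows(rows)
  attr(out, "truth_path") <- truth_path
  out
}
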