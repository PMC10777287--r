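#' Uniform histogram grid along the reaction coordinate
#'
#' Defines the binning used for all WHAM histograms: `n_bins` uniform bins on
#' `[xi_min, xi_max]`.  Bins are half-open `[edge_k, edge_{k+1})` except the
#' last, which is closed, so every point of the interval belongs to exactly
#' one bin.
#'
#' @param xi_min,xi_max Grid limits in angstrom; `xi_min < xi_max`.
#' @param n_bins Number of bins (>= 2).  The free-energy profile plateaus for
#'   100 bins or more on typical strand-separation data; 150 is the package
#'   default elsewhere.
#' @return An object of class `wham_grid`: a list with `xi_min`, `xi_max`,
#'   `n_bins`, bin `edges` (length `n_bins + 1`) and bin `centers`.
#' @export
#' @examples
#' g <- histogram_grid(0, 45, 150)
#' head(g$centers)
histogram_grid <- function(xi_min, xi_max, n_bins = 150) {
  .stopifnot_scalar_num(xi_min, "xi_min")
  .stopifnot_scalar_num(xi_max, "xi_max")
  if (xi_min >= xi_max) abort("`xi_min` must be smaller than `xi_max`.")
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2 ||
      n_bins != round(n_bins)) {
    abort("`n_bins` must be a single integer >= 2.")
  }
  n_bins <- as.integer(n_bins)
  edges <- seq(xi_min, xi_max, length.out = n_bins + 1L)
  structure(
    list(
      xi_min = xi_min, xi_max = xi_max, n_bins = n_bins,
      edges = edges,
      centers = (edges[-1L] + edges[-(n_bins + 1L)]) / 2
    ),
    class = "wham_grid"
  )
}

#' @export
print.wham_grid <- function(x, ...) {
  cat(sprintf(
    "<wham_grid> %d bins on [%.3f, %.3f] A (width %.4f A)\n",
    x$n_bins, x$xi_min, x$xi_max, diff(x$edges[1:2])
  ))
  invisible(x)
}

#' Default analysis grid for a set of umbrella windows
#'
#' Builds a grid spanning `[0, max(bias_center) + 2 * sigma_bias]`, where
#' `sigma_bias` is the coordinate standard deviation implied by the harmonic
#' bias at the window temperature.  Two sigma covers the bulk of the
#' outermost window's histogram; bins further out would be reached only by
#' that window's extreme tail, where the bias varies so steeply across a bin
#' that the bin-center WHAM weights acquire a systematic discretization error
#' of order 0.2 kcal/mol at the default bin width.
#'
#' @param windows A windows tibble (see [build_histograms()]).
#' @param n_bins Number of bins; defaults to 150.
#' @param half_factor Bias convention flag, see [solve_wham()].
#' @return A [histogram_grid()] object.
#' @export
default_grid <- function(windows, n_bins = 150, half_factor = TRUE) {
  windows <- .validate_windows(windows)
  k <- min(windows$bias_constant[windows$bias_constant > 0], Inf)
  sigma <- if (is.finite(k)) {
    .bias_sigma(k, windows$temperature[1], half_factor)
  } else {
    1
  }
  histogram_grid(0, max(windows$bias_center) + 2 * sigma, n_bins)
}

## assign samples to bins; returns integer indices, 0 / n_bins + 1 for
## out-of-grid values (half-open bins, last bin closed)
.bin_index <- function(x, grid) {
  findInterval(x, grid$edges, rightmost.closed = TRUE)
}
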