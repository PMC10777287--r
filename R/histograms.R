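## windows tibble: one row per umbrella window, columns
##   bias_center (A), bias_constant (kcal/(mol A^2)), temperature (K),
##   values (list column of numeric reaction-coordinate samples)
.validate_windows <- function(windows, require_values = TRUE) {
  if (!is.data.frame(windows)) abort("`windows` must be a data frame.")
  windows <- as_tibble(windows)
  need <- c("bias_center", "bias_constant", "temperature")
  missing <- setdiff(need, names(windows))
  if (length(missing)) {
    abort(paste0("`windows` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(windows) == 0L) abort("`windows` has no rows.")
  if (any(!is.finite(windows$bias_center)) || any(windows$bias_center < 0)) {
    abort("`bias_center` must be finite and >= 0.")
  }
  if (any(!is.finite(windows$bias_constant)) || any(windows$bias_constant < 0)) {
    abort("`bias_constant` must be finite and >= 0.")
  }
  if (any(!is.finite(windows$temperature)) || any(windows$temperature <= 0)) {
    abort("`temperature` must be finite and > 0.")
  }
  if (require_values) {
    if (!"values" %in% names(windows) || !is.list(windows$values)) {
      abort("`windows` needs a `values` list column of numeric samples.")
    }
    ok <- vapply(
      windows$values,
      function(v) is.numeric(v) && length(v) >= 1L && all(is.finite(v)) && all(v >= 0),
      logical(1)
    )
    if (!all(ok)) {
      abort(sprintf(
        "window %d: `values` must be non-empty, finite and >= 0.", which(!ok)[1]
      ))
    }
  }
  windows
}

#' Build biased histograms from umbrella windows
#'
#' Bins each window's reaction-coordinate samples on a common grid.  All
#' windows must share one simulation temperature.  An optional burn-in
#' fraction discards the leading part of every series before binning (an
#' equilibration allowance; the default keeps everything).  Samples outside
#' the grid are dropped and counted per window.
#'
#' @param windows Tibble with one row per window: `bias_center` (A),
#'   `bias_constant` (kcal/(mol A^2)), `temperature` (K) and a `values` list
#'   column of coordinate samples (A).
#' @param grid A [histogram_grid()]; defaults to [default_grid()] of the
#'   windows with 150 bins.
#' @param burn_in Fraction in `[0, 1)` of each series discarded from the
#'   front.
#' @return An object of class `wham_histograms`: grid, per-window bin
#'   `counts` (windows x bins integer matrix), post-burn-in `totals`,
#'   per-window `n_dropped` (out-of-grid samples), the window metadata and
#'   the shared `temperature`.
#' @export
#' @examples
#' w <- tibble::tibble(
#'   bias_center = 2, bias_constant = 10, temperature = 310,
#'   values = list(c(1.0, 1.2, 3.9))
#' )
#' h <- build_histograms(w, histogram_grid(0, 4, 4))
#' h$counts
build_histograms <- function(windows, grid = NULL, burn_in = 0) {
  windows <- .validate_windows(windows)
  if (!is.numeric(burn_in) || length(burn_in) != 1L || burn_in < 0 || burn_in >= 1) {
    abort("`burn_in` must be a single number in [0, 1).")
  }
  temps <- unique(windows$temperature)
  if (length(temps) != 1L) {
    abort(sprintf(
      "all windows must share one temperature; found: %s K.",
      paste(format(temps), collapse = ", ")
    ))
  }
  if (is.null(grid)) grid <- default_grid(windows)
  if (!inherits(grid, "wham_grid")) abort("`grid` must be a `wham_grid`.")

  nw <- nrow(windows)
  counts <- matrix(0L, nrow = nw, ncol = grid$n_bins)
  totals <- integer(nw)
  dropped <- integer(nw)
  for (i in seq_len(nw)) {
    v <- windows$values[[i]]
    keep_from <- floor(burn_in * length(v)) + 1L
    v <- v[keep_from:length(v)]
    if (length(v) == 0L) {
      abort(sprintf("window %d (center %.3f A) is empty after burn-in.",
                    i, windows$bias_center[i]))
    }
    idx <- .bin_index(v, grid)
    ingrid <- idx >= 1L & idx <= grid$n_bins
    counts[i, ] <- tabulate(idx[ingrid], nbins = grid$n_bins)
    totals[i] <- sum(ingrid)
    dropped[i] <- sum(!ingrid)
  }

  structure(
    list(
      grid = grid,
      counts = counts,
      totals = totals,
      n_dropped = dropped,
      meta = dplyr::select(windows, -dplyr::any_of(c("values", "times"))),
      temperature = temps
    ),
    class = "wham_histograms"
  )
}

#' @export
print.wham_histograms <- function(x, ...) {
  cat(sprintf(
    "<wham_histograms> %d windows, %d bins, T = %.1f K, %d samples (%d dropped)\n",
    nrow(x$counts), x$grid$n_bins, x$temperature, sum(x$totals), sum(x$n_dropped)
  ))
  invisible(x)
}

## construct directly from a counts matrix (used by bootstrap and tests)
.new_wham_histograms <- function(counts, totals, grid, meta, temperature,
                                 n_dropped = integer(nrow(counts))) {
  structure(
    list(grid = grid, counts = counts, totals = totals, n_dropped = n_dropped,
         meta = meta, temperature = temperature),
    class = "wham_histograms"
  )
}

#' Histogram overlap between adjacent umbrella windows
#'
#' For WHAM to connect windows into one profile, neighbouring windows must
#' sample overlapping stretches of the reaction coordinate; the accepted rule
#' of thumb requires at least 20 % overlap.  For each adjacent pair (ordered
#' by bias center) the overlap is `sum_b min(p_i(b), p_j(b))` of the two
#' normalized histograms, a number in `[0, 1]` that is symmetric in the pair.
#'
#' @param hists A [build_histograms()] result with at least two windows.
#' @param threshold Pass/fail threshold; 0.20 by default.
#' @return A tibble with one row per adjacent pair: `center_lo`, `center_hi`,
#'   `overlap`, `pass`; attributes `min_overlap`, `threshold` and `all_pass`
#'   summarise the set.
#' @export
adjacent_overlap <- function(hists, threshold = 0.20) {
  if (!inherits(hists, "wham_histograms")) {
    abort("`hists` must come from build_histograms().")
  }
  nw <- nrow(hists$counts)
  if (nw < 2L) abort("need at least 2 windows to compute overlaps.")
  ord <- order(hists$meta$bias_center)
  counts <- hists$counts[ord, , drop = FALSE]
  centers <- hists$meta$bias_center[ord]
  ingrid <- rowSums(counts)
  if (any(ingrid == 0)) {
    abort(sprintf("window at center %.3f A has no in-grid samples.",
                  centers[which(ingrid == 0)[1]]))
  }
  p <- counts / ingrid
  ov <- vapply(
    seq_len(nw - 1L),
    function(i) sum(pmin(p[i, ], p[i + 1L, ])),
    numeric(1)
  )
  out <- tibble(
    center_lo = centers[-nw],
    center_hi = centers[-1L],
    overlap = ov,
    pass = ov >= threshold
  )
  attr(out, "min_overlap") <- min(ov)
  attr(out, "threshold") <- threshold
  attr(out, "all_pass") <- all(out$pass)
  out
}
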