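## Exponentiated negative bias matrix A[i, b] = exp(-w_i(xi_b) / RT), the
## standard bin-center convention.  Far windows underflow to exact 0, which
## the update equations tolerate.
.bias_matrix <- function(hists, half_factor, bias_offsets = NULL) {
  centers <- hists$meta$bias_center
  ks <- hists$meta$bias_constant
  xb <- hists$grid$centers
  rt <- .rt(hists$temperature)
  w <- outer(seq_along(centers), seq_along(xb), function(i, b) {
    .bias_energy(xb[b], centers[i], ks[i], half_factor)
  })
  if (!is.null(bias_offsets)) {
    if (length(bias_offsets) != length(centers)) {
      abort("`bias_offsets` must have one value per window.")
    }
    w <- w + bias_offsets
  }
  exp(-w / rt)
}

## Plain self-consistent iteration of the coupled WHAM equations:
##   p(b)  = sum_i n_i(b) / sum_i N_i exp((f_i - w_i(b))/RT)
##   f_i   = -RT log sum_b p(b) exp(-w_i(b)/RT)
## Convergence is max_i |change in f_i| (mean-centred) < tol, in kcal/mol.
.wham_iterate <- function(ctot, totals, A, rt, tol, max_iter, f_init = NULL) {
  nw <- nrow(A)
  f <- if (is.null(f_init)) numeric(nw) else f_init - mean(f_init)
  p <- NULL
  it <- 0L
  delta <- Inf
  repeat {
    it <- it + 1L
    g <- totals * exp(f / rt)
    denom <- as.vector(crossprod(A, g))
    p <- ifelse(denom > 0, ctot / denom, 0)
    s <- as.vector(A %*% p)
    if (any(s <= 0)) {
      abort("a window sees zero unbiased density; its bias region is unsampled.")
    }
    f_new <- -rt * log(s)
    f_new <- f_new - mean(f_new)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol || it >= max_iter) break
  }
  list(p = p, f = f, iterations = it, converged = delta < tol, last_delta = delta)
}

#' Solve the WHAM equations for a potential of mean force
#'
#' Combines the biased histograms of all umbrella windows at one temperature
#' into an unbiased probability distribution along the reaction coordinate by
#' self-consistent iteration of the standard coupled WHAM equations, then
#' reports the potential of mean force `PMF(b) = -RT log p(b)`.
#'
#' The per-window free-energy shifts `f_i` are iterated until the largest
#' change between successive iterations falls below `tol` (kcal/mol).  Bins
#' with zero total count get `PMF = +Inf` and zero probability; they are
#' ignored by downstream minimum/maximum searches.
#'
#' @param hists A [build_histograms()] result.
#' @param tol Convergence threshold on the free-energy shifts, kcal/mol.
#' @param max_iter Iteration cap; on hitting it the profile is returned with
#'   `converged = FALSE` and a warning, not an error.
#' @param half_factor If `TRUE` (default) the bias is `w = K/2 (xi - c)^2`
#'   (the convention of the classic WHAM implementations); if `FALSE`,
#'   `w = K (xi - c)^2` (the AMBER restraint convention).  Must match how the
#'   simulations were biased.
#' @param reference How to anchor the arbitrary PMF offset: `"plateau"`
#'   (default) zeroes the mean over the last 5 % of finite bins, i.e. the
#'   dissociated plateau; `"min"` zeroes the minimum; `"none"` leaves the raw
#'   `-RT log p`.  Purely cosmetic: free-energy differences are unaffected.
#' @param bias_offsets Optional per-window constants (kcal/mol) added to the
#'   harmonic bias; the PMF is invariant to a shared constant.
#' @param f_init Optional warm-start shifts.
#' @return A `pmf_profile`: grid, `pmf` (kcal/mol), normalized `prob`
#'   (sums to 1), window `shifts`, `temperature`, `iterations`, `converged`.
#' @seealso [bootstrap_pmf()] for uncertainties, [extract_delta_g()] for the
#'   formation free energy.
#' @export
solve_wham <- function(hists, tol = 1e-6, max_iter = 1e5, half_factor = TRUE,
                       reference = c("plateau", "min", "none"),
                       bias_offsets = NULL, f_init = NULL) {
  if (!inherits(hists, "wham_histograms")) {
    abort("`hists` must come from build_histograms().")
  }
  .stopifnot_scalar_num(tol, "tol", positive = TRUE)
  reference <- match.arg(reference)
  ctot <- colSums(hists$counts)
  if (all(ctot == 0)) abort("all bins are empty; no samples fell on the grid.")
  rt <- .rt(hists$temperature)
  A <- .bias_matrix(hists, half_factor, bias_offsets)
  sol <- .wham_iterate(ctot, hists$totals, A, rt, tol, max_iter, f_init)
  if (!sol$converged) {
    warn(sprintf(
      "WHAM did not converge in %d iterations (last shift change %.3g kcal/mol).",
      sol$iterations, sol$last_delta
    ))
  }
  prob <- sol$p / sum(sol$p)
  pmf <- ifelse(prob > 0, -rt * log(prob), Inf)
  pmf <- .shift_pmf(pmf, reference)

  structure(
    list(
      grid = hists$grid,
      pmf = pmf,
      prob = prob,
      err = NULL,
      rel_err = NULL,
      temperature = hists$temperature,
      shifts = tibble(bias_center = hists$meta$bias_center, f = sol$f),
      iterations = sol$iterations,
      converged = sol$converged,
      tol = tol,
      half_factor = isTRUE(half_factor),
      reference = reference,
      n_windows = nrow(hists$counts),
      n_samples = sum(hists$totals)
    ),
    class = "pmf_profile"
  )
}

.shift_pmf <- function(pmf, reference) {
  fin <- which(is.finite(pmf))
  if (!length(fin)) return(pmf)
  shift <- switch(reference,
    plateau = {
      tail_ids <- fin[fin >= stats::quantile(fin, 0.95, type = 1)]
      mean(pmf[tail_ids])
    },
    min = min(pmf[fin]),
    none = 0
  )
  pmf - shift
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf(
    "<pmf_profile> T = %.1f K, %d bins, %d windows, %d iterations (%s)\n",
    x$temperature, x$grid$n_bins, x$n_windows, x$iterations,
    if (x$converged) "converged" else "NOT converged"
  ))
  if (!is.null(x$err)) cat("  bootstrap errors attached\n")
  invisible(x)
}

#' @rdname solve_wham
#' @param x A `pmf_profile`.
#' @param ... Unused.
#' @method tidy pmf_profile
#' @export
tidy.pmf_profile <- function(x, ...) {
  out <- tibble(
    xi = x$grid$centers,
    pmf = x$pmf,
    prob = x$prob
  )
  if (!is.null(x$err)) {
    out$err <- x$err
    out$rel_err <- x$rel_err
  }
  out
}

#' @rdname solve_wham
#' @method glance pmf_profile
#' @export
glance.pmf_profile <- function(x, ...) {
  tibble(
    temperature = x$temperature,
    n_bins = x$grid$n_bins,
    n_windows = x$n_windows,
    n_samples = x$n_samples,
    iterations = x$iterations,
    converged = x$converged,
    tol = x$tol
  )
}

#' Bootstrap uncertainty of a WHAM profile
#'
#' Estimates per-bin PMF standard errors by the Monte-Carlo bootstrap: each
#' replicate resamples every window's in-grid samples with replacement (same
#' size, implemented as a multinomial redraw of its histogram), re-solves the
#' WHAM equations, and aligns the replicate profile to the common reference.
#' The per-bin error is the standard deviation across replicates; the
#' relative error divides it by the magnitude of the formation free energy
#' extracted from the full-data profile.
#'
#' @inheritParams build_histograms
#' @inheritParams solve_wham
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed making the resampling deterministic.
#' @return The full-data `pmf_profile` with `err` and `rel_err` filled, plus a
#'   `boot` element: replicate count, failures, per-replicate formation free
#'   energies `delta_g`, and their standard deviation `delta_g_se`.
#' @export
bootstrap_pmf <- function(windows, grid = NULL, burn_in = 0, tol = 1e-6,
                          max_iter = 1e5, half_factor = TRUE,
                          reference = c("plateau", "min", "none"),
                          n_boot = 20, seed = NULL) {
  if (!is.numeric(n_boot) || length(n_boot) != 1L || n_boot < 2) {
    abort("`n_boot` must be >= 2.")
  }
  n_boot <- as.integer(n_boot)
  reference <- match.arg(reference)
  hists <- build_histograms(windows, grid, burn_in)
  base <- solve_wham(hists, tol, max_iter, half_factor, reference)
  base_dg <- extract_delta_g(base)

  nw <- nrow(hists$counts)
  run_replicate <- function() {
    counts <- hists$counts
    for (i in seq_len(nw)) {
      n_in <- sum(counts[i, ])
      counts[i, ] <- as.integer(stats::rmultinom(1, n_in, hists$counts[i, ]))
    }
    h <- .new_wham_histograms(counts, hists$totals, hists$grid, hists$meta,
                              hists$temperature)
    prof <- suppressWarnings(
      solve_wham(h, tol, max_iter, half_factor, reference,
                 f_init = base$shifts$f)
    )
    list(pmf = prof$pmf, dg = extract_delta_g(prof)$delta_g)
  }

  reps <- withr::with_seed(seed %||% sample.int(.Machine$integer.max, 1), {
    purrr::map(seq_len(n_boot), function(r) {
      tryCatch(run_replicate(), error = function(e) NULL)
    })
  })
  failed <- vapply(reps, is.null, logical(1))
  if (mean(failed) > 0.10) {
    abort(sprintf("%d of %d bootstrap replicates failed.", sum(failed), n_boot))
  }
  reps <- reps[!failed]
  pmat <- do.call(rbind, purrr::map(reps, "pmf"))
  pmat[!is.finite(pmat)] <- NA_real_
  err <- apply(pmat, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) >= 2) sd(col) else NA_real_
  })
  err[!is.finite(base$pmf)] <- NA_real_

  base$err <- err
  base$rel_err <- err / abs(base_dg$delta_g)
  dgs <- vapply(reps, function(r) r$dg, numeric(1))
  base$boot <- list(
    n_boot = n_boot,
    n_failed = sum(failed),
    delta_g = dgs,
    delta_g_se = sd(dgs)
  )
  base
}

#' Convergence of the formation free energy with bin count
#'
#' Re-solves the WHAM equations at several bin counts and extracts the
#' formation free energy for each, to verify the plateau reached once the
#' reaction coordinate is partitioned finely enough (about 100 bins or more
#' on strand-separation profiles).
#'
#' @inheritParams bootstrap_pmf
#' @param bin_counts Bin counts to scan, each >= 2.
#' @param xi_range Optional `c(min, max)` grid limits shared by all scans;
#'   defaults to the [default_grid()] limits.
#' @return A tibble with one row per bin count: `n_bins`, `delta_g`,
#'   `xi_min`, `xi_max`, `converged`, and `below_plateau` flagging counts
#'   under 100.  Attribute `plateau_spread` gives the ΔG range over the
#'   counts >= 100.
#' @export
bin_convergence_scan <- function(windows, bin_counts = c(100, 150, 300, 1000),
                                 burn_in = 0, tol = 1e-6, max_iter = 1e5,
                                 half_factor = TRUE, xi_range = NULL) {
  if (any(bin_counts < 2)) abort("`bin_counts` must each be >= 2.")
  windows <- .validate_windows(windows)
  if (is.null(xi_range)) {
    g0 <- default_grid(windows, half_factor = half_factor)
    xi_range <- c(g0$xi_min, g0$xi_max)
  }
  rows <- purrr::map(bin_counts, function(m) {
    res <- tryCatch(
      {
        grid <- histogram_grid(xi_range[1], xi_range[2], m)
        hists <- build_histograms(windows, grid, burn_in)
        prof <- solve_wham(hists, tol, max_iter, half_factor)
        dg <- extract_delta_g(prof)
        tibble(
          n_bins = as.integer(m), delta_g = dg$delta_g,
          xi_min = dg$xi_min, xi_max = dg$xi_max,
          converged = prof$converged
        )
      },
      error = function(e) {
        abort(sprintf("bin count %d: %s", m, conditionMessage(e)))
      }
    )
    res
  })
  out <- dplyr::bind_rows(rows)
  out$below_plateau <- out$n_bins < 100L
  plateau <- out$delta_g[!out$below_plateau]
  attr(out, "plateau_spread") <- if (length(plateau) >= 2) diff(range(plateau)) else NA_real_
  out
}
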