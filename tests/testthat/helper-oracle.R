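# Independent reference WHAM implementation used as an oracle.
#
# Same estimator, different numerics: everything is accumulated in log space
# with log-sum-exp, shifts are anchored to the first window, and convergence
# is tested on the log-domain shifts.  Intentionally shares no code with the
# package solver.

reference_wham <- function(counts, totals, centers, ks, bin_centers,
                           temperature, half_factor = TRUE,
                           tol = 1e-10, max_iter = 4e5) {
  rt <- 1.987204e-3 * temperature
  nw <- nrow(counts)
  nb <- ncol(counts)
  fac <- if (half_factor) 0.5 else 1
  logw <- matrix(0, nw, nb) # -w/RT at bin centers
  for (i in seq_len(nw)) {
    logw[i, ] <- -fac * ks[i] * (bin_centers - centers[i])^2 / rt
  }
  ctot <- colSums(counts)
  logc <- ifelse(ctot > 0, log(ctot), -Inf)
  logN <- log(totals)
  col_lse <- function(m) {
    cm <- apply(m, 2, max)
    cm + log(colSums(exp(sweep(m, 2, cm))))
  }
  row_lse <- function(m) {
    rm_ <- apply(m, 1, max)
    rm_ + log(rowSums(exp(m - rm_)))
  }
  logf <- numeric(nw) # f_i / RT
  logp <- rep(-Inf, nb)
  for (it in seq_len(max_iter)) {
    logp_new <- logc - col_lse(logN + logf + logw)
    logf_new <- -row_lse(sweep(logw, 2, logp_new, "+"))
    logf_new <- logf_new - logf_new[1]
    done <- max(abs(logf_new - logf)) * rt < tol
    logf <- logf_new
    logp <- logp_new
    if (done) break
  }
  fin <- is.finite(logp)
  z <- max(logp[fin]) + log(sum(exp(logp[fin] - max(logp[fin]))))
  logp <- logp - z
  pmf <- ifelse(is.finite(logp), -rt * logp, Inf)
  list(pmf = pmf, prob = exp(logp), iterations = it)
}

# align two profiles on their common finite bins, return max abs difference
max_aligned_diff <- function(a, b) {
  fin <- is.finite(a) & is.finite(b)
  d <- a[fin] - b[fin]
  max(abs(d - mean(d)))
}

# quick flat-surface model (G == 0 everywhere)
flat_model <- function() {
  model_pmf(
    well_depth = 0, wall_height = 0, barrier_height = 0, plateau_slope = 0
  )
}

# small standard test dataset: bound well + barrier on a short coordinate,
# windows every 0.5 A as in the full layout
small_windows <- function(n = 1500, temperature = 310, seed = 42,
                          xi_hi = 18, spacing = 0.5, ...) {
  truth <- ground_truth(-60, -160)
  simulate_windows(
    truth, temperature,
    centers = seq(0, xi_hi, by = spacing),
    n_per_window = n, seed = seed, ...
  )
}
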