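.read_lines_nonempty <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readLines(path, warn = FALSE)
}

.num_or_abort <- function(tok, path, lineno, what) {
  x <- suppressWarnings(as.numeric(tok))
  if (any(is.na(x))) {
    abort(sprintf("%s, line %d: non-numeric %s `%s`.",
                  path, lineno, what, tok[is.na(x)][1]))
  }
  x
}

#' Read an umbrella-window metadata index
#'
#' Parses the conventional one-window-per-line text index used by WHAM
#' programs: `series_path bias_center bias_constant [temperature]`,
#' whitespace-separated, `#` comments and blank lines skipped.  Relative
#' series paths are resolved against the metadata file's directory.  Window
#' time series are *not* read here; a missing series file only errors when
#' [read_windows()] touches it.
#'
#' @param path Metadata file.
#' @param default_temperature Temperature (K) applied to lines without a
#'   fourth field; required if any line omits it.
#' @return A tibble with columns `series_path`, `bias_center` (A),
#'   `bias_constant` (kcal/(mol A^2)), `temperature` (K), ordered as in the
#'   file.  Within each temperature, bias centers must be strictly
#'   increasing.
#' @export
read_metadata <- function(path, default_temperature = NULL) {
  lines <- .read_lines_nonempty(path)
  base_dir <- dirname(path)
  rows <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (raw == "" || startsWith(raw, "#")) next
    tok <- strsplit(raw, "[[:space:]]+")[[1]]
    if (length(tok) < 3L) {
      abort(sprintf(
        "%s, line %d: expected `path center spring_const [temperature]`, got %d field(s).",
        path, ln, length(tok)
      ))
    }
    center <- .num_or_abort(tok[2], path, ln, "bias center")
    k <- .num_or_abort(tok[3], path, ln, "bias constant")
    temp <- if (length(tok) >= 4L) {
      .num_or_abort(tok[4], path, ln, "temperature")
    } else if (!is.null(default_temperature)) {
      default_temperature
    } else {
      abort(sprintf(
        "%s, line %d: no temperature field and no `default_temperature` given.",
        path, ln
      ))
    }
    sp <- tok[1]
    if (!grepl("^(/|[A-Za-z]:)", sp)) sp <- file.path(base_dir, sp)
    rows[[length(rows) + 1L]] <- tibble(
      series_path = sp, bias_center = center, bias_constant = k,
      temperature = temp
    )
  }
  if (!length(rows)) abort(sprintf("%s: no data lines.", path))
  out <- dplyr::bind_rows(rows)
  if (any(out$bias_center < 0)) abort("bias centers must be >= 0.")
  if (any(out$bias_constant <= 0)) abort("bias constants must be > 0.")
  if (any(out$temperature <= 0)) abort("temperatures must be > 0.")
  bad <- out |>
    dplyr::group_by(.data$temperature) |>
    dplyr::summarise(ok = !is.unsorted(.data$bias_center, strictly = TRUE))
  if (any(!bad$ok)) {
    abort(sprintf(
      "bias centers must be strictly increasing within temperature %.1f K.",
      bad$temperature[!bad$ok][1]
    ))
  }
  out
}

#' Read one window time series
#'
#' Reads a plain-text window file: one or two whitespace-separated numeric
#' columns (`time value` or `value` only), `#` comments and blank lines
#' skipped.
#'
#' @param x A file path, or one row of a [read_metadata()] index (its
#'   `series_path` is used).
#' @return A tibble with columns `time` (ps; `NA` for one-column files) and
#'   `xi` (A).
#' @export
read_timeseries <- function(x) {
  path <- if (is.data.frame(x)) {
    if (nrow(x) != 1L || !"series_path" %in% names(x)) {
      abort("`x` must be a single metadata row with `series_path`.")
    }
    x$series_path
  } else {
    x
  }
  lines <- .read_lines_nonempty(path)
  times <- numeric(0)
  vals <- numeric(0)
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (raw == "" || startsWith(raw, "#")) next
    tok <- strsplit(raw, "[[:space:]]+")[[1]]
    nums <- .num_or_abort(tok, path, ln, "token")
    if (length(nums) == 1L) {
      times <- c(times, NA_real_)
      vals <- c(vals, nums)
    } else {
      times <- c(times, nums[1])
      vals <- c(vals, nums[2])
    }
  }
  if (!length(vals)) abort(sprintf("%s: no samples.", path))
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort(sprintf("%s: reaction-coordinate values must be finite and >= 0.", path))
  }
  tibble(time = times, xi = vals)
}

#' Read all window series of a metadata index
#'
#' @param index A [read_metadata()] tibble.
#' @return The index with a `values` list column added (and `times`), ready
#'   for [build_histograms()].
#' @export
read_windows <- function(index) {
  if (!is.data.frame(index) || !"series_path" %in% names(index)) {
    abort("`index` must come from read_metadata().")
  }
  series <- purrr::map(index$series_path, read_timeseries)
  index$times <- purrr::map(series, "time")
  index$values <- purrr::map(series, "xi")
  as_tibble(index)
}

#' Write / read a PMF table
#'
#' Writes the binned free-energy profile as a tab-separated table: bin center
#' (A), PMF (kcal/mol), bootstrap error (kcal/mol, `NA` if not estimated) and
#' unbiased probability, with a `#` header recording temperature, bin count,
#' convergence tolerance and iteration count.  Values round-trip through
#' [read_pmf_table()] to six decimals.
#'
#' @param profile A `pmf_profile` from [solve_wham()] or [bootstrap_pmf()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pmf_table <- function(profile, path) {
  if (!inherits(profile, "pmf_profile")) abort("`profile` must be a pmf_profile.")
  n <- profile$grid$n_bins
  if (n < 1L || !any(is.finite(profile$pmf))) {
    abort("refusing to write an empty profile.")
  }
  err <- profile$err %||% rep(NA_real_, n)
  header <- c(
    "# whamtherm PMF table",
    sprintf("# temperature_K: %.6f", profile$temperature),
    sprintf("# n_bins: %d", n),
    sprintf("# tol_kcal_mol: %g", profile$tol),
    sprintf("# iterations: %d", profile$iterations),
    sprintf("# converged: %s", profile$converged),
    "# xi_angstrom\tpmf_kcal_mol\terr_kcal_mol\tprob"
  )
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  body <- sprintf(
    "%.6f\t%s\t%s\t%.6e",
    profile$grid$centers, fmt(profile$pmf), fmt(err), profile$prob
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_pmf_table
#' @return For `read_pmf_table()`: a tibble `xi`, `pmf`, `err`, `prob` with
#'   attributes `temperature`, `n_bins`, `tol`, `iterations`, `converged`.
#' @export
read_pmf_table <- function(path) {
  lines <- .read_lines_nonempty(path)
  hdr <- lines[startsWith(lines, "#")]
  pick <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(NA)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(body)) abort(sprintf("%s: no data rows.", path))
  mat <- do.call(rbind, strsplit(body, "\t"))
  out <- tibble(
    xi = as.numeric(mat[, 1]),
    pmf = as.numeric(mat[, 2]),
    err = suppressWarnings(as.numeric(mat[, 3])),
    prob = as.numeric(mat[, 4])
  )
  attr(out, "temperature") <- as.numeric(pick("temperature_K"))
  attr(out, "n_bins") <- as.integer(pick("n_bins"))
  attr(out, "tol") <- as.numeric(pick("tol_kcal_mol"))
  attr(out, "iterations") <- as.integer(pick("iterations"))
  attr(out, "converged") <- identical(pick("converged"), "TRUE")
  out
}

#' Write / read a thermodynamic report
#'
#' Writes the fitted duplex-formation parameters and the per-temperature
#' free energies as a tab-separated report in the field's conventional
#' units: ΔH° and ΔG°37 in kcal/mol, ΔS° in cal/(mol K), Tm in °C.
#'
#' @param fit A `vanthoff_fit` from [fit_gibbs_temperature()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_thermo_report <- function(fit, path) {
  if (!inherits(fit, "vanthoff_fit")) abort("`fit` must be a vanthoff_fit.")
  kv <- c(
    sprintf("duplex_id\t%s", fit$duplex_id),
    sprintf("delta_h_kcal_mol\t%.6f", fit$delta_h),
    sprintf("delta_s_cal_mol_K\t%.6f", fit$delta_s),
    sprintf("dg37_kcal_mol\t%.6f", fit$dg37),
    sprintf("tm_celsius\t%.6f", fit$tm),
    sprintf("r_squared\t%.8f", fit$r_squared),
    sprintf("se_delta_h_kcal_mol\t%.6f", fit$se_delta_h),
    sprintf("se_delta_s_cal_mol_K\t%.6f", fit$se_delta_s),
    sprintf("ct_mol_L\t%g", fit$ct),
    sprintf("self_complementary\t%s", fit$self_complementary),
    sprintf("corrected\t%s", fit$corrected)
  )
  series <- fit$data
  err <- if ("delta_g_err" %in% names(series)) series$delta_g_err else NA_real_
  rows <- sprintf(
    "%.4f\t%.6f\t%s", series$temperature, series$delta_g,
    ifelse(is.na(err), "NA", sprintf("%.6f", err))
  )
  writeLines(
    c("# whamtherm thermodynamic report",
      "# parameter\tvalue", kv,
      "# temperature_K\tdelta_g_kcal_mol\tdelta_g_err_kcal_mol", rows),
    path
  )
  invisible(path)
}

#' @rdname write_thermo_report
#' @return For `read_thermo_report()`: a list with `params` (one-row tibble:
#'   `duplex_id`, `delta_h`, `delta_s`, `dg37`, `tm`, `r_squared`,
#'   `corrected`) and `series` (tibble `temperature`, `delta_g`,
#'   `delta_g_err`).
#' @export
read_thermo_report <- function(path) {
  lines <- .read_lines_nonempty(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "\t")
  is_kv <- vapply(toks, function(t) is.na(suppressWarnings(as.numeric(t[1]))),
                  logical(1))
  kv <- setNames(
    vapply(toks[is_kv], `[`, character(1), 2),
    vapply(toks[is_kv], `[`, character(1), 1)
  )
  series_rows <- toks[!is_kv]
  series <- tibble(
    temperature = vapply(series_rows, function(t) as.numeric(t[1]), numeric(1)),
    delta_g = vapply(series_rows, function(t) as.numeric(t[2]), numeric(1)),
    delta_g_err = vapply(series_rows,
                         function(t) suppressWarnings(as.numeric(t[3])),
                         numeric(1))
  )
  list(
    params = tibble(
      duplex_id = unname(kv[["duplex_id"]]),
      delta_h = as.numeric(kv[["delta_h_kcal_mol"]]),
      delta_s = as.numeric(kv[["delta_s_cal_mol_K"]]),
      dg37 = as.numeric(kv[["dg37_kcal_mol"]]),
      tm = as.numeric(kv[["tm_celsius"]]),
      r_squared = as.numeric(kv[["r_squared"]]),
      corrected = identical(kv[["corrected"]], "TRUE")
    ),
    series = series
  )
}
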