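#' Configuration for an end-to-end WHAM run
#'
#' Bundles every knob of the pipeline with defaults matching the standard
#' protocol: 150 bins, convergence tolerance 1e-6 kcal/mol, Ct = 10 μM, the
#' 273–333 K temperature grid (via the plan), no burn-in.
#'
#' @param metadata_files Character vector of metadata index files (one or
#'   more temperatures per file); alternative to `plan`.
#' @param plan A [simulation_plan()] for a synthetic run; requires `truth`.
#' @param truth A [ground_truth()] used with `plan`.
#' @param out_dir Output directory for PMF tables, the report and the
#'   manifest.
#' @param bins Number of histogram bins.
#' @param tol WHAM convergence tolerance, kcal/mol.
#' @param max_iter WHAM iteration cap.
#' @param n_boot Bootstrap replicates per temperature (0 disables the
#'   bootstrap).
#' @param seed Integer seed for bootstrap resampling (and, with a plan, for
#'   data generation via the plan's own seed).
#' @param ct Total strand concentration, mol/L.
#' @param self_complementary Molecularity flag, see [melting_temperature()].
#' @param burn_in Leading fraction of each series to discard.
#' @param half_factor Bias convention, see [solve_wham()].
#' @param overlap_threshold Adjacent-overlap pass threshold.
#' @param strict_overlap If `TRUE`, an overlap below threshold aborts the run
#'   instead of warning.
#' @param xi_range Optional shared grid limits `c(min, max)`.
#' @param duplex_id Label for the report.
#' @param write_dataset With a plan: also write the raw synthetic window
#'   files to `out_dir/dataset` and analyse the files as read back from disk.
#' @param default_temperature Fallback for metadata lines lacking one.
#' @return A validated `wham_run_config` list.
#' @export
run_config <- function(metadata_files = NULL, plan = NULL, truth = NULL,
                       out_dir = tempfile("whamtherm_run_"), bins = 150,
                       tol = 1e-6, max_iter = 1e5, n_boot = 0, seed = 1,
                       ct = 1e-5, self_complementary = FALSE, burn_in = 0,
                       half_factor = TRUE, overlap_threshold = 0.20,
                       strict_overlap = FALSE, xi_range = NULL,
                       duplex_id = "duplex", write_dataset = FALSE,
                       default_temperature = NULL) {
  if (is.null(metadata_files) && is.null(plan)) {
    abort("give either `metadata_files` or a simulation `plan`.")
  }
  if (!is.null(plan)) {
    if (!inherits(plan, "simulation_plan")) abort("`plan` must be a simulation_plan.")
    if (!inherits(truth, "ground_truth")) {
      abort("a simulation `plan` requires a `truth` (see ground_truth()).")
    }
  }
  if (!is.null(metadata_files) && !all(file.exists(metadata_files))) {
    abort("some `metadata_files` do not exist.")
  }
  .stopifnot_scalar_num(tol, "tol", positive = TRUE)
  .stopifnot_scalar_num(ct, "ct", positive = TRUE)
  if (bins < 2) abort("`bins` must be >= 2.")
  if (n_boot != 0 && n_boot < 2) abort("`n_boot` must be 0 or >= 2.")
  if (burn_in < 0 || burn_in >= 1) abort("`burn_in` must be in [0, 1).")
  structure(
    list(
      metadata_files = metadata_files, plan = plan, truth = truth,
      out_dir = out_dir, bins = as.integer(bins), tol = tol,
      max_iter = max_iter, n_boot = as.integer(n_boot),
      seed = as.integer(seed), ct = ct,
      self_complementary = isTRUE(self_complementary), burn_in = burn_in,
      half_factor = isTRUE(half_factor),
      overlap_threshold = overlap_threshold,
      strict_overlap = isTRUE(strict_overlap), xi_range = xi_range,
      duplex_id = duplex_id, write_dataset = isTRUE(write_dataset),
      default_temperature = default_temperature
    ),
    class = "wham_run_config"
  )
}

.stage <- function(name, temperature, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage `%s` failed at T = %.1f K: %s",
                  name, temperature, conditionMessage(e)))
  })
}

#' Run the full analysis protocol
#'
#' Per temperature: bin the windows, check adjacent histogram overlap (warn
#' below threshold, or abort under `strict_overlap`), solve the WHAM
#' equations (with bootstrap errors if requested), write the PMF table and
#' extract the formation free energy.  Then fit the van't Hoff line over
#' temperatures, write the thermodynamic report, and record a manifest
#' (config, seed, versions, output checksums) sufficient to re-run the
#' pipeline identically.
#'
#' @param config A [run_config()].
#' @return A `wham_pipeline` list: `delta_g` table, the `fit`, `profiles`,
#'   `overlaps`, output `paths`, and the `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "wham_run_config")) abort("`config` must come from run_config().")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  ## gather windows grouped by temperature
  if (!is.null(config$plan)) {
    plan <- config$plan
    if (config$write_dataset) {
      ds_dir <- file.path(config$out_dir, "dataset")
      idx <- generate_dataset(plan, config$truth, ds_dir,
                              half_factor = config$half_factor)
      window_sets <- purrr::map(idx$metadata_path, function(p) {
        read_windows(read_metadata(p))
      })
      temperatures <- idx$temperature
    } else {
      temperatures <- plan$temperatures
      window_sets <- purrr::imap(temperatures, function(temp, t_idx) {
        simulate_windows(
          config$truth, temp, plan$centers, plan$bias_constant,
          plan$n_per_window, seed = plan$seed + 1000L * t_idx,
          mode = plan$sampling_mode, ar1_corr = plan$ar1_corr,
          half_factor = config$half_factor
        )
      })
    }
  } else {
    meta <- dplyr::bind_rows(purrr::map(
      config$metadata_files, read_metadata,
      default_temperature = config$default_temperature
    ))
    all_windows <- read_windows(meta)
    temperatures <- sort(unique(all_windows$temperature))
    window_sets <- purrr::map(temperatures, function(temp) {
      dplyr::filter(all_windows, .data$temperature == temp)
    })
  }

  xi_range <- config$xi_range
  if (is.null(xi_range)) {
    g0 <- default_grid(window_sets[[1]], config$bins, config$half_factor)
    xi_range <- c(g0$xi_min, g0$xi_max)
  }
  grid <- histogram_grid(xi_range[1], xi_range[2], config$bins)

  profiles <- list()
  overlaps <- list()
  dg_rows <- list()
  pmf_paths <- character(0)
  for (j in seq_along(temperatures)) {
    temp <- temperatures[j]
    windows <- window_sets[[j]]
    hists <- .stage("histograms", temp,
                    build_histograms(windows, grid, config$burn_in))
    ov <- .stage("overlap", temp,
                 adjacent_overlap(hists, config$overlap_threshold))
    if (!attr(ov, "all_pass")) {
      msg <- sprintf(
        "T = %.1f K: minimum adjacent overlap %.3f is below %.2f.",
        temp, attr(ov, "min_overlap"), attr(ov, "threshold")
      )
      if (config$strict_overlap) abort(paste("stage `overlap`:", msg)) else warn(msg)
    }
    prof <- .stage("wham", temp, {
      if (config$n_boot >= 2) {
        bootstrap_pmf(
          windows, grid, config$burn_in, config$tol, config$max_iter,
          config$half_factor, n_boot = config$n_boot,
          seed = config$seed + j
        )
      } else {
        solve_wham(hists, config$tol, config$max_iter, config$half_factor)
      }
    })
    pmf_path <- file.path(config$out_dir,
                          sprintf("pmf_T%03d.tsv", as.integer(round(temp))))
    .stage("write_pmf", temp, write_pmf_table(prof, pmf_path))
    dg <- .stage("extract_delta_g", temp, extract_delta_g(prof))
    dg$temperature <- temp
    dg$delta_g_err <- if (!is.null(prof$boot)) prof$boot$delta_g_se else NA_real_
    profiles[[j]] <- prof
    overlaps[[j]] <- ov
    dg_rows[[j]] <- dg
    pmf_paths <- c(pmf_paths, pmf_path)
  }

  series <- dplyr::bind_rows(dg_rows) |>
    dplyr::select("temperature", "delta_g", "delta_g_err",
                  "xi_min", "xi_max")
  fit <- fit_gibbs_temperature(series, config$ct, config$self_complementary,
                               duplex_id = config$duplex_id)
  report_path <- file.path(config$out_dir, "thermo_report.tsv")
  write_thermo_report(fit, report_path)

  out_files <- c(pmf_paths, report_path)
  manifest <- list(
    package = "whamtherm",
    version = as.character(utils::packageVersion("whamtherm")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config[!(names(config) %in% c("plan", "truth"))],
    plan = if (!is.null(config$plan)) unclass(config$plan) else NULL,
    truth = if (!is.null(config$truth)) {
      list(delta_h = config$truth$delta_h, delta_s = config$truth$delta_s)
    } else NULL,
    temperatures = temperatures,
    checksums = as.list(tools::md5sum(out_files))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")

  structure(
    list(
      delta_g = series,
      fit = fit,
      profiles = setNames(profiles, sprintf("T%g", temperatures)),
      overlaps = setNames(overlaps, sprintf("T%g", temperatures)),
      paths = list(pmf = pmf_paths, report = report_path,
                   manifest = manifest_path, out_dir = config$out_dir),
      manifest = manifest
    ),
    class = "wham_pipeline"
  )
}

#' @export
print.wham_pipeline <- function(x, ...) {
  cat(sprintf("<wham_pipeline> %d temperatures -> %s\n",
              nrow(x$delta_g), x$paths$out_dir))
  print(x$fit)
  invisible(x)
}
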