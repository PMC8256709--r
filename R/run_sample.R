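# Per-sample orchestration: segmentation -> per-window peak histograms ->
# average-profile step-model fit -> asymmetry -> gap-fraction landscape.

#' Analysis run configuration
#'
#' Bundles every tunable of the per-sample pipeline. Defaults equal the
#' published analysis settings where one exists: starting overlap fraction
#' 0.46, at most 10 outer fit iterations, grid steps of 0.001 in
#' `delta_rho` and `sigma`, 0.1 nm in `D` and `w`, 0.01 in `c`; asymmetry
#' orders up to 9; 4 segmentation subsets.
#'
#' @param fit_range Optional `c(q_min, q_max)` for the step-model fit.
#' @param max_iter Maximum outer fit iterations.
#' @param delta_rho_step,sigma_step,D_step,w_step,c_step Coordinate-descent
#'   grid steps.
#' @param sigma0 Starting overlap fraction.
#' @param windows Character vector of [peak_window] names to analyse.
#' @param max_order Highest diffraction order in the asymmetry value.
#' @param asymmetry_mode `"area"` or `"odd_heights"` (see
#'   [asymmetry_value()]).
#' @param k Number of segmentation subsets.
#' @param sigma_grid Overlap-fraction grid for the error landscape.
#' @param seed Seed for the seeded stages (segmentation).
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(fit_range = NULL, max_iter = 10L,
                       delta_rho_step = 0.001, sigma_step = 0.001,
                       D_step = 0.1, w_step = 0.1, c_step = 0.01,
                       sigma0 = 0.46,
                       windows = c("waxs_equatorial", "waxs_meridional",
                                   "saxs_meridional_9th",
                                   "saxs_equatorial_fibril"),
                       max_order = 9L,
                       asymmetry_mode = "area",
                       k = 4L,
                       sigma_grid = seq(0.3, 0.7, by = 0.005),
                       seed = 1L, log_level = "info") {
  structure(list(fit_range = fit_range, max_iter = as.integer(max_iter),
                 delta_rho_step = delta_rho_step, sigma_step = sigma_step,
                 D_step = D_step, w_step = w_step, c_step = c_step,
                 sigma0 = sigma0, windows = windows,
                 max_order = as.integer(max_order),
                 asymmetry_mode = asymmetry_mode, k = as.integer(k),
                 sigma_grid = sigma_grid, seed = as.integer(seed),
                 log_level = log_level),
            class = "run_config")
}

#' Serialise or parse a run configuration
#'
#' JSON round trip for [run_config()]; serialise -> parse -> serialise is
#' idempotent.
#'
#' @param config A [run_config].
#' @param path File path.
#' @return `read_config` returns a [run_config]; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$fit_range <- if (is.null(x$fit_range)) NULL else as.numeric(x$fit_range)
  do.call(run_config, x)
}

.log_msg <- function(config, ...) {
  if (identical(config$log_level, "info")) message(sprintf(...))
}

#' Run the full per-sample analysis
#'
#' Orchestrates the standard per-sample workflow on a scanned sample:
#' segmentation of the SAXS (and, when given, WAXS) scan; per-pixel
#' single-peak fits and histogram condensation for each configured length
#' scale window; step-density model fit of the average SAXS profile;
#' diffraction-order indexing and the even/odd asymmetry value; and the
#' gap-fraction RMSE landscape around the fit. Stage failures are caught
#' and recorded per stage; the report marks incomplete stages rather than
#' aborting.
#'
#' @param scan_saxs A SAXS [scan_grid].
#' @param scan_waxs Optional WAXS [scan_grid] of the same sample.
#' @param config A [run_config].
#' @param out_dir Optional directory; when given, the report
#'   (`report.json`), segmentation labels (`labels.csv`), per-window peak
#'   tables, the landscape (`landscape.csv`) and the average profile are
#'   written there.
#' @return An object of class `sample_report` (a list): `stages` (status
#'   per stage), `segmentation`, `histograms`, `fit`, `orders`,
#'   `asymmetry`, `landscape`, `config`, `seed`.
#' @export
run_sample <- function(scan_saxs, scan_waxs = NULL, config = run_config(),
                       out_dir = NULL) {
  stopifnot(inherits(scan_saxs, "scan_grid"))
  stages <- list()
  report <- list(config = config, seed = config$seed)

  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      structure(list(message = conditionMessage(e)), class = "stage_error")
    })
    stages[[name]] <<- if (inherits(res, "stage_error")) {
      paste("failed:", res$message)
    } else "ok"
    res
  }

  seg <- run_stage("segmentation", {
    out <- list(saxs = segment_scan(scan_saxs, k = config$k,
                                    seed = config$seed))
    if (!is.null(scan_waxs)) {
      out$waxs <- segment_scan(scan_waxs, k = config$k, seed = config$seed)
    }
    out
  })
  report$segmentation <- seg

  hist_out <- list()
  peak_tables <- list()
  for (wname in config$windows) {
    grid <- if (startsWith(wname, "waxs")) scan_waxs else scan_saxs
    if (is.null(grid)) {
      stages[[paste0("peaks_", wname)]] <- "skipped: no grid for modality"
      next
    }
    res <- run_stage(paste0("peaks_", wname), {
      tab <- scan_peaks(grid, peak_window(wname))
      list(table = tab, summary = summarize_histogram(tab))
    })
    if (!inherits(res, "stage_error") && !is.null(res$summary)) {
      peak_tables[[wname]] <- res$table
      hist_out[[wname]] <- res$summary
    }
  }
  report$histograms <- hist_out

  avg <- average_profile(scan_saxs)
  fit <- run_stage("step_fit", {
    fit_profile(avg, fit_range = config$fit_range,
                max_iter = config$max_iter,
                steps = list(delta_rho = config$delta_rho_step,
                             w = config$w_step, c = config$c_step,
                             D = config$D_step, sigma = config$sigma_step),
                sigma0 = config$sigma0)
  })
  if (!inherits(fit, "stage_error")) report$fit <- fit

  orders <- run_stage("asymmetry", {
    tab <- index_orders(avg, D_init = if (!inherits(fit, "stage_error")) {
      fit$params$D
    } else NULL)
    list(orders = tab,
         asymmetry = asymmetry_value(tab, max_order = config$max_order,
                                     mode = config$asymmetry_mode))
  })
  if (!inherits(orders, "stage_error")) {
    report$orders <- orders$orders
    report$asymmetry <- orders$asymmetry
  }

  land <- run_stage("landscape", {
    if (inherits(fit, "stage_error")) stop("no fit available")
    sigma_landscape(avg, fit, sigma_grid = config$sigma_grid)
  })
  if (!inherits(land, "stage_error")) report$landscape <- land

  report$stages <- stages
  class(report) <- "sample_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_profile(avg, file.path(out_dir, "average_saxs.txt"))
    if (!inherits(seg, "stage_error")) {
      lab <- seg$saxs$index
      lab$label <- seg$saxs$labels
      lab <- cbind(lab, as.data.frame(seg$saxs$scores[, 1:min(3, ncol(seg$saxs$scores)), drop = FALSE]))
      utils::write.csv(lab, file.path(out_dir, "labels.csv"),
                       row.names = FALSE)
    }
    for (wname in names(peak_tables)) {
      utils::write.csv(peak_tables[[wname]],
                       file.path(out_dir, paste0("peaks_", wname, ".csv")),
                       row.names = FALSE)
    }
    if (!inherits(land, "stage_error")) {
      utils::write.csv(as.data.frame(land),
                       file.path(out_dir, "landscape.csv"),
                       row.names = FALSE)
    }
    writeLines(report_json(report), file.path(out_dir, "report.json"))
  }
  report
}

#' JSON rendering of a sample report
#'
#' Deterministic (timestamp-free) JSON summary of a [run_sample()] report:
#' stage statuses, segmentation abundances, histogram summaries, fitted
#' step-model parameters, asymmetry value and landscape minimum.
#'
#' @param report A `sample_report`.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  stopifnot(inherits(report, "sample_report"))
  out <- list(seed = report$seed, stages = report$stages)
  if (!is.null(report$segmentation$saxs)) {
    out$segmentation <- list(
      k = report$segmentation$saxs$k,
      abundance = report$segmentation$saxs$abundance,
      explained_variance = report$segmentation$saxs$explained_variance)
  }
  if (length(report$histograms)) {
    out$histograms <- lapply(report$histograms, function(h) {
      list(weighted_position = h$weighted_position,
           weighted_fwhm = h$weighted_fwhm,
           weighted_d = h$weighted_d,
           n_components = h$n_components,
           n_values = h$n_values)
    })
  }
  if (!is.null(report$fit)) {
    out$fit <- c(unclass(report$fit$params),
                 list(r_squared = report$fit$r_squared,
                      rmse = report$fit$rmse,
                      n_iterations = report$fit$n_iterations,
                      converged = report$fit$converged))
  }
  if (!is.null(report$asymmetry)) {
    out$asymmetry <- list(value = report$asymmetry$value,
                          D_est = report$asymmetry$D_est,
                          even_orders = report$asymmetry$even_orders_used,
                          odd_orders = report$asymmetry$odd_orders_used)
  }
  if (!is.null(report$landscape)) {
    out$landscape_min_gap_fraction <- landscape_minimum(report$landscape)
  }
  as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' @export
print.sample_report <- function(x, ...) {
  cat("<sample_report>\n")
  for (nm in names(x$stages)) cat(sprintf("  %-28s %s\n", nm, x$stages[[nm]]))
  if (!is.null(x$asymmetry)) {
    cat(sprintf("  asymmetry value: %.4g, D_est = %.2f nm\n",
                x$asymmetry$value, x$asymmetry$D_est))
  }
  invisible(x)
}
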