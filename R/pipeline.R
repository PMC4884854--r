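#' Experiment configuration
#'
#' Bundles every setting of the compression-SWEI experiment.  The
#' `"reference"` preset reproduces the full study: 100 x 40 mm
#' semi-elliptical phantom with a 10 mm tumor, compression levels 0, 10,
#' 20, 30 %, 3 mm / 180 us midline push, 40 ms record at 125 us / 0.2 mm
#' resolution, 3 mm TOF kernels with 2 x 2 mm median smoothing.  The
#' `"fast"` preset coarsens the grids and shortens the record for quick
#' checks.
#'
#' @param preset `"reference"` or `"fast"`.
#' @param ... overrides of individual fields.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(preset = c("reference", "fast"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    phantom = list(width = 100, height = 40, tumor_center = c(12, 20),
                   tumor_diameter = 10, spacing = 1),
    levels = c(0, 0.1, 0.2, 0.3),
    excitation = excitation_spec(),
    record_ms = 40,
    record_dt = 125e-6,
    out_spacing = 0.2,
    engine = "sh",
    kernels = list(x = 3, y = 3, median = 2),
    tof = list(arrival_on = "velocity", front_vmin = 0.3, min_offset = 2),
    roi = list(surr_center = NULL, surr_diameter = NULL),
    control = compression_control(),
    density = 1000,
    seed = 1L)
  if (preset == "fast") {
    cfg$phantom$spacing <- 2
    cfg$out_spacing <- 0.4
    cfg$record_ms <- 30
    cfg$levels <- c(0, 0.3)
  }
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  if (is.unsorted(cfg$levels) || any(cfg$levels < 0 | cfg$levels > 0.35))
    nlswei_abort("levels must be ascending, within [0, 0.35]",
                 "nlswei_invalid_input")
  class(cfg) <- "experiment_config"
  cfg
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> levels %s; mesh %g mm, grid %g mm, record %g ms\n",
    paste(x$levels, collapse = "/"), x$phantom$spacing, x$out_spacing,
    x$record_ms))
  invisible(x)
}

#' Run the compression-SWEI experiment end to end
#'
#' For each compression level: static platen compression, shear-wave
#' simulation on the deformed, pre-strained medium, directional
#' filtering, time-of-flight reconstruction, and modulus mapping;
#' finally the per-level contrast report.  The pipeline is deterministic
#' given the configuration.
#'
#' @param config an [experiment_config()].
#' @param phantom optionally a pre-built phantom (overrides
#'   `config$phantom`).
#' @param outdir if given, per-level modulus maps (CSV), profile traces
#'   and the report are written there.
#' @param keep_records keep the (large) space-time displacement records
#'   in the returned object.
#' @param quiet suppress progress messages.
#' @return list with `report` (a `contrast_report`), `maps`, `states`,
#'   `phantom`, `config` and optionally `records`.
#' @export
run_experiment <- function(config = experiment_config(), phantom = NULL,
                           outdir = NULL, keep_records = FALSE,
                           quiet = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  if (is.null(phantom)) phantom <- do.call(build_phantom, config$phantom)
  t0 <- proc.time()[["elapsed"]]
  states <- staged_compression(phantom, config$levels, config$control)
  say("compression solved in %.1f s", proc.time()[["elapsed"]] - t0)
  maps <- vector("list", length(states))
  records <- if (keep_records) vector("list", length(states)) else NULL
  for (k in seq_along(states)) {
    tk <- proc.time()[["elapsed"]]
    rec <- simulate_wave(states[[k]], phantom, config$excitation,
                         record_ms = config$record_ms,
                         record_dt = config$record_dt,
                         out_spacing = config$out_spacing,
                         engine = config$engine, roi = config$roi)
    recf <- directional_filter(rec, "forward")
    sp <- tof_speed(recf, x_kernel = config$kernels$x,
                    y_kernel = config$kernels$y,
                    median_kernel = config$kernels$median,
                    arrival_on = config$tof$arrival_on,
                    front_vmin = config$tof$front_vmin,
                    min_offset = config$tof$min_offset)
    maps[[k]] <- modulus_map(sp, config$density)
    if (keep_records) records[[k]] <- rec
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      gk <- maps[[k]]$modulus / 1e3
      write.csv(gk, file.path(outdir, sprintf("modulus_map_L%02.0f.csv",
                                              100 * config$levels[k])),
                row.names = FALSE)
      pro <- try(extract_profiles(rec, c(10.2, 13.3, 20.2, 23.3), 20),
                 silent = TRUE)
      if (!inherits(pro, "try-error"))
        write.csv(pro, file.path(outdir, sprintf("profiles_L%02.0f.csv",
                                                 100 * config$levels[k])),
                  row.names = FALSE)
    }
    say("level %.2f reconstructed in %.1f s", config$levels[k],
        proc.time()[["elapsed"]] - tk)
    rm(rec, recf); gc(FALSE)
  }
  report <- build_report(maps, states, phantom,
                         config$roi$surr_center, config$roi$surr_diameter)
  if (!is.null(outdir)) write_report(report, file.path(outdir, "report.csv"))
  out <- list(report = report, maps = maps, states = states,
              phantom = phantom, config = config)
  if (keep_records) out$records <- records
  out
}

#' Ratio of speed-increase factors, tumor versus background
#'
#' From the report's ROI-averaged moduli between the lowest and highest
#' level present: \eqn{(c_{in}(30)/c_{in}(0)) / (c_{out}(30)/c_{out}(0))}
#' with \eqn{c = \sqrt{G/\rho}}, i.e. the square root of the modulus
#' increase-factor ratio.
#'
#' @param report a `contrast_report` containing both levels.
#' @param from,to compression levels to compare (defaults: first and
#'   last row).
#' @return dimensionless ratio; > 1 when the tumor speeds up more.
#' @export
speed_increase_ratio <- function(report, from = NULL, to = NULL) {
  stopifnot(inherits(report, "contrast_report"))
  from <- from %||% min(report$level)
  to <- to %||% max(report$level)
  r0 <- report[report$level == from, ]
  r1 <- report[report$level == to, ]
  if (nrow(r0) != 1 || nrow(r1) != 1)
    nlswei_abort("report must contain the requested levels",
                 "nlswei_invalid_input")
  sqrt((r1$g_tumor / r0$g_tumor) / (r1$g_surr / r0$g_surr))
}
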