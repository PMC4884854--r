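#' Frequency-wavenumber directional filter
#'
#' Separates waves by lateral propagation direction: for each depth row
#' the (time, x) plane is transformed to the frequency-wavenumber
#' domain, the two quadrants carrying the rejected direction are zeroed
#' (hard mask; the zero-frequency and zero-wavenumber lines are kept),
#' and the record is transformed back.  Used to remove reflections from
#' the lateral boundaries before time-of-flight estimation.
#'
#' @param record a `wave_record`, uniformly sampled in t and x.
#' @param keep `"forward"` keeps waves moving toward +x, `"backward"`
#'   the opposite.
#' @return a filtered `wave_record`.
#' @export
directional_filter <- function(record, keep = c("forward", "backward")) {
  stopifnot(inherits(record, "wave_record"))
  keep <- match.arg(keep)
  d <- dim(record$u)
  nt <- d[1]; nx <- d[2]
  if (nt < 8 || nx < 8)
    nlswei_abort("record too short in t or x for a meaningful spectrum",
                 "nlswei_invalid_input")
  ft <- c(0:floor(nt / 2), -((ceiling(nt / 2) - 1):1))
  fx <- c(0:floor(nx / 2), -((ceiling(nx / 2) - 1):1))
  s <- outer(sign(ft), sign(fx))
  # a wave exp(i(kx - wt)) moving toward +x carries sign(f_t)*sign(f_x) < 0
  drop <- if (keep == "forward") s > 0 else s < 0
  # the zero-wavenumber column carries no laterally propagating signal,
  # only whole-column motion (quasi-static offsets, base reverberation);
  # removing it cleans the arrival picking without touching moving waves
  drop[, fx == 0] <- TRUE
  out <- record
  for (iy in seq_len(d[3])) {
    S <- fft(record$u[, , iy])
    S[drop] <- 0
    out$u[, , iy] <- Re(fft(S, inverse = TRUE)) / (nt * nx)
  }
  out$provenance$directional_filter <- keep
  out
}

#' Time-of-flight shear-wave speed map
#'
#' Arrival times (time of peak displacement magnitude, with optional
#' 3-point parabolic refinement) are picked at every lateral position,
#' averaged over a depth kernel, and a straight line is fitted to
#' lateral position versus arrival time within a sliding lateral window;
#' the slope is the local speed.  The map is then smoothed with a median
#' filter.  Cells where the fit is degenerate (too few valid arrivals,
#' non-positive or out-of-range slope) are masked `NA`.
#'
#' @param record a (directionally filtered) `wave_record`.
#' @param x_kernel lateral fitting window (mm).
#' @param y_kernel depth averaging window (mm).
#' @param median_kernel median smoothing window (mm).
#' @param side reconstruct on which side of the push (`"right"` follows
#'   waves moving toward +x).
#' @param min_offset exclude columns closer than this to the push (mm).
#' @param rel_thresh arrival picking amplitude threshold, relative to
#'   the record peak.
#' @param refine parabolic sub-sample refinement of arrival times.
#' @param arrival_on pick the peak of the particle `"velocity"` (default;
#'   robust to the quasi-static displacement offset left behind the
#'   front by a full-depth push) or of the raw `"displacement"`.
#' @param front_vmin slowest physical speed (m/s) assumed by the
#'   front-tracking search window; arrivals are looked for no later than
#'   `dx / front_vmin` past the previous lateral position's arrival,
#'   which keeps the picker immune to late reverberant energy.
#' @param aggregate depth aggregation: average arrival times before
#'   fitting (`"arrival"`, default) or median-average row speeds after
#'   fitting (`"speed"`).
#' @param speed_range admissible speeds (m/s); estimates outside are
#'   masked.
#' @return object of class `speed_map` with the speed array (x by y,
#'   m/s), validity mask and kernel metadata.
#' @export
tof_speed <- function(record, x_kernel = 3, y_kernel = 3, median_kernel = 2,
                      side = c("right", "left"), min_offset = 2,
                      rel_thresh = 0.02, refine = TRUE,
                      arrival_on = c("velocity", "displacement"),
                      front_vmin = 0.3,
                      aggregate = c("arrival", "speed"),
                      speed_range = c(0.05, 100)) {
  stopifnot(inherits(record, "wave_record"))
  side <- match.arg(side)
  aggregate <- match.arg(aggregate)
  arrival_on <- match.arg(arrival_on)
  h <- record$h
  w <- record$u
  if (arrival_on == "velocity") {
    d <- dim(w)
    w <- (w[c(2:d[1], d[1]), , , drop = FALSE] -
            w[c(1, 1:(d[1] - 1)), , , drop = FALSE])
  }
  if (side == "left") {
    w <- w[, rev(seq_len(dim(w)[2])), , drop = FALSE]  # march along -x
    xrel <- rev(record$push_x - record$x)
  } else {
    xrel <- record$x - record$push_x
  }
  # exclude the first/last frames, where the hard spectral mask leaves
  # wrap-around ringing
  nt <- dim(record$u)[1]
  trim <- max(3L, as.integer(ceiling(0.02 * nt)))
  istart <- which(xrel >= mm(min_offset))[1]
  if (is.na(istart))
    nlswei_abort("no columns on the requested side of the push",
                 "nlswei_invalid_input")
  arr <- cpp_front_arrival(w, record$dt, h, rel_thresh, refine, 2L,
                           nt - 1L - trim, istart - 1L, xrel[istart],
                           front_vmin, 2L, 0L, 0.5)
  rm(w)
  msk <- if (side == "left") record$mask[rev(seq_len(nrow(record$mask))), ,
                                         drop = FALSE] else record$mask
  arr[!msk] <- NA_real_
  hw_x <- max(1L, as.integer(round(mm(x_kernel) / h / 2)))
  hw_y <- max(1L, as.integer(round(mm(y_kernel) / h / 2)))
  hw_m <- max(1L, as.integer(round(mm(median_kernel) / h / 2)))
  if (aggregate == "arrival") {
    arr_s <- cpp_movmean_y(arr, hw_y, hw_y + 1L)
    speed <- cpp_tof_slope(arr_s, h, hw_x, 3L, speed_range[1], speed_range[2])
  } else {
    speed <- cpp_tof_slope(arr, h, hw_x, 3L, speed_range[1], speed_range[2])
    speed <- cpp_movmean_y(speed, hw_y, hw_y + 1L)
  }
  speed <- cpp_median2d(speed, hw_m, 3L)
  if (side == "left") speed <- speed[rev(seq_len(nrow(speed))), , drop = FALSE]
  structure(list(speed = speed, x = record$x, y = record$y, h = h,
                 label = record$label, valid = is.finite(speed),
                 kernels = list(x = x_kernel, y = y_kernel,
                                median = median_kernel,
                                aggregate = aggregate, side = side,
                                arrival_on = arrival_on),
                 compression_level = record$compression_level,
                 density = record$density),
            class = "speed_map")
}

#' @export
print.speed_map <- function(x, ...) {
  cat(sprintf("<speed_map> %d x %d grid, %.0f%% valid, level %s\n",
              nrow(x$speed), ncol(x$speed), 100 * mean(x$valid),
              format(x$compression_level)))
  invisible(x)
}

#' Shear modulus map from a speed map
#'
#' Applies \eqn{G = \rho c^2} cell-wise, preserving the validity mask.
#'
#' @param speed a [tof_speed()] map.
#' @param density medium density (kg/m^3); defaults to the value carried
#'   by the record.
#' @return object of class `modulus_map` (modulus in Pa).
#' @export
modulus_map <- function(speed, density = NULL) {
  stopifnot(inherits(speed, "speed_map"))
  density <- density %||% speed$density
  if (!is.finite(density) || density <= 0)
    nlswei_abort("density must be positive", "nlswei_invalid_input")
  structure(list(modulus = density * speed$speed^2, x = speed$x, y = speed$y,
                 h = speed$h, label = speed$label, valid = speed$valid,
                 density = density,
                 compression_level = speed$compression_level,
                 kernels = speed$kernels),
            class = "modulus_map")
}

#' @export
print.modulus_map <- function(x, ...) {
  cat(sprintf("<modulus_map> %d x %d grid, level %s, median %.3g kPa\n",
              nrow(x$modulus), ncol(x$modulus), format(x$compression_level),
              median(x$modulus[x$valid]) / 1e3))
  invisible(x)
}

#' ROI means over a reconstructed map
#'
#' @param map a `modulus_map` or `speed_map`.
#' @param which ROI: `"tumor"` (grid label 2) or `"surrounding"` (grid
#'   label 3).
#' @return named vector with `mean`, `sd`, `n`.
#' @export
roi_mean <- function(map, which = c("tumor", "surrounding")) {
  which <- match.arg(which)
  val <- if (inherits(map, "modulus_map")) map$modulus else map$speed
  lab <- if (which == "tumor") 2L else 3L
  sel <- !is.na(map$label) & map$label == lab & map$valid
  if (!any(sel)) nlswei_abort("empty ROI on the map", "nlswei_invalid_input")
  c(mean = mean(val[sel]), sd = sd(val[sel]), n = sum(sel))
}

#' Shear modulus contrast
#'
#' \eqn{C = (G_{tumor} - G_{surr}) / G_{surr}}.
#'
#' @param g_tumor,g_surr ROI-averaged shear moduli (same units).
#' @return dimensionless contrast.
#' @examples
#' contrast(6, 4)  # 0.5
#' @export
contrast <- function(g_tumor, g_surr) {
  check_finite(c(g_tumor, g_surr), "moduli")
  if (any(g_surr <= 0))
    nlswei_abort("surrounding modulus must be positive", "nlswei_invalid_input")
  (g_tumor - g_surr) / g_surr
}

#' Per-level contrast report
#'
#' Combines reconstructed modulus maps and static solutions into the
#' summary table: ROI-averaged moduli (tumor disc and the surrounding
#' disc tracked through the deformation), developed strains and vertical
#' stresses from the static solve, and the modulus contrast per level.
#'
#' @param maps list of `modulus_map`, one per level.
#' @param states list of `deformed_state`, same levels, same order.
#' @param phantom the phantom both were computed on.
#' @param surr_center,surr_diameter surrounding-ROI placement for the
#'   static summaries, see [roi_statistics()].
#' @return data.frame of class `contrast_report`; moduli/stresses in
#'   kPa, strains in percent, ordered by level.
#' @export
build_report <- function(maps, states, phantom, surr_center = NULL,
                         surr_diameter = NULL) {
  if (length(maps) != length(states))
    nlswei_abort("maps and states must have the same length",
                 "nlswei_invalid_input")
  lv_m <- vapply(maps, function(m) m$compression_level, numeric(1))
  lv_s <- vapply(states, function(s) s$compression_level, numeric(1))
  if (!isTRUE(all.equal(lv_m, lv_s)))
    nlswei_abort("compression levels of maps and states disagree",
                 "nlswei_invalid_input")
  rows <- lapply(seq_along(maps), function(k) {
    gt <- roi_mean(maps[[k]], "tumor")
    gs <- roi_mean(maps[[k]], "surrounding")
    st <- roi_statistics(states[[k]], phantom, surr_center, surr_diameter)
    data.frame(level = lv_m[k],
               g_tumor = gt[["mean"]] / 1e3, g_tumor_sd = gt[["sd"]] / 1e3,
               g_surr = gs[["mean"]] / 1e3, g_surr_sd = gs[["sd"]] / 1e3,
               strain_tumor = 100 * st$strain[st$tissue == "tumor"],
               strain_surr = 100 * st$strain[st$tissue == "surrounding"],
               contrast = contrast(gt[["mean"]], gs[["mean"]]),
               stress_tumor = st$stress[st$tissue == "tumor"] / 1e3,
               stress_surr = st$stress[st$tissue == "surrounding"] / 1e3)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$level), ]
  rownames(out) <- NULL
  class(out) <- c("contrast_report", "data.frame")
  out
}

#' Write a contrast report as CSV
#' @param report a `contrast_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
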