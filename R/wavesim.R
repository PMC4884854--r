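#' Body-force excitation settings
#'
#' The acoustic-radiation-force push is idealized as a downward body
#' force applied over a narrow vertical band through the entire depth of
#' the model for a short duration (rectangular in time, uniform over the
#' band).
#'
#' @param center_x lateral position of the band center (mm); 0 is the
#'   model midline.
#' @param width band width (mm).
#' @param duration push duration (s).
#' @param amplitude force density (N/m^3); when `NULL`, scaled so the
#'   peak displacement is of order 10 um (the choice is irrelevant to
#'   reconstructed speeds, the propagation solve being linear).
#' @return object of class `excitation_spec`.
#' @export
excitation_spec <- function(center_x = 0, width = 3, duration = 180e-6,
                            amplitude = NULL) {
  if (width <= 0 || duration <= 0)
    nlswei_abort("width and duration must be positive", "nlswei_invalid_input")
  structure(list(center_x = mm(center_x), width = mm(width),
                 duration = duration, amplitude = amplitude),
            class = "excitation_spec")
}

#' Shear-wave propagation through the (pre-strained) phantom
#'
#' Linear elastodynamics superposed on the static pre-strain: the
#' per-element tangent shear modulus field is mapped onto a regular grid
#' over the deformed geometry and an explicit (leapfrog) solver is run
#' with CFL-stable internal substeps, recording vertical displacement at
#' the requested output interval.  The base is clamped; all other
#' boundaries are traction-free (reflections are physical and are later
#' removed by the directional filter).  No attenuation term is included.
#'
#' The default engine solves the scalar shear equation
#' \eqn{\rho u_{tt} = \nabla\cdot(\mu\nabla u)} for the vertical
#' displacement, appropriate for the vertical full-depth push in a
#' nearly incompressible medium; `engine = "psv"` runs a full vector
#' P-SV solve for validation.
#'
#' @param state a converged [solve_compression()] state (level 0 for the
#'   uncompressed phantom).
#' @param phantom the phantom the state refers to.
#' @param excitation an [excitation_spec()].
#' @param record_ms record duration (ms).
#' @param record_dt output sampling interval (s).
#' @param out_spacing output grid spacing (mm).
#' @param engine `"sh"` (scalar shear) or `"psv"` (vector, validation).
#' @param roi optional list with `surr_center`, `surr_diameter` (mm):
#'   cells of the surrounding-tissue disc are tagged in the grid label
#'   map (label 3) so reconstruction ROIs track the deformed tissue.
#' @param dt_safety CFL safety factor for the internal time step.
#' @return object of class `wave_record`: `u` is the displacement array
#'   (time x x x y, metres), with grid vectors `x`, `y` (m), sampling
#'   `dt` (s) and spacing `h` (m), plus the grid label map and metadata.
#' @export
simulate_wave <- function(state, phantom, excitation = excitation_spec(),
                          record_ms = 40, record_dt = 125e-6,
                          out_spacing = 0.2, engine = c("sh", "psv"),
                          roi = NULL, dt_safety = 0.9) {
  stopifnot(inherits(state, "deformed_state"), inherits(phantom, "phantom_model"))
  engine <- match.arg(engine)
  if (!isTRUE(state$converged))
    nlswei_abort("input state is not converged", "nlswei_invalid_input")
  rho <- phantom$materials[[1]]$density
  h <- mm(out_spacing)

  XY <- phantom$node_xy + state$u
  lab <- phantom$label[phantom$elem_cell]
  if (!is.null(roi)) {
    re <- roi_elements(phantom, roi$surr_center, roi$surr_diameter)
    lab[re$surr] <- 3L
  }
  x0 <- min(XY[, 1]) - h
  x1 <- max(XY[, 1]) + h
  y1 <- max(XY[, 2]) + h
  nx <- as.integer(ceiling((x1 - x0) / h)) + 1L
  ny <- as.integer(ceiling(y1 / h)) + 1L
  ras <- cpp_rasterize(XY, phantom$elems, state$tangent_modulus, lab,
                       x0, 0, h, nx, ny)
  mu <- ras$value
  glab <- ras$label
  mu[is.na(mu)] <- 0
  fixed <- matrix(FALSE, nx, ny)
  fixed[, 1] <- mu[, 1] > 0

  xg <- x0 + (seq_len(nx) - 1) * h
  yg <- (seq_len(ny) - 1) * h
  band <- abs(xg - excitation$center_x) <= excitation$width / 2 + 1e-9
  if (!any(band))
    nlswei_abort("excitation band lies outside the domain",
                 "nlswei_invalid_input")
  amp <- excitation$amplitude %||%
    (2 * rho * 10e-6 / excitation$duration^2)
  fbody <- matrix(0, nx, ny)
  fbody[band, ] <- -amp / rho          # downward acceleration
  fbody[mu <= 0] <- 0

  cmax <- sqrt(max(mu) / rho)
  if (engine == "psv") {
    lamv <- vapply(phantom$materials, function(m) 2 / m$d1 - 2 / 3 * mu0(m),
                   numeric(1))
    rl <- cpp_rasterize(XY, phantom$elems, lamv[phantom$elem_mat + 1L], lab,
                        x0, 0, h, nx, ny)
    lam <- rl$value
    lam[is.na(lam)] <- 0
    cmax <- sqrt((max(lam) + 2 * max(mu)) / rho)
  }
  dt_cfl <- dt_safety * h / (cmax * sqrt(2))
  nsub <- as.integer(ceiling(record_dt / dt_cfl))
  dt <- record_dt / nsub
  nrec <- as.integer(round(record_ms * 1e-3 / record_dt)) + 1L

  rec <- if (engine == "sh")
    cpp_wave_sh(mu, fixed, rho, h, dt, nsub, nrec, fbody, excitation$duration)
  else
    cpp_wave_psv(mu, lam, fixed, rho, h, dt, nsub, nrec, fbody,
                 excitation$duration)
  u <- aperm(rec, c(3, 1, 2))   # -> (time, x, y)

  structure(list(u = u, t = (seq_len(nrec) - 1) * record_dt,
                 x = xg, y = yg, dt = record_dt, h = h,
                 label = glab, mask = mu > 0,
                 compression_level = state$compression_level,
                 push_x = excitation$center_x, engine = engine,
                 density = rho,
                 provenance = list(excitation = unclass(excitation),
                                   spacing = phantom$spacing,
                                   nsub = nsub)),
            class = "wave_record")
}

#' Assemble a wave record from an externally supplied array
#'
#' The reconstruction functions operate on any uniformly sampled
#' space-time record of vertical displacement, not only on simulated
#' ones.
#'
#' @param u numeric array with dimensions (time, x, y); a (time, x)
#'   matrix is treated as a single depth row.
#' @param dt temporal sampling interval (s).
#' @param h spatial grid spacing (m), equal in x and y.
#' @param x0,y0 coordinates of the first grid sample (m).
#' @param push_x lateral position of the excitation (m).
#' @param density medium density (kg/m^3).
#' @param label optional integer grid label map (1 background, 2 tumor
#'   ROI, 3 surrounding ROI).
#' @return a `wave_record`.
#' @export
wave_record <- function(u, dt, h, x0 = 0, y0 = 0, push_x = 0,
                        density = 1000, label = NULL) {
  if (length(dim(u)) == 2) dim(u) <- c(dim(u), 1L)
  if (length(dim(u)) != 3)
    nlswei_abort("u must be a (time, x, y) array", "nlswei_invalid_input")
  check_finite(u, "displacement record")
  d <- dim(u)
  structure(list(u = u, t = (seq_len(d[1]) - 1) * dt,
                 x = x0 + (seq_len(d[2]) - 1) * h,
                 y = y0 + (seq_len(d[3]) - 1) * h,
                 dt = dt, h = h,
                 label = label %||% matrix(1L, d[2], d[3]),
                 mask = matrix(TRUE, d[2], d[3]),
                 compression_level = NA_real_, push_x = push_x,
                 engine = "external", density = density,
                 provenance = list()),
            class = "wave_record")
}

#' @export
print.wave_record <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf(
    "<wave_record> %d frames x %d x %d grid, dt %.3g us, h %.3g mm (%s)\n",
    d[1], d[2], d[3], x$dt * 1e6, x$h * 1e3, x$engine))
  cat(sprintf("  peak |u| %.3g um, level %s\n", max(abs(x$u)) * 1e6,
              format(x$compression_level)))
  invisible(x)
}

#' Displacement-versus-time traces at given lateral positions
#'
#' Extracts nearest-grid-column traces of vertical displacement at one
#' depth, the standard diagnostic for time-of-flight inspection.
#'
#' @param record a `wave_record`.
#' @param x_positions lateral positions (mm).
#' @param y depth (mm).
#' @return data.frame: `time` (s) and one column per position (m).
#' @export
extract_profiles <- function(record, x_positions, y) {
  stopifnot(inherits(record, "wave_record"))
  xp <- mm(x_positions); yp <- mm(y)
  if (any(xp < min(record$x) | xp > max(record$x)) ||
      yp < min(record$y) || yp > max(record$y))
    nlswei_abort("requested position outside the record extent",
                 "nlswei_invalid_input")
  iy <- which.min(abs(record$y - yp))
  out <- data.frame(time = record$t)
  for (k in seq_along(xp)) {
    ix <- which.min(abs(record$x - xp[k]))
    out[[sprintf("x%.1fmm", x_positions[k])]] <- record$u[, ix, iy]
  }
  out
}
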