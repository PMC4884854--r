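#' Display a reconstructed modulus map
#'
#' @param x a `modulus_map`.
#' @param zlim modulus limits (kPa); defaults to the valid data range.
#' @param ... passed to [graphics::image()].
#' @export
plot.modulus_map <- function(x, zlim = NULL, ...) {
  g <- x$modulus / 1e3
  if (is.null(zlim)) zlim <- range(g[x$valid], finite = TRUE)
  graphics::image(x$x * 1e3, x$y * 1e3, pmin(pmax(g, zlim[1]), zlim[2]),
                  asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                  zlim = zlim, useRaster = TRUE, ...)
  invisible(x)
}

#' Display a wave record frame
#'
#' @param x a `wave_record`.
#' @param frame frame index (1-based).
#' @param ... passed to [graphics::image()].
#' @export
plot.wave_record <- function(x, frame = dim(x$u)[1], ...) {
  graphics::image(x$x * 1e3, x$y * 1e3, x$u[frame, , ] * 1e6, asp = 1,
                  xlab = "x (mm)", ylab = "y (mm)", useRaster = TRUE, ...)
  invisible(x)
}
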