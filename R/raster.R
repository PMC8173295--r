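#' Visual-field raster geometry
#'
#' A square pixel raster over the visual field, centred on fixation, on which
#' stimulus apertures and pRF coverage maps are evaluated. Pixel centres lie at
#' integer multiples of `step` (including the origin), so the default raster is
#' 181 x 181 pixels at 0.5 deg/pixel spanning +/-45 deg. x is positive
#' rightward, y positive upward, both in degrees of visual angle.
#'
#' @param half_extent Half-width of the field in degrees (default 45, the
#'   maximum eccentricity of the wide-field mapping stimulus).
#' @param step Pixel size in degrees (default 0.5). `half_extent` must be an
#'   integer multiple of `step`.
#' @return An object of class `vf_raster`: a list with `half_extent`, `step`,
#'   the vector of pixel-centre coordinates `centers`, and the side length `n`.
#' @examples
#' r <- vf_raster()
#' r$n # 181
#' @export
vf_raster <- function(half_extent = 45, step = 0.5) {
  stopifnot(is.numeric(half_extent), length(half_extent) == 1L, half_extent > 0,
            is.numeric(step), length(step) == 1L, step > 0)
  k <- half_extent / step
  if (abs(k - round(k)) > 1e-8) {
    stop("`half_extent` must be an integer multiple of `step`", call. = FALSE)
  }
  centers <- seq(-half_extent, half_extent, by = step)
  structure(
    list(half_extent = half_extent, step = step,
         centers = centers, n = length(centers)),
    class = "vf_raster"
  )
}

#' @export
print.vf_raster <- function(x, ...) {
  cat(sprintf("<vf_raster> %d x %d pixels, %.3g deg/pixel, +/-%g deg\n",
              x$n, x$n, x$step, x$half_extent))
  invisible(x)
}

#' Pixel-centre coordinates of a raster
#'
#' @param raster A [vf_raster()].
#' @return A tibble with one row per pixel (x fastest): `px`, `py` in degrees
#'   and the eccentricity `ecc`.
#' @export
raster_coords <- function(raster) {
  stopifnot(inherits(raster, "vf_raster"))
  px <- rep(raster$centers, times = raster$n)
  py <- rep(raster$centers, each = raster$n)
  tibble::tibble(px = px, py = py, ecc = sqrt(px^2 + py^2))
}
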