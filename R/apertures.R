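#' @keywords internal
new_stim_aperture <- function(kind, frames, raster, frame_period, cycle_seconds,
                              n_cycles, meta) {
  structure(
    c(list(kind = kind, frames = frames, raster = raster,
           frame_period = frame_period, cycle_seconds = cycle_seconds,
           n_cycles = n_cycles, n_frames = ncol(frames)),
      meta),
    class = "stim_aperture"
  )
}

check_aperture_timing <- function(cycle_seconds, frame_period) {
  fpc <- cycle_seconds / frame_period
  if (abs(fpc - round(fpc)) > 1e-9) {
    stop(sprintf("cycle length (%g s) is not divisible by the frame period (%g s)",
                 cycle_seconds, frame_period), call. = FALSE)
  }
  as.integer(round(fpc))
}

#' Rotating-wedge stimulus aperture
#'
#' Binary spatial-occupancy movie of a wedge-shaped checkerboard envelope
#' rotating counterclockwise about fixation, one frame per repetition time.
#' The checkerboard texture and its 2 Hz contrast reversal are deliberately not
#' modelled: only spatial occupancy enters the pRF forward model. The wedge
#' leading edge starts on the positive horizontal meridian (`start_angle = 0`)
#' and trails `width_deg` behind it; the leading edge advances by
#' `360 * frame_period / cycle_seconds` degrees per frame.
#'
#' @param raster A [vf_raster()].
#' @param frame_period Seconds per frame (the fMRI repetition time, default 2).
#' @param n_cycles Number of rotation cycles (default 1).
#' @param width_deg Angular wedge width in degrees, in (0, 360) (default 45).
#' @param start_angle Polar angle (deg, counterclockwise from positive x) of
#'   the wedge's leading edge at frame 1.
#' @param cycle_seconds Seconds per full rotation (default 64).
#' @return A `stim_aperture` object. `frames` is an `n_pixels x n_frames`
#'   0/1 matrix aligned with [raster_coords()].
#' @examples
#' ap <- make_wedge_aperture(vf_raster(10, 1))
#' ap$n_frames # 32
#' @export
make_wedge_aperture <- function(raster, frame_period = 2, n_cycles = 1,
                                width_deg = 45, start_angle = 0,
                                cycle_seconds = 64) {
  stopifnot(inherits(raster, "vf_raster"), n_cycles >= 1)
  if (raster$n < 1) stop("zero-size raster", call. = FALSE)
  if (width_deg <= 0 || width_deg >= 360) {
    stop("`width_deg` must lie in (0, 360)", call. = FALSE)
  }
  fpc <- check_aperture_timing(cycle_seconds, frame_period)
  co <- raster_coords(raster)
  ang <- (atan2(co$py, co$px) * 180 / pi) %% 360
  in_disc <- co$ecc <= raster$half_extent & co$ecc > 0 # origin has no angle
  step_deg <- 360 / fpc
  frames <- matrix(0, nrow = nrow(co), ncol = fpc)
  for (k in seq_len(fpc)) {
    phase <- (start_angle + (k - 1) * step_deg) %% 360
    d <- (phase - ang) %% 360 # angular lag behind the leading edge
    frames[, k] <- as.numeric(in_disc & d < width_deg)
  }
  if (n_cycles > 1) frames <- frames[, rep(seq_len(fpc), n_cycles), drop = FALSE]
  new_stim_aperture("wedge", frames, raster, frame_period, cycle_seconds,
                    as.integer(n_cycles),
                    list(width_deg = width_deg, start_angle = start_angle,
                         direction = "counterclockwise"))
}

#' Expanding-ring stimulus aperture
#'
#' Binary occupancy movie of a checkerboard ring sweeping from fixation to the
#' raster edge in one cycle. Ring width follows the inverse-linear cortical
#' magnification rule `w(e) = c * (e + e2)`: ring centres advance linearly in
#' eccentricity and `c` is fixed so that the first two annuli exactly abut,
#' which makes the union of one cycle's rings cover the full disc and recovers
#' constant-width rings in the limit `e2 -> Inf`. The first frame is a central
#' disc (inner radius 0); annuli are clipped at eccentricity `half_extent`.
#'
#' @inheritParams make_wedge_aperture
#' @param e2 Eccentricity constant (deg) of the magnification rule (> 0,
#'   default 0.75).
#' @return A `stim_aperture` object with per-frame ring geometry in
#'   `$ring_inner`, `$ring_outer`, `$ring_center` (degrees, one cycle).
#' @export
make_ring_aperture <- function(raster, frame_period = 2, n_cycles = 1,
                               e2 = 0.75, cycle_seconds = 64) {
  stopifnot(inherits(raster, "vf_raster"), n_cycles >= 1, e2 > 0)
  if (raster$n < 1) stop("zero-size raster", call. = FALSE)
  fpc <- check_aperture_timing(cycle_seconds, frame_period)
  if (fpc < 2) stop("need at least two frames per cycle", call. = FALSE)
  co <- raster_coords(raster)
  delta <- raster$half_extent / (fpc - 1)
  centers <- delta * (seq_len(fpc) - 1)
  cc <- 2 * delta / (delta + 2 * e2)
  width <- cc * (centers + e2)
  inner <- pmax(0, centers - width / 2)
  outer <- pmin(raster$half_extent, centers + width / 2)
  frames <- matrix(0, nrow = nrow(co), ncol = fpc)
  for (k in seq_len(fpc)) {
    frames[, k] <- as.numeric(co$ecc >= inner[k] & co$ecc <= outer[k])
  }
  if (n_cycles > 1) frames <- frames[, rep(seq_len(fpc), n_cycles), drop = FALSE]
  new_stim_aperture("ring", frames, raster, frame_period, cycle_seconds,
                    as.integer(n_cycles),
                    list(e2 = e2, ring_center = centers,
                         ring_inner = inner, ring_outer = outer))
}

#' @export
print.stim_aperture <- function(x, ...) {
  cat(sprintf("<stim_aperture> %s, %d frames (%g s each, %g s/cycle, %d cycle%s)\n",
              x$kind, x$n_frames, x$frame_period, x$cycle_seconds, x$n_cycles,
              if (x$n_cycles > 1) "s" else ""))
  print(x$raster)
  invisible(x)
}

#' Save / load a stimulus aperture as plain text
#'
#' The frame matrix is written as a whitespace-delimited 0/1 table (one row per
#' pixel, one column per frame) next to a JSON sidecar holding the raster
#' geometry, timing and kind, so a movie can be round-tripped or inspected
#' outside R.
#'
#' @param aperture A `stim_aperture`.
#' @param path Output path for the frame table; the sidecar is `<path>.json`.
#' @return `write_aperture()` returns `path` invisibly; `read_aperture()`
#'   returns the reconstructed `stim_aperture`.
#' @export
write_aperture <- function(aperture, path) {
  stopifnot(inherits(aperture, "stim_aperture"))
  utils::write.table(aperture$frames, path, row.names = FALSE,
                     col.names = FALSE)
  meta <- aperture[setdiff(names(aperture), c("frames", "raster"))]
  meta$raster <- list(half_extent = aperture$raster$half_extent,
                      step = aperture$raster$step)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_aperture
#' @export
read_aperture <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- as.matrix(utils::read.table(path))
  dimnames(frames) <- NULL
  raster <- vf_raster(meta$raster$half_extent, meta$raster$step)
  extra <- meta[setdiff(names(meta),
                        c("kind", "frames", "raster", "frame_period",
                          "cycle_seconds", "n_cycles", "n_frames"))]
  new_stim_aperture(meta$kind, frames, raster, meta$frame_period,
                    meta$cycle_seconds, meta$n_cycles, extra)
}
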