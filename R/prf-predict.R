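#' Predicted BOLD time series of a Gaussian pRF
#'
#' Forward model of the pRF framework: the per-frame neural drive is the
#' overlap of the binary stimulus aperture with a circularly symmetric
#' Gaussian receptive field,
#' `drive_k = sum_pixels aperture(k, pixel) * exp(-((px-x0)^2+(py-y0)^2)/(2 sigma^2))`,
#' convolved causally with the HRF kernel and truncated to the number of
#' frames. With `unit_amplitude = TRUE` (default) the prediction is scaled to
#' peak 1, so a fitted amplitude is expressed in signal units.
#'
#' @param x0,y0 pRF centre in degrees (must lie within the raster extent).
#' @param sigma pRF size in degrees (> 0).
#' @param aperture A `stim_aperture` (or list of them; see Details).
#' @param hrf An `hrf_model`; defaults to the canonical double gamma at the
#'   aperture's frame period.
#' @param unit_amplitude Scale output to maximum 1 when the drive is non-zero.
#' @details When `aperture` is a list, each run is predicted and convolved
#'   separately (convolution never crosses a run boundary) and the runs are
#'   concatenated, matching joint fitting of wedge and ring runs.
#' @return Numeric vector, one value per frame. Deterministic.
#' @export
predict_timeseries <- function(x0, y0, sigma, aperture,
                               hrf = NULL, unit_amplitude = TRUE) {
  runs <- if (inherits(aperture, "stim_aperture")) list(aperture) else aperture
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, TRUE, "stim_aperture")))
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("`sigma` must be a positive number", call. = FALSE)
  }
  he <- runs[[1]]$raster$half_extent
  if (abs(x0) > he || abs(y0) > he) {
    stop("pRF centre lies outside the raster extent", call. = FALSE)
  }
  if (is.null(hrf)) hrf <- hrf_double_gamma(runs[[1]]$frame_period)
  stopifnot(inherits(hrf, "hrf_model"))
  out <- unlist(lapply(runs, function(ap) {
    co <- raster_coords(ap$raster)
    g <- exp(-((co$px - x0)^2 + (co$py - y0)^2) / (2 * sigma^2))
    drive <- as.vector(crossprod(ap$frames, g))
    convolve_causal(drive, hrf$kernel)
  }), use.names = FALSE)
  if (unit_amplitude) {
    m <- max(out)
    if (m > 0) out <- out / m
  }
  out
}

# Predicted series for many candidates at once, for one concatenated set of
# runs. Returns an n_frames_total x n_candidates matrix, each column scaled to
# peak 1 where possible. Chunked so the pixel x candidate Gaussian matrix
# stays small.
predict_matrix <- function(candidates, runs, hrf, chunk = 256L) {
  co <- raster_coords(runs[[1]]$raster)
  n_time <- sum(vapply(runs, function(a) ncol(a$frames), 1L))
  P <- matrix(0, n_time, nrow(candidates))
  idx <- seq_len(nrow(candidates))
  for (block in split(idx, ceiling(idx / chunk))) {
    G <- exp(-(outer(co$px, candidates$x0[block], "-")^2 +
                 outer(co$py, candidates$y0[block], "-")^2) /
               (2 * rep(candidates$sigma[block]^2, each = nrow(co))))
    preds <- do.call(rbind, lapply(runs, function(ap) {
      drives <- crossprod(ap$frames, G)
      out <- vapply(seq_len(ncol(drives)),
                    function(j) convolve_causal(drives[, j], hrf$kernel),
                    numeric(nrow(drives)))
      matrix(out, nrow = nrow(drives))
    }))
    mx <- apply(preds, 2, max)
    pos <- mx > 0
    preds[, pos] <- sweep(preds[, pos, drop = FALSE], 2, mx[pos], "/")
    P[, block] <- preds
  }
  P
}
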