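#' Canonical double-gamma haemodynamic response function
#'
#' The standard two-gamma BOLD impulse response (peak at ~6 s, undershoot at
#' ~16 s, undershoot amplitude 1/6 of the peak), sampled at the frame period
#' starting at lag 0. With `normalize = TRUE` (default) the kernel sums to 1,
#' so convolution preserves the mean drive level.
#'
#' @param frame_period Sampling interval in seconds (default 2).
#' @param peak_delay,undershoot_delay Gamma means in seconds (defaults 6, 16).
#' @param peak_disp,undershoot_disp Gamma dispersions (defaults 1).
#' @param ratio Undershoot-to-peak amplitude ratio (default 1/6).
#' @param duration Kernel length in seconds (default 32).
#' @param normalize Scale the kernel to unit sum (default TRUE).
#' @return An `hrf_model`: list with the sampled `kernel`, `frame_period` and
#'   the parameters used.
#' @export
hrf_double_gamma <- function(frame_period = 2, peak_delay = 6,
                             undershoot_delay = 16, peak_disp = 1,
                             undershoot_disp = 1, ratio = 1 / 6,
                             duration = 32, normalize = TRUE) {
  stopifnot(frame_period > 0, duration >= frame_period)
  t <- seq(0, duration, by = frame_period)
  h <- stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
    ratio * stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                          scale = undershoot_disp)
  if (!all(is.finite(h))) stop("non-finite HRF kernel", call. = FALSE)
  if (normalize) h <- h / sum(h)
  structure(
    list(kernel = h, frame_period = frame_period, normalize = normalize,
         params = list(peak_delay = peak_delay,
                       undershoot_delay = undershoot_delay,
                       peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                       ratio = ratio, duration = duration)),
    class = "hrf_model"
  )
}

#' Identity (delta) response kernel
#'
#' Convolution with this kernel returns the raw neural drive; useful for
#' testing the spatial stage of the forward model in isolation.
#'
#' @inheritParams hrf_double_gamma
#' @export
hrf_delta <- function(frame_period = 2) {
  structure(list(kernel = 1, frame_period = frame_period, normalize = TRUE,
                 params = list(delta = TRUE)),
            class = "hrf_model")
}

# causal convolution truncated to length(x)
convolve_causal <- function(x, kernel) {
  n <- length(x)
  out <- numeric(n)
  for (k in seq_along(kernel)) {
    if (k > n) break
    out[k:n] <- out[k:n] + kernel[k] * x[seq_len(n - k + 1)]
  }
  out
}
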