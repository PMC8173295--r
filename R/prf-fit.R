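#' Candidate grid for the coarse pRF search
#'
#' Polar lattice of candidate centres over the stimulated field plus
#' log-spaced candidate sizes, the first stage of the two-stage
#' (grid-then-refine) search.
#'
#' @param half_extent Maximum candidate eccentricity in degrees (default 45).
#' @param eccs Candidate eccentricities; default `0` plus 10 log-spaced values
#'   from 0.75 deg to just inside `half_extent`.
#' @param n_angles Number of equally spaced polar angles (default 16).
#' @param sigmas Candidate pRF sizes in degrees; default 8 values log-spaced
#'   0.5-15 deg.
#' @return A tibble of candidates with columns `x0`, `y0`, `sigma`, `ecc`.
#' @export
prf_search_grid <- function(half_extent = 45, eccs = NULL, n_angles = 16,
                            sigmas = NULL) {
  if (is.null(eccs)) {
    eccs <- c(0, exp(seq(log(0.75), log(0.98 * half_extent), length.out = 10)))
  }
  if (is.null(sigmas)) sigmas <- exp(seq(log(0.5), log(15), length.out = 8))
  stopifnot(length(eccs) >= 1, length(sigmas) >= 1, all(sigmas > 0),
            all(eccs >= 0), all(eccs <= half_extent), n_angles >= 1)
  ang <- seq(0, 2 * pi, length.out = n_angles + 1)[seq_len(n_angles)]
  pos <- unique(tibble::tibble(
    x0 = round(rep(eccs, each = n_angles) * cos(rep(ang, length(eccs))), 10),
    y0 = round(rep(eccs, each = n_angles) * sin(rep(ang, length(eccs))), 10)
  ))
  grid <- tidyr::expand_grid(pos, sigma = sigmas)
  grid$ecc <- sqrt(grid$x0^2 + grid$y0^2)
  grid
}

# series input -> n_time x n_voxel matrix with voxel ids
as_series_matrix <- function(series) {
  if (is.matrix(series)) {
    ids <- colnames(series)
    if (is.null(ids)) ids <- paste0("v", seq_len(ncol(series)))
    return(list(Y = unname(series), ids = ids))
  }
  stopifnot(is.data.frame(series),
            all(c("voxel_id", "volume", "signal") %in% names(series)))
  wide <- tidyr::pivot_wider(series[c("voxel_id", "volume", "signal")],
                             names_from = "voxel_id", values_from = "signal")
  wide <- wide[order(wide$volume), ]
  list(Y = as.matrix(wide[-1]), ids = names(wide)[-1])
}

#' Fit circular Gaussian pRFs by residual-sum-of-squares minimisation
#'
#' For every voxel, every grid candidate's predicted series (unit amplitude,
#' HRF-convolved) is regressed against the data with a non-negative amplitude
#' `beta` and a free baseline solved in closed form; the candidate with
#' minimal residual sum of squares wins and is optionally polished by
#' derivative-free local refinement (Nelder-Mead on x0, y0, log sigma with
#' profiled linear terms). Variance explained is `1 - RSS / TSS` with TSS
#' about the mean.
#'
#' Exact RSS ties are broken deterministically: smallest `sigma`, then
#' smallest eccentricity, then lexicographic (x0, y0). A flat (zero-variance)
#' series is returned with `variance_explained = 0` and `degenerate = TRUE`
#' rather than an error.
#'
#' @param series Either a long tibble with columns `voxel_id`, `volume`,
#'   `signal`, or an `n_volumes x n_voxels` numeric matrix (column names used
#'   as voxel ids).
#' @param apertures A `stim_aperture` or list of them (wedge and ring runs are
#'   fitted jointly by concatenation; convolution stays within runs).
#' @param hrf An `hrf_model` (default: canonical double gamma).
#' @param grid Candidate tibble from [prf_search_grid()].
#' @param refine Run local refinement from the best grid candidates
#'   (default TRUE). Switch off for exact grid-reproducibility.
#' @param n_starts Number of refinement starts (best candidate at each of the
#'   `n_starts` lowest-RSS sigma values; default 3).
#' @param nonneg_beta Constrain the amplitude to be >= 0 (default TRUE).
#' @param detrend Remove a per-voxel linear trend before fitting.
#' @return A tibble of class `prf_estimates`, one row per voxel: `voxel_id`,
#'   `x0`, `y0`, `sigma`, `beta`, `baseline`, `ve`, `ecc`, `polar_angle`
#'   (degrees, counterclockwise from the positive x axis) and `degenerate`.
#' @export
fit_prf <- function(series, apertures, hrf = NULL,
                    grid = prf_search_grid(half_extent = half_extent),
                    refine = TRUE, n_starts = 3, nonneg_beta = TRUE,
                    detrend = FALSE) {
  runs <- if (inherits(apertures, "stim_aperture")) list(apertures) else apertures
  stopifnot(all(vapply(runs, inherits, TRUE, "stim_aperture")))
  half_extent <- runs[[1]]$raster$half_extent
  if (is.null(hrf)) hrf <- hrf_double_gamma(runs[[1]]$frame_period)
  sm <- as_series_matrix(series)
  Y <- sm$Y
  n_time <- sum(vapply(runs, function(a) ncol(a$frames), 1L))
  if (nrow(Y) != n_time) {
    stop(sprintf("series length (%d) does not match aperture frame count (%d)",
                 nrow(Y), n_time), call. = FALSE)
  }
  if (anyNA(Y)) stop("missing values in time series", call. = FALSE)
  if (detrend) {
    tt <- seq_len(nrow(Y))
    Y <- apply(Y, 2, function(y) stats::residuals(stats::lm(y ~ tt)) + mean(y))
  }
  force(grid)

  # order used for tie-breaking: sigma, eccentricity, then position
  ord <- order(grid$sigma, grid$ecc, grid$x0, grid$y0)
  grid <- grid[ord, ]
  P <- predict_matrix(grid, runs, hrf)
  Pc <- sweep(P, 2, colMeans(P))
  nrm <- colSums(Pc^2)
  usable <- nrm > 1e-12

  fit_one <- function(y) {
    mu <- mean(y)
    yc <- y - mu
    tss <- sum(yc^2)
    if (tss < 1e-12) { # flat series
      j <- which(usable)[1]
      return(list(row = grid[j, ], beta = 0, baseline = mu, ve = 0,
                  degenerate = TRUE, rss = tss))
    }
    xy <- as.vector(crossprod(Pc, yc))
    b <- xy / pmax(nrm, 1e-12)
    if (nonneg_beta) b[b < 0] <- 0
    b[!usable] <- 0
    rss <- tss - 2 * b * xy + b^2 * nrm
    # grid is pre-sorted, so the first candidate within a float tolerance of
    # the minimum implements the smallest-sigma/eccentricity tie-break
    j <- which(rss <= min(rss) + 1e-9 * max(tss, 1))[1]
    best <- list(x0 = grid$x0[j], y0 = grid$y0[j], sigma = grid$sigma[j],
                 beta = b[j], rss = rss[j], mean_p = mean(P[, j]))
    if (refine) {
      obj <- function(par) {
        x0 <- par[1]; y0 <- par[2]; s <- exp(par[3])
        if (sqrt(x0^2 + y0^2) > half_extent || s < 0.05 || s > 4 * half_extent) {
          return(tss * 10)
        }
        p <- predict_timeseries(x0, y0, s, runs, hrf)
        pc <- p - mean(p)
        np <- sum(pc^2)
        if (np < 1e-12) return(tss)
        bb <- sum(pc * yc) / np
        if (nonneg_beta && bb < 0) bb <- 0
        tss - 2 * bb * sum(pc * yc) + bb^2 * np
      }
      # multi-start: the RSS surface trades sigma against position, so refine
      # from the best candidate at each of the `n_starts` best sigma values
      by_sigma <- tapply(seq_len(nrow(grid)), grid$sigma,
                         function(ix) ix[which.min(rss[ix])])
      starts <- unlist(by_sigma)[order(rss[unlist(by_sigma)])]
      starts <- utils::head(starts, n_starts)
      for (s0 in starts) {
        opt <- stats::optim(c(grid$x0[s0], grid$y0[s0], log(grid$sigma[s0])),
                            obj, method = "Nelder-Mead",
                            control = list(reltol = 1e-6, maxit = 300))
        if (opt$value < best$rss) {
          x0 <- opt$par[1]; y0 <- opt$par[2]; s <- exp(opt$par[3])
          p <- predict_timeseries(x0, y0, s, runs, hrf)
          pc <- p - mean(p)
          np <- sum(pc^2)
          bb <- if (np > 1e-12) sum(pc * yc) / np else 0
          if (nonneg_beta && bb < 0) bb <- 0
          best <- list(x0 = x0, y0 = y0, sigma = s, beta = bb,
                       rss = opt$value, mean_p = mean(p))
        }
      }
    }
    list(row = tibble::tibble(x0 = best$x0, y0 = best$y0, sigma = best$sigma),
         beta = best$beta, baseline = mu - best$beta * best$mean_p,
         ve = max(0, 1 - best$rss / tss), degenerate = FALSE, rss = best$rss)
  }

  res <- lapply(seq_len(ncol(Y)), function(i) fit_one(Y[, i]))
  out <- tibble::tibble(
    voxel_id = sm$ids,
    x0 = vapply(res, function(r) r$row$x0[1], 1),
    y0 = vapply(res, function(r) r$row$y0[1], 1),
    sigma = vapply(res, function(r) r$row$sigma[1], 1),
    beta = vapply(res, function(r) r$beta, 1),
    baseline = vapply(res, function(r) r$baseline, 1),
    ve = vapply(res, function(r) r$ve, 1),
    degenerate = vapply(res, function(r) r$degenerate, TRUE)
  )
  out$ecc <- sqrt(out$x0^2 + out$y0^2)
  out$polar_angle <- (atan2(out$y0, out$x0) * 180 / pi) %% 360
  out <- out[c("voxel_id", "x0", "y0", "sigma", "beta", "baseline", "ve",
               "ecc", "polar_angle", "degenerate")]
  class(out) <- c("prf_estimates", class(out))
  attr(out, "refine") <- refine
  out
}

#' Retain pRF estimates above a variance-explained cutoff
#'
#' Keeps exactly the estimates with `ve >= ve_min` (boundary inclusive). The
#' 20% default mirrors the standard coverage-map inclusion criterion.
#'
#' @param estimates A `prf_estimates` tibble (or any tibble with a `ve`
#'   column).
#' @param ve_min Variance-explained threshold in `[0, 1]` (default 0.20).
#' @return The retained rows, with attributes `ve_min` and `n_rejected`; a
#'   warning is raised when nothing survives.
#' @export
filter_estimates <- function(estimates, ve_min = 0.20) {
  stopifnot(is.data.frame(estimates), "ve" %in% names(estimates),
            is.numeric(ve_min), length(ve_min) == 1L,
            ve_min >= 0, ve_min <= 1)
  keep <- estimates$ve >= ve_min
  out <- estimates[keep, ]
  attr(out, "ve_min") <- ve_min
  attr(out, "n_rejected") <- sum(!keep)
  message(sprintf("filter_estimates: retained %d of %d voxels at ve >= %g",
                  sum(keep), length(keep), ve_min))
  if (!any(keep)) warning("no estimates survive the variance-explained filter",
                          call. = FALSE)
  out
}
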