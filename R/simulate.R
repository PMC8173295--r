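with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Simulate ground-truth pRFs for a lesioned hemisphere pair
#'
#' Candidate pRF centres tile the field with density following cortical
#' magnification (radial sampling with density proportional to `1/(e + e2)`,
#' uniform polar angle) and sizes growing linearly with eccentricity
#' (`sigma = sigma0 + sigma_slope * ecc`). Voxels whose centres fall in the
#' neural scotoma (behavioural scotoma eroded by the reserve margin, minus
#' spared islands) are removed; all candidates are returned with membership
#' flags so removal can be verified.
#'
#' @param lesion A [lesion_spec()] (or `NULL`: intact field, nothing removed).
#' @param n_voxels Number of candidate voxels before removal (default 400).
#' @param half_extent Field half-width in degrees (default 45).
#' @param e2 Magnification eccentricity constant (default 0.75).
#' @param sigma0,sigma_slope pRF size intercept/slope in degrees (defaults
#'   0.5 and 0.15, a pooled-visual-hierarchy scale).
#' @param beta,baseline Response amplitude and offset in signal units.
#' @param seed Optional seed (ambient RNG restored).
#' @return A tibble: `voxel_id`, `x0`, `y0`, `sigma`, `beta`, `baseline`,
#'   `in_scotoma`, `in_island`, `surviving`.
#' @export
simulate_voxels <- function(lesion = NULL, n_voxels = 400, half_extent = 45,
                            e2 = 0.75, sigma0 = 0.5, sigma_slope = 0.15,
                            beta = 1, baseline = 0, seed = NULL) {
  stopifnot(n_voxels >= 1)
  with_seed(seed, {
    u <- stats::runif(n_voxels)
    ecc <- e2 * ((1 + half_extent / e2)^u - 1) # density ~ 1/(e + e2)
    ang <- stats::runif(n_voxels, 0, 2 * pi)
    x0 <- ecc * cos(ang)
    y0 <- ecc * sin(ang)
    in_scot <- if (is.null(lesion)) rep(FALSE, n_voxels)
    else in_behavioral_scotoma(lesion, x0, y0)
    in_neur <- if (is.null(lesion)) rep(FALSE, n_voxels)
    else in_neural_scotoma(lesion, x0, y0)
    in_island <- in_scot & !in_neur &
      (if (is.null(lesion) || is.null(lesion$islands)) FALSE else {
        hit <- rep(FALSE, n_voxels)
        for (i in seq_len(nrow(lesion$islands))) {
          hit <- hit | ((x0 - lesion$islands$x[i])^2 +
                          (y0 - lesion$islands$y[i])^2 <=
                          lesion$islands$radius[i]^2)
        }
        hit
      })
    tibble::tibble(
      voxel_id = sprintf("v%04d", seq_len(n_voxels)),
      x0 = x0, y0 = y0,
      sigma = sigma0 + sigma_slope * ecc,
      beta = beta, baseline = baseline,
      in_scotoma = in_scot, in_island = in_island,
      surviving = !in_neur
    )
  })
}

#' Simulate BOLD time series from ground-truth pRFs
#'
#' Forward model plus additive Gaussian noise:
#' `signal = beta * prediction + baseline + N(0, (beta/snr)^2)` per volume,
#' with the unit-amplitude prediction of [predict_timeseries()]. `snr = Inf`
#' gives the exact prediction.
#'
#' @param truth Tibble with `voxel_id`, `x0`, `y0`, `sigma`, `beta`,
#'   `baseline` (e.g. surviving rows of [simulate_voxels()]).
#' @param apertures A `stim_aperture` or list of runs.
#' @param hrf An `hrf_model` (default canonical double gamma).
#' @param snr Signal-to-noise ratio, amplitude over noise SD (default 3).
#' @param seed Optional seed (ambient RNG restored).
#' @return A long tibble: `voxel_id`, `volume`, `signal`.
#' @export
simulate_timeseries <- function(truth, apertures, hrf = NULL, snr = 3,
                                seed = NULL) {
  stopifnot(is.data.frame(truth), nrow(truth) >= 1, snr > 0)
  runs <- if (inherits(apertures, "stim_aperture")) list(apertures)
  else apertures
  if (is.null(hrf)) hrf <- hrf_double_gamma(runs[[1]]$frame_period)
  P <- predict_matrix(truth[c("x0", "y0", "sigma")], runs, hrf)
  with_seed(seed, {
    n_time <- nrow(P)
    sig <- sweep(P, 2, truth$beta, "*")
    sig <- sweep(sig, 2, truth$baseline, "+")
    if (is.finite(snr)) {
      sig <- sig + matrix(stats::rnorm(length(sig)), nrow(sig)) *
        rep(truth$beta / snr, each = n_time)
    }
    tibble::tibble(
      voxel_id = rep(truth$voxel_id, each = n_time),
      volume = rep(seq_len(n_time), times = nrow(truth)),
      signal = as.vector(sig)
    )
  })
}

#' Simulate a pre-training Humphrey map
#'
#' Hill-of-vision model: outside the behavioural scotoma the sensitivity is
#' `peak_db - slope_db * ecc` plus Gaussian measurement noise, clamped to
#' `[0, ceiling_db]`; locations inside the scotoma and the blind spot measure
#' 0 dB exactly (the perimeter's floor is treated as absorbing and reliable,
#' matching the reproducibility of deep defects in clinical test-retest data).
#'
#' @param lesion A [lesion_spec()] (or `NULL` for an intact field).
#' @param grid A [make_302_grid()].
#' @param peak_db Foveal sensitivity in dB (default 33, within the ~30-35 dB
#'   subject-specific maximum).
#' @param slope_db Sensitivity decline in dB per degree of eccentricity
#'   (default 0.3).
#' @param noise_sd Measurement noise SD in dB (default 1.5, clinical
#'   test-retest scale).
#' @param ceiling_db Device ceiling (default 35).
#' @param seed Optional seed (ambient RNG restored).
#' @param reliability,subject Passed to [perimetry_map()]; reliability
#'   defaults to excellent indices.
#' @return A [perimetry_map()] with session `"pre"`.
#' @export
simulate_perimetry <- function(lesion = NULL, grid = make_302_grid(),
                               peak_db = 33, slope_db = 0.3, noise_sd = 1.5,
                               ceiling_db = 35, seed = NULL,
                               reliability = list(fixation_losses = 0.05,
                                                  false_positive = 0.02,
                                                  false_negative = 0.02,
                                                  blindspot_fp = 0.05),
                               subject = NULL) {
  stopifnot(inherits(grid, "perimetric_grid"), noise_sd >= 0)
  with_seed(seed, {
    db <- peak_db - slope_db * grid$ecc +
      stats::rnorm(nrow(grid), sd = noise_sd)
    db <- pmin(pmax(db, 0), ceiling_db)
    scot <- if (is.null(lesion)) rep(FALSE, nrow(grid))
    else in_behavioral_scotoma(lesion, grid$x_deg, grid$y_deg)
    db[scot] <- 0
    db[grid$blind_spot] <- 0
    perimetry_map(db, grid, session = "pre", reliability = reliability,
                  subject = subject)
  })
}

#' Default per-category effect parameters
#'
#' Category means default to the observed cohort-level training effects
#' (reserve 1.34 dB, intact-seen 0.76 dB, blind-blind 0.22 dB; the rare
#' Hum+/Ret- category borrows the seen mean). Location-level SDs are a
#' synthetic choice (no location-level dispersions are published) at clinical
#' test-retest scale.
#' @keywords internal
default_effect_means <- function() {
  c(HumP_RetP = 0.76, HumP_RetM = 0.76, HumM_RetP = 1.34, HumM_RetM = 0.22)
}

#' @keywords internal
default_effect_sds <- function() {
  c(HumP_RetP = 0.8, HumP_RetM = 0.8, HumM_RetP = 1.0, HumM_RetM = 0.3)
}

#' Simulate a post-training Humphrey map with category-dependent effects
#'
#' Adds to each location a draw from its ground-truth category's effect
#' distribution, then clamps the result to `[0, ceiling_db]`. Two effect
#' models are available:
#' * Gaussian (default): `change ~ N(mean_cat, sd_cat)`.
#' * Zero-inflated mixture (`mixture = TRUE`): a location improves with
#'   probability `mean_cat / improved_mean` by a draw from
#'   `N(improved_mean, improved_sd)` and is unchanged otherwise, so the
#'   category mean stays at `mean_cat` while improved locations average
#'   `improved_mean` (default 9.12 dB, the changed-only reserve effect).
#'
#' The blind-spot location never changes. The drawn effects are attached as
#' attribute `"true_effect"`.
#'
#' @param pre A pre-training [perimetry_map()].
#' @param categories Ground-truth category per location (character/factor
#'   using the `HumP_RetP` ... `HumM_RetM` labels).
#' @param effect_means,effect_sds Named per-category parameters (dB); see
#'   defaults above.
#' @param mixture Use the zero-inflated model (default FALSE).
#' @param improved_mean,improved_sd Mixture parameters (defaults 9.12, 0.93).
#' @param ceiling_db Device ceiling (default 35).
#' @param seed Optional seed (ambient RNG restored).
#' @return A [perimetry_map()] with session `"post"`.
#' @export
simulate_post_training <- function(pre, categories,
                                   effect_means = default_effect_means(),
                                   effect_sds = default_effect_sds(),
                                   mixture = FALSE, improved_mean = 9.12,
                                   improved_sd = 0.93, ceiling_db = 35,
                                   seed = NULL) {
  stopifnot(inherits(pre, "perimetry_map"),
            length(categories) == nrow(pre), all(effect_sds >= 0))
  categories <- as.character(categories)
  stopifnot(all(categories %in% c(names(effect_means), "excluded")))
  with_seed(seed, {
    n <- nrow(pre)
    mu <- unname(c(effect_means, excluded = 0)[categories])
    if (mixture) {
      p_imp <- pmin(mu / improved_mean, 1)
      improved <- stats::runif(n) < p_imp
      eff <- ifelse(improved,
                    stats::rnorm(n, improved_mean, improved_sd), 0)
    } else {
      sds <- unname(c(effect_sds, excluded = 0)[categories])
      eff <- stats::rnorm(n, mu, sds)
    }
    eff[pre$blind_spot] <- 0
    post_db <- pmin(pmax(pre$db + eff, 0), ceiling_db)
    post_db[pre$blind_spot] <- 0
    out <- perimetry_map(post_db, make_302_grid(attr(pre, "eye")),
                         session = "post",
                         reliability = attr(pre, "reliability"),
                         subject = attr(pre, "subject"))
    attr(out, "true_effect") <- eff
    # clamping at the dB floor/ceiling biases realised changes; report it
    realised <- post_db - pre$db
    attr(out, "truncation_bias") <-
      tapply(realised - eff, categories, mean)[unique(categories)]
    out
  })
}

#' Simulate goal-attainment scores linked to recovered reserve
#'
#' Each patient's three goal scores are
#' `clamp(intercept + slope * n_improved + noise, -3, 2)` on the 6-point
#' goal-attainment scale (worse than before = -3 ... much better than goal =
#' +2); the aggregate is their mean. Scores are kept real-valued within the
#' scale so a noise-free linkage is exactly linear.
#'
#' @param n_improved Integer vector: per-patient count of neural-reserve
#'   locations that improved by >= 1 dB.
#' @param slope,intercept Linear linkage (defaults 0.12 and -2).
#' @param noise_sd Per-goal noise SD (default 1).
#' @param seed Optional seed (ambient RNG restored).
#' @return A tibble: `patient`, `goal1`-`goal3`, `gas` (aggregate).
#' @export
simulate_gas <- function(n_improved, slope = 0.12, intercept = -2,
                         noise_sd = 1, seed = NULL) {
  with_seed(seed, {
    n <- length(n_improved)
    goal <- function() {
      pmin(pmax(intercept + slope * n_improved +
                  stats::rnorm(n, sd = noise_sd), -3), 2)
    }
    g1 <- goal(); g2 <- goal(); g3 <- goal()
    tibble::tibble(patient = seq_len(n), goal1 = g1, goal2 = g2, goal3 = g3,
                   gas = (g1 + g2 + g3) / 3)
  })
}
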