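#' Simulate a complete training cohort at the perimetric level
#'
#' Generates, per patient: a lesion (hemianopia or quadrantanopia with a
#' reserve margin and spared islands), ground-truth location categories, a
#' per-location neural-coverage value, pre/post Humphrey maps with
#' category-dependent training effects, and goal-attainment scores linked to
#' the number of recovered reserve locations. Everything is deterministic
#' under `seed`: per-patient sub-seeds are drawn from the master seed and
#' recorded in the output.
#'
#' Ground truth: a location is Hum- when inside the behavioural scotoma and
#' Ret+ when outside the *neural* scotoma (reserve margin + islands); a small
#' fraction `p_mismatch` of seeing locations is flipped to Ret-
#' (Hum+/Ret-), emulating noisy pRF dropout. Coverage values are drawn
#' uniformly from (0.55, 1) for Ret+ truth and (0, 0.45) for Ret- truth, so
#' the default 0.5 binarisation reproduces truth exactly while 0.25/0.75
#' thresholds perturb it realistically.
#'
#' @param n_patients Number of patients (default 20).
#' @param seed Master seed (default 1; ambient RNG restored).
#' @param effect_means,effect_sds Per-category dB effect parameters, see
#'   [simulate_post_training()].
#' @param mixture Use the zero-inflated effect model.
#' @param null_effects If TRUE, ignore categories and draw every location's
#'   change from `N(null_mean, null_sd)` (a category-independent null).
#' @param null_mean,null_sd Null-model parameters (defaults 0.76, 0.8).
#' @param untrained If TRUE, simulate spontaneous test-retest drift instead of
#'   training: category-independent changes `N(drift_mean, drift_sd)`.
#' @param drift_mean,drift_sd Drift parameters (defaults 0.11 and 0.5 dB).
#' @param patient_sd SD of a per-patient additive change offset shared by all
#'   locations (between-patient heterogeneity, default 0.3 dB).
#' @param reserve_margin Erosion of the neural scotoma in degrees (default 7:
#'   the innermost column of scotoma test locations retains coverage).
#' @param n_islands,island_radius Spared islands per lesion and their radius
#'   in degrees (defaults 2 and 6).
#' @param p_mismatch Probability that a seeing location lacks neural coverage
#'   (default 0.015).
#' @param noise_sd Humphrey measurement noise SD for the hill of vision
#'   (default 1.5 dB); set 0 for noiseless ground truth.
#' @param gas_slope,gas_noise Goal-attainment linkage (see [simulate_gas()]).
#' @param p_hemianopia Probability a patient has a hemianopia rather than a
#'   quadrantanopia (default 0.7).
#' @return An object of class `np_cohort`: list with `locations` (long tibble:
#'   `patient`, grid coordinates, `blind_spot`, `category_true`, `coverage`,
#'   `db_pre`, `db_post`, `change`), `patients` (per-patient tibble with eye,
#'   lesion descriptors, reserve counts and `gas`), and `params`.
#' @export
simulate_cohort <- function(n_patients = 20, seed = 1,
                            effect_means = default_effect_means(),
                            effect_sds = default_effect_sds(),
                            mixture = FALSE,
                            null_effects = FALSE, null_mean = 0.76,
                            null_sd = 0.8,
                            untrained = FALSE, drift_mean = 0.11,
                            drift_sd = 0.5,
                            patient_sd = 0.3,
                            reserve_margin = 7, n_islands = 2,
                            island_radius = 6, p_mismatch = 0.015,
                            noise_sd = 1.5, gas_slope = 0.12, gas_noise = 1,
                            p_hemianopia = 0.7) {
  stopifnot(n_patients >= 1)
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n_patients)
    pts <- vector("list", n_patients)
    for (i in seq_len(n_patients)) {
      pts[[i]] <- simulate_one_patient(
        patient = i, seed = sub_seeds[i], effect_means = effect_means,
        effect_sds = effect_sds, mixture = mixture,
        null_effects = null_effects, null_mean = null_mean,
        null_sd = null_sd, untrained = untrained, drift_mean = drift_mean,
        drift_sd = drift_sd, patient_sd = patient_sd,
        reserve_margin = reserve_margin, n_islands = n_islands,
        island_radius = island_radius, p_mismatch = p_mismatch,
        noise_sd = noise_sd, p_hemianopia = p_hemianopia)
    }
    locations <- dplyr::bind_rows(lapply(pts, `[[`, "locations"))
    patients <- dplyr::bind_rows(lapply(pts, `[[`, "patient_row"))
    gas <- simulate_gas(patients$n_reserve_improved, slope = gas_slope,
                        noise_sd = gas_noise,
                        seed = sub_seeds[1] %% 100000L + 7L)
    patients$gas <- gas$gas
    structure(
      list(locations = locations, patients = patients,
           params = list(seed = seed, sub_seeds = sub_seeds,
                         effect_means = effect_means,
                         effect_sds = effect_sds, mixture = mixture,
                         null_effects = null_effects, untrained = untrained,
                         noise_sd = noise_sd, patient_sd = patient_sd,
                         reserve_margin = reserve_margin,
                         gas_slope = gas_slope)),
      class = "np_cohort"
    )
  })
}

simulate_one_patient <- function(patient, seed, effect_means, effect_sds,
                                 mixture, null_effects, null_mean, null_sd,
                                 untrained, drift_mean, drift_sd, patient_sd,
                                 reserve_margin, n_islands, island_radius,
                                 p_mismatch, noise_sd, p_hemianopia) {
  with_seed(seed, {
    side <- sample(c("left", "right"), 1)
    type <- if (stats::runif(1) < p_hemianopia) "hemianopia" else "quadrantanopia"
    scot <- if (type == "hemianopia") region_hemifield(side)
    else region_quadrant(sample(paste(c("upper", "lower"), side, sep = "_"), 1))
    eye <- setdiff(c("left", "right"), side) # blind spot in the intact field
    grid <- make_302_grid(eye)
    # spared islands at scotoma test locations
    islands <- NULL
    if (n_islands > 0) {
      cand <- grid[region_contains(scot, grid$x_deg, grid$y_deg) &
                     !grid$blind_spot, ]
      if (nrow(cand) > 0) {
        take <- cand[sample.int(nrow(cand), min(n_islands, nrow(cand))), ]
        islands <- tibble::tibble(x = take$x_deg, y = take$y_deg,
                                  radius = island_radius)
      }
    }
    lesion <- lesion_spec(scot, islands, reserve_margin)

    hum_minus <- in_behavioral_scotoma(lesion, grid$x_deg, grid$y_deg)
    ret_plus <- !in_neural_scotoma(lesion, grid$x_deg, grid$y_deg)
    flip <- !hum_minus & stats::runif(nrow(grid)) < p_mismatch
    ret_plus[flip] <- FALSE
    category_true <- dplyr::case_when(
      grid$blind_spot ~ "excluded",
      !hum_minus & ret_plus ~ "HumP_RetP",
      !hum_minus & !ret_plus ~ "HumP_RetM",
      hum_minus & ret_plus ~ "HumM_RetP",
      TRUE ~ "HumM_RetM"
    )
    coverage <- ifelse(ret_plus, stats::runif(nrow(grid), 0.55, 1),
                       stats::runif(nrow(grid), 0, 0.45))

    pre <- simulate_perimetry(lesion, grid, noise_sd = noise_sd,
                              subject = sprintf("P%02d", patient))
    offset <- stats::rnorm(1, 0, patient_sd) # between-patient heterogeneity
    keep <- !grid$blind_spot
    if (null_effects) {
      # calibration world: the *realised* change is drawn identically for
      # every location (floor censoring inside the draw), so category labels
      # are genuinely exchangeable within patient
      eff <- pmax(0, stats::rnorm(nrow(grid), null_mean, null_sd) + offset)
      eff[grid$blind_spot] <- 0
      post_db <- pmin(pre$db + eff, 35)
      post_db[grid$blind_spot] <- 0
      post <- perimetry_map(post_db, grid, session = "post",
                            reliability = attr(pre, "reliability"),
                            subject = attr(pre, "subject"))
    } else if (untrained) {
      eff <- stats::rnorm(nrow(grid), drift_mean, drift_sd) + offset
      eff[grid$blind_spot] <- 0
      post_db <- pmin(pmax(pre$db + eff, 0), 35)
      post_db[grid$blind_spot] <- 0
      post <- perimetry_map(post_db, grid, session = "post",
                            reliability = attr(pre, "reliability"),
                            subject = attr(pre, "subject"))
    } else {
      post <- simulate_post_training(pre, category_true,
                                     effect_means = effect_means,
                                     effect_sds = effect_sds,
                                     mixture = mixture)
      post$db[keep] <- pmin(pmax(post$db[keep] + offset, 0), 35)
    }

    chg <- change_map(pre, post)
    locations <- tibble::tibble(
      patient = patient,
      x_deg = grid$x_deg, y_deg = grid$y_deg, blind_spot = grid$blind_spot,
      category_true = factor(category_true, levels = np_category_levels),
      coverage = coverage,
      db_pre = pre$db, db_post = post$db, change = chg$change
    )
    improved <- locations$category_true == "HumM_RetP" &
      locations$change >= 1
    patient_row <- tibble::tibble(
      patient = patient, eye = eye, lesion_side = side, lesion_type = type,
      seed = seed,
      n_reserve = sum(locations$category_true == "HumM_RetP"),
      n_reserve_improved = sum(improved)
    )
    list(locations = locations, patient_row = patient_row)
  })
}

#' @export
print.np_cohort <- function(x, ...) {
  cat(sprintf("<np_cohort> %d patients, %d locations (seed %s)\n",
              nrow(x$patients), nrow(x$locations),
              format(x$params$seed)))
  print(category_fractions_cohort(x))
  invisible(x)
}

category_fractions_cohort <- function(cohort) {
  d <- cohort$locations[cohort$locations$category_true != "excluded", ]
  tab <- table(droplevels(d$category_true))
  tibble::tibble(category = names(tab), n = as.integer(tab),
                 fraction = as.integer(tab) / sum(tab))
}

#' Run the classification pipeline over a simulated cohort
#'
#' Rebuilds, per patient, the real analysis objects (a [perimetry_map()] from
#' `db_pre` and a [neural_perimetry_from_values()] map from the coverage
#' values), binarises at `threshold`, classifies with [classify_locations()]
#' and joins the observed dB change - i.e. the cohort flows through the same
#' code path as real data.
#'
#' @param cohort An [simulate_cohort()] result.
#' @param threshold Coverage binarisation threshold (default 0.5).
#' @param drop_rare Exclude the rare Hum+/Ret- category (default TRUE).
#' @return A long tibble with `patient`, grid coordinates, `category`,
#'   `category_true` and `change`, ready for [category_effects()] and
#'   [permutation_test_categories()].
#' @export
classify_cohort <- function(cohort, threshold = 0.5, drop_rare = TRUE) {
  stopifnot(inherits(cohort, "np_cohort"))
  purrr::map_dfr(split(cohort$locations, cohort$locations$patient),
                 function(d) {
    eye <- cohort$patients$eye[cohort$patients$patient == d$patient[1]]
    grid <- make_302_grid(eye)
    stopifnot(identical(grid$x_deg, d$x_deg), identical(grid$y_deg, d$y_deg))
    hum <- perimetry_map(d$db_pre, grid)
    neu <- binarize_coverage(neural_perimetry_from_values(d$coverage, grid),
                             threshold)
    cl <- classify_locations(hum, neu)
    if (drop_rare) cl <- drop_rare_category(cl)
    tibble::tibble(patient = d$patient, x_deg = d$x_deg, y_deg = d$y_deg,
                   category = cl$category, category_true = d$category_true,
                   change = d$change)
  })
}

#' One-call cohort analysis
#'
#' Classifies a simulated (or assembled) cohort at `threshold`, estimates
#' per-category training effects, runs the within-patient permutation test
#' and the goal-attainment association, and reports the agreement fraction.
#'
#' @param cohort An `np_cohort`.
#' @param threshold Binarisation threshold (default 0.5).
#' @param n_iterations Permutation iterations (default 10000).
#' @param seed Seed for the permutation stage.
#' @param variant Effect variant, see [category_effects()].
#' @return A list: `classified` (long tibble), `effects`, `permutation`,
#'   `gas`, `agreement`, `overall` (cohort-level [summarize_change()]-style
#'   mean change).
#' @export
analyze_cohort <- function(cohort, threshold = 0.5, n_iterations = 10000,
                           seed = NULL, variant = "all_locations") {
  cl <- classify_cohort(cohort, threshold)
  eff <- category_effects(cl, variant = variant)
  perm <- permutation_test_categories(cl, n_iterations = n_iterations,
                                      seed = seed, variant = variant)
  gas <- gas_association(cohort$patients)
  keep <- cl$category != "excluded"
  agreement <- mean(cl$category[keep] %in% c("HumP_RetP", "HumM_RetM"))
  per_pat <- dplyr::summarise(dplyr::group_by(cl[keep, ], .data$patient),
                              m = mean(.data$change), .groups = "drop")
  list(classified = cl, effects = eff, permutation = perm, gas = gas,
       agreement = agreement,
       overall = tibble::tibble(mean_change = mean(per_pat$m),
                                se = stats::sd(per_pat$m) /
                                  sqrt(nrow(per_pat)),
                                n_patients = nrow(per_pat)))
}

#' Per-patient mean dB change of a cohort
#'
#' Convenience accessor used for trained-vs-untrained comparisons: mean change
#' over non-blind-spot locations per patient.
#'
#' @param cohort An `np_cohort`.
#' @return Numeric vector, one value per patient.
#' @export
cohort_mean_changes <- function(cohort) {
  stopifnot(inherits(cohort, "np_cohort"))
  d <- cohort$locations[!cohort$locations$blind_spot, ]
  as.numeric(tapply(d$change, d$patient, mean))
}
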