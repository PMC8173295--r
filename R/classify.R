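np_category_levels <- c("HumP_RetP", "HumP_RetM", "HumM_RetP", "HumM_RetM",
                        "excluded")

#' Classify perimetric locations into Humphrey/retinotopy agreement categories
#'
#' Each 30-2 location is labelled by the cross of behavioural and neural
#' coverage: Hum+ iff the pre-training Humphrey sensitivity is strictly
#' greater than 0 dB, Ret+ iff the binarised neural perimetry marks it
#' covered. `HumM_RetP` (blind behaviourally, responsive cortically) is the
#' neural-reserve category. The blind-spot location is excluded before
#' classification.
#'
#' @param humphrey_pre A pre-training [perimetry_map()].
#' @param neural A [binarize_coverage()]-d `neural_perimetry_map` on the same
#'   grid.
#' @return A tibble of class `np_classification`: grid columns, `db`,
#'   `covered`, `category` (factor with the four categories plus
#'   `"excluded"`) and `excluded_reason`.
#' @export
classify_locations <- function(humphrey_pre, neural) {
  stopifnot(inherits(humphrey_pre, "perimetry_map"),
            inherits(neural, "neural_perimetry_map"))
  if (!"covered" %in% names(neural)) {
    stop("`neural` must be binarised first (see binarize_coverage())",
         call. = FALSE)
  }
  same <- identical(humphrey_pre$x_deg, neural$x_deg) &&
    identical(humphrey_pre$y_deg, neural$y_deg) &&
    identical(humphrey_pre$blind_spot, neural$blind_spot)
  if (!same) stop("maps are not on the same perimetric grid", call. = FALSE)
  hum <- humphrey_pre$db > 0
  ret <- neural$covered == 1L
  category <- dplyr::case_when(
    humphrey_pre$blind_spot ~ "excluded",
    hum & ret ~ "HumP_RetP",
    hum & !ret ~ "HumP_RetM",
    !hum & ret ~ "HumM_RetP",
    TRUE ~ "HumM_RetM"
  )
  out <- tibble::tibble(
    x_deg = humphrey_pre$x_deg, y_deg = humphrey_pre$y_deg,
    blind_spot = humphrey_pre$blind_spot,
    db = humphrey_pre$db, covered = neural$covered,
    category = factor(category, levels = np_category_levels),
    excluded_reason = ifelse(humphrey_pre$blind_spot, "blind_spot",
                             NA_character_)
  )
  class(out) <- c("np_classification", class(out))
  attr(out, "threshold") <- attr(neural, "threshold")
  out
}

#' Category counts and fractions
#'
#' @param classification An [classify_locations()] result.
#' @return A tibble with `category`, `n` and `fraction`; fractions are over
#'   non-excluded locations and sum to 1.
#' @export
category_counts <- function(classification) {
  stopifnot(inherits(classification, "np_classification"))
  tab <- table(classification$category)
  active <- setdiff(np_category_levels, "excluded")
  n_active <- sum(tab[active])
  tibble::tibble(
    category = factor(np_category_levels, levels = np_category_levels),
    n = as.integer(tab[np_category_levels]),
    fraction = ifelse(np_category_levels == "excluded", NA_real_,
                      as.numeric(tab[np_category_levels]) / n_active)
  )
}

#' Exclude an infrequent category from analysis
#'
#' The Hum+/Ret- category (behavioural sensitivity without measured neural
#' coverage) is rare (~1.5% of locations in practice) and hard to interpret,
#' so it is dropped before training-effect statistics. The original label is
#' retained in `category_original`, making the exclusion reversible.
#'
#' @param classification An [classify_locations()] result.
#' @param category Category to exclude (default `"HumP_RetM"`).
#' @return The classification with matching locations relabelled `"excluded"`
#'   (`excluded_reason = "rare_category"`).
#' @export
drop_rare_category <- function(classification, category = "HumP_RetM") {
  stopifnot(inherits(classification, "np_classification"),
            category %in% np_category_levels)
  if (!"category_original" %in% names(classification)) {
    classification$category_original <- classification$category
  }
  hit <- classification$category == category
  classification$category[hit] <- "excluded"
  classification$excluded_reason[hit] <- "rare_category"
  classification
}

#' Fraction of locations where the two perimetries agree
#'
#' Agreement means Hum+/Ret+ or Hum-/Ret-; the fraction is over non-excluded
#' locations.
#'
#' @param classification An [classify_locations()] result.
#' @return A single numeric fraction.
#' @export
agreement_fraction <- function(classification) {
  stopifnot(inherits(classification, "np_classification"))
  cat_ <- classification$category[classification$category != "excluded"]
  mean(cat_ %in% c("HumP_RetP", "HumM_RetM"))
}
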