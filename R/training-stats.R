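# canonical long format for cohort-level statistics: one row per location with
# columns patient, category, change; rows labelled "excluded" are dropped.
prepare_effect_data <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("patient", "category", "change") %in% names(data)))
  d <- data[!is.na(data$category) & data$category != "excluded", ]
  d$category <- factor(as.character(d$category),
                       levels = setdiff(np_category_levels, "excluded"))
  d
}

#' Per-category training-effect summary
#'
#' Mean dB change per Humphrey/retinotopy category, either over all
#' non-excluded locations or over locations that improved by at least
#' `changed_threshold` dB (the "changed-only" reading of the effect;
#' `changed_rule = "nonzero"` instead drops only exact-zero changes).
#'
#' Pooling `"per_patient_then_mean"` (default) averages locations within each
#' patient first and reports the mean and standard error across patients;
#' `"pooled_locations"` pools all locations.
#'
#' @param data Tibble with columns `patient`, `category`, `change` (e.g. a
#'   joined [classify_locations()] + [change_map()] cohort, or
#'   [cohort_locations()] output).
#' @param variant `"all_locations"` (default) or `"changed_only"`.
#' @param pooling `"per_patient_then_mean"` (default) or `"pooled_locations"`.
#' @param changed_threshold dB improvement cutoff for `"changed_only"`
#'   (default 1, inclusive).
#' @param changed_rule `"at_least_threshold"` (default) or `"nonzero"`.
#' @return A tibble of class `category_effects`: `category`, `mean_change`,
#'   `se`, `n` (pooling units) and `n_locations`. Empty categories are
#'   reported with `n = 0` and `NA` mean.
#' @export
category_effects <- function(data,
                             variant = c("all_locations", "changed_only"),
                             pooling = c("per_patient_then_mean",
                                         "pooled_locations"),
                             changed_threshold = 1,
                             changed_rule = c("at_least_threshold", "nonzero")) {
  variant <- match.arg(variant)
  pooling <- match.arg(pooling)
  changed_rule <- match.arg(changed_rule)
  d <- prepare_effect_data(data)
  if (variant == "changed_only") {
    d <- if (changed_rule == "nonzero") d[d$change != 0, ]
    else d[d$change >= changed_threshold, ]
  }
  levs <- levels(d$category)
  if (pooling == "pooled_locations") {
    out <- dplyr::summarise(
      dplyr::group_by(d, .data$category, .drop = FALSE),
      mean_change = mean(.data$change),
      se = stats::sd(.data$change) / sqrt(dplyr::n()),
      n = dplyr::n(), n_locations = dplyr::n(), .groups = "drop")
  } else {
    per_pat <- dplyr::summarise(
      dplyr::group_by(d, .data$patient, .data$category, .drop = FALSE),
      m = mean(.data$change), nl = dplyr::n(), .groups = "drop")
    per_pat <- per_pat[per_pat$nl > 0, ] # patients lacking a category drop out
    out <- dplyr::summarise(
      dplyr::group_by(per_pat, .data$category, .drop = FALSE),
      mean_change = mean(.data$m),
      se = stats::sd(.data$m) / sqrt(dplyr::n()),
      n = dplyr::n(),
      n_locations = sum(.data$nl), .groups = "drop")
  }
  out$mean_change[out$n == 0] <- NA_real_
  out$category <- factor(as.character(out$category), levels = levs)
  out <- out[order(out$category), ]
  class(out) <- c("category_effects", class(out))
  attr(out, "variant") <- variant
  attr(out, "pooling") <- pooling
  out
}

# Pooled per-category means for a change vector under a fixed grouping.
# layout is precomputed by perm_layout(); ch must be ordered as layout$ord.
pooled_category_means <- function(ch, layout) {
  sums <- rowsum(ch, layout$gid, reorder = TRUE)
  if (layout$pooling == "pooled_locations") {
    return(as.vector(sums) / layout$counts)
  }
  m <- matrix(NA_real_, layout$n_pat, layout$n_cat)
  m[layout$slots] <- as.vector(sums) / layout$counts
  colMeans(m, na.rm = TRUE)
}

perm_layout <- function(d, pooling) {
  pat <- match(d$patient, unique(d$patient))
  cat_i <- as.integer(d$category)
  n_cat <- nlevels(d$category)
  ord <- order(pat)
  pat <- pat[ord]; cat_i <- cat_i[ord]
  # for per-patient pooling the group id doubles as the column-major linear
  # index of an n_pat x n_cat matrix
  gid <- if (pooling == "pooled_locations") cat_i
  else (cat_i - 1L) * max(pat) + pat
  slots <- sort(unique(gid))
  counts <- as.vector(rowsum(rep(1, length(gid)), gid, reorder = TRUE))
  list(ord = ord, pat = pat, cat = cat_i, gid = gid, slots = slots,
       counts = counts, n_pat = max(pat), n_cat = n_cat, pooling = pooling,
       blocks = split(seq_along(pat), pat))
}

#' Permutation test of category differences in training effect
#'
#' Tests whether the mean dB change in a reference category (default the
#' neural-reserve category Hum-/Ret+) exceeds that of each other category.
#' The null distribution is built by randomly permuting, within each patient,
#' the assignment of observed changes to locations (equivalently the category
#' labels, since per-patient category compositions are preserved) and
#' recomputing the pooled category-mean differences. The p-value uses the
#' standard Monte-Carlo +1 smoothing, `p = (1 + #(null >= obs)) / (1 + B)`.
#'
#' @inheritParams category_effects
#' @param n_iterations Number of label permutations (default 10000; fewer than
#'   100 draws a warning).
#' @param seed Optional integer seed; the ambient RNG state is restored on
#'   exit.
#' @param reference Reference category (default `"HumM_RetP"`).
#' @param alternative `"greater"` (reference exceeds the other category;
#'   default) or `"two.sided"`.
#' @return An object of class `np_permutation` with the observed differences,
#'   per-comparison p-values and null summaries; see [tidy.np_permutation()].
#' @export
permutation_test_categories <- function(data, n_iterations = 10000,
                                        seed = NULL,
                                        reference = "HumM_RetP",
                                        alternative = c("greater", "two.sided"),
                                        pooling = c("per_patient_then_mean",
                                                    "pooled_locations"),
                                        variant = c("all_locations",
                                                    "changed_only"),
                                        changed_threshold = 1) {
  alternative <- match.arg(alternative)
  pooling <- match.arg(pooling)
  variant <- match.arg(variant)
  d <- prepare_effect_data(data)
  if (variant == "changed_only") d <- d[d$change >= changed_threshold, ]
  present <- levels(droplevels(d$category))
  if (length(present) < 2) {
    stop("need at least two non-empty categories", call. = FALSE)
  }
  if (!reference %in% present) {
    stop(sprintf("reference category '%s' is empty", reference), call. = FALSE)
  }
  if (n_iterations < 100) {
    warning("fewer than 100 permutation iterations", call. = FALSE)
  }
  d$category <- droplevels(d$category)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()), add = TRUE)
    set.seed(seed)
  }
  layout <- perm_layout(d, pooling)
  ch <- d$change[layout$ord]
  ref_i <- match(reference, levels(d$category))
  others <- setdiff(seq_along(levels(d$category)), ref_i)

  obs_means <- pooled_category_means(ch, layout)
  observed <- obs_means[ref_i] - obs_means[others]
  null_mat <- matrix(NA_real_, n_iterations, length(others))
  for (b in seq_len(n_iterations)) {
    perm <- unlist(lapply(layout$blocks, function(ix) {
      if (length(ix) > 1) sample(ix) else ix
    }), use.names = FALSE)
    m <- pooled_category_means(ch[perm], layout)
    null_mat[b, ] <- m[ref_i] - m[others]
  }
  p <- vapply(seq_along(others), function(j) {
    if (alternative == "greater") {
      (1 + sum(null_mat[, j] >= observed[j])) / (1 + n_iterations)
    } else {
      (1 + sum(abs(null_mat[, j]) >= abs(observed[j]))) / (1 + n_iterations)
    }
  }, 1)
  comparisons <- tibble::tibble(
    reference = reference,
    category = levels(d$category)[others],
    observed_diff = observed,
    null_mean = colMeans(null_mat),
    null_sd = apply(null_mat, 2, stats::sd),
    null_q95 = apply(null_mat, 2, stats::quantile, probs = 0.95),
    p_value = p
  )
  structure(
    list(comparisons = comparisons, category_means = obs_means,
         categories = levels(d$category), reference = reference,
         n_iterations = n_iterations, seed = seed, alternative = alternative,
         pooling = pooling, variant = variant,
         n_patients = layout$n_pat, n_locations = nrow(d)),
    class = "np_permutation"
  )
}

#' @export
print.np_permutation <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s, %d iterations, %s pooling, %d patients)\n",
    x$alternative, x$n_iterations, x$pooling, x$n_patients))
  print(as.data.frame(x$comparisons[c("reference", "category",
                                      "observed_diff", "p_value")]),
        row.names = FALSE)
  invisible(x)
}

#' Association between recovered neural-reserve locations and goal attainment
#'
#' Ordinary least-squares fit of the per-patient goal-attainment score on the
#' number of neural-reserve locations that improved, with the Pearson
#' correlation and its two-sided p-value.
#'
#' @param data Tibble with one row per patient.
#' @param predictor,score Column names (default `"n_reserve_improved"` and
#'   `"gas"`).
#' @return An object of class `np_association` holding the `lm` fit, `r`,
#'   `p_value`, `slope`, `intercept` and `n`; `r` is `NA` (with a warning)
#'   when the predictor has zero variance.
#' @export
gas_association <- function(data, predictor = "n_reserve_improved",
                            score = "gas") {
  stopifnot(is.data.frame(data), predictor %in% names(data),
            score %in% names(data))
  x <- data[[predictor]]
  y <- data[[score]]
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 patients", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("predictor has zero variance: correlation undefined",
            call. = FALSE)
    return(structure(list(fit = NULL, r = NA_real_, p_value = NA_real_,
                          slope = NA_real_, intercept = NA_real_,
                          n = length(x), predictor = predictor,
                          degenerate = TRUE),
                     class = "np_association"))
  }
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  structure(
    list(fit = fit, r = unname(ct$estimate), p_value = ct$p.value,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         n = length(x), predictor = predictor, degenerate = FALSE),
    class = "np_association"
  )
}

#' @export
print.np_association <- function(x, ...) {
  cat(sprintf("GAS association (n = %d): r = %.3f, p = %.4g, slope = %.3f\n",
              x$n, x$r, x$p_value, x$slope))
  invisible(x)
}

#' Compare mean dB changes of a trained and an untrained cohort
#'
#' Two-sample comparison of per-patient mean sensitivity changes, testing
#' whether training exceeds spontaneous test-retest drift. The default test
#' permutes cohort membership (`n_iterations` reassignments, +1-smoothed
#' one-sided p); a Welch t-test is reported alongside for reference.
#'
#' @param trained,untrained Numeric vectors of per-patient mean dB changes
#'   (each of length >= 2).
#' @param n_iterations Membership permutations (default 10000).
#' @param seed Optional seed (ambient RNG state restored).
#' @return An object of class `np_two_sample` with the observed difference,
#'   permutation p-value, and Welch statistics.
#' @export
pre_post_reliability_compare <- function(trained, untrained,
                                         n_iterations = 10000, seed = NULL) {
  trained <- as.numeric(trained)
  untrained <- as.numeric(untrained)
  if (length(trained) < 2 || length(untrained) < 2) {
    stop("need at least two patients per cohort", call. = FALSE)
  }
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()), add = TRUE)
    set.seed(seed)
  }
  obs <- mean(trained) - mean(untrained)
  pool <- c(trained, untrained)
  n1 <- length(trained)
  null <- vapply(seq_len(n_iterations), function(b) {
    ix <- sample.int(length(pool), n1)
    mean(pool[ix]) - mean(pool[-ix])
  }, 1)
  p_perm <- (1 + sum(null >= obs)) / (1 + n_iterations)
  tt <- stats::t.test(trained, untrained)
  structure(
    list(difference = obs, p_value = p_perm,
         mean_trained = mean(trained), mean_untrained = mean(untrained),
         n_trained = n1, n_untrained = length(untrained),
         t_statistic = unname(tt$statistic), p_welch = tt$p.value,
         n_iterations = n_iterations, seed = seed),
    class = "np_two_sample"
  )
}

#' @export
print.np_two_sample <- function(x, ...) {
  cat(sprintf(
    "Trained (n=%d, mean %.3f dB) vs untrained (n=%d, mean %.3f dB)\n",
    x$n_trained, x$mean_trained, x$n_untrained, x$mean_untrained))
  cat(sprintf("difference %.3f dB, one-sided permutation p = %.4g\n",
              x$difference, x$p_value))
  invisible(x)
}

#' Paired t-tests of Humphrey reliability indices across sessions
#'
#' QC report comparing per-patient reliability indices (fixation losses,
#' false positives/negatives, blind-spot false detections) before vs after
#' training; a non-significant result supports pooling sessions.
#'
#' @param pre,post Tibbles with one row per patient and numeric index
#'   columns; shared numeric columns are compared (rows aligned by position).
#' @return A tibble with one row per index: means, paired t statistic, df and
#'   two-sided p.
#' @export
reliability_ttests <- function(pre, post) {
  stopifnot(is.data.frame(pre), is.data.frame(post), nrow(pre) == nrow(post))
  idx <- intersect(names(pre)[vapply(pre, is.numeric, TRUE)],
                   names(post)[vapply(post, is.numeric, TRUE)])
  purrr::map_dfr(idx, function(nm) {
    tt <- tryCatch(stats::t.test(pre[[nm]], post[[nm]], paired = TRUE),
                   error = function(e) NULL) # constant differences
    tibble::tibble(index = nm, mean_pre = mean(pre[[nm]]),
                   mean_post = mean(post[[nm]]),
                   t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                   df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
                   p_value = if (is.null(tt)) NA_real_ else tt$p.value)
  })
}
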