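#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a permutation test result
#'
#' @param x An `np_permutation` object.
#' @param ... Unused.
#' @return One row per pairwise comparison: `reference`, `category`,
#'   `observed_diff`, `null_mean`, `null_sd`, `null_q95`, `p_value`.
#' @method tidy np_permutation
#' @export
tidy.np_permutation <- function(x, ...) {
  x$comparisons
}

#' @rdname tidy.np_permutation
#' @return `glance()`: one row with the test settings and the smallest
#'   p-value.
#' @method glance np_permutation
#' @export
glance.np_permutation <- function(x, ...) {
  tibble::tibble(
    reference = x$reference, n_comparisons = nrow(x$comparisons),
    n_iterations = x$n_iterations, alternative = x$alternative,
    pooling = x$pooling, variant = x$variant,
    n_patients = x$n_patients, n_locations = x$n_locations,
    min_p_value = min(x$comparisons$p_value)
  )
}

#' Tidy a goal-attainment association
#'
#' @param x An `np_association` object.
#' @param ... Unused.
#' @return `tidy()`: the linear-model coefficient table; `glance()`: one row
#'   with `r`, `p_value`, `slope`, `intercept`, `n` and `degenerate`.
#' @method tidy np_association
#' @export
tidy.np_association <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), statistic = numeric(),
                          p.value = numeric()))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("(Intercept)", x$predictor),
                 estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname tidy.np_association
#' @method glance np_association
#' @export
glance.np_association <- function(x, ...) {
  tibble::tibble(r = x$r, p_value = x$p_value, slope = x$slope,
                 intercept = x$intercept, n = x$n, degenerate = x$degenerate)
}

#' Tidy a trained-vs-untrained comparison
#'
#' @param x An `np_two_sample` object.
#' @param ... Unused.
#' @return A one-row tibble with the group means, difference, permutation p
#'   and Welch reference statistics.
#' @method tidy np_two_sample
#' @export
tidy.np_two_sample <- function(x, ...) {
  tibble::tibble(
    mean_trained = x$mean_trained, mean_untrained = x$mean_untrained,
    difference = x$difference, p_value = x$p_value,
    t_statistic = x$t_statistic, p_welch = x$p_welch,
    n_trained = x$n_trained, n_untrained = x$n_untrained
  )
}

#' @rdname tidy.np_two_sample
#' @method glance np_two_sample
#' @export
glance.np_two_sample <- function(x, ...) {
  tidy.np_two_sample(x)
}
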