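#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods render the pipeline's objects with ggplot2: stimulus
#' aperture frames, pixel-level coverage maps, Humphrey dB maps, downsampled
#' neural perimetry, the category classification, and the permutation null
#' distribution. [plot_category_effects()] draws the per-category training
#' effect with standard-error bars.
#'
#' @param object The object to plot.
#' @param frame Frame index for apertures.
#' @param ... Unused.
#' @name neuroreserve-plots
NULL

#' @rdname neuroreserve-plots
#' @method autoplot stim_aperture
#' @export
autoplot.stim_aperture <- function(object, frame = 1, ...) {
  co <- raster_coords(object$raster)
  co$on <- object$frames[, frame]
  ggplot2::ggplot(co, ggplot2::aes(.data$px, .data$py, fill = .data$on)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s aperture, frame %d", object$kind, frame),
                  x = "x (deg)", y = "y (deg)")
}

#' @rdname neuroreserve-plots
#' @method autoplot coverage_map
#' @export
autoplot.coverage_map <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$px, .data$py, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "coverage") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)",
                  title = sprintf("pRF coverage (%d voxels)", object$n_voxels))
}

#' @rdname neuroreserve-plots
#' @method autoplot perimetry_map
#' @export
autoplot.perimetry_map <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x_deg, .data$y_deg,
                                  fill = .data$db)) +
    ggplot2::geom_tile(width = 6, height = 6, colour = "grey30") +
    ggplot2::geom_point(data = d[d$blind_spot, ], shape = 4, size = 3) +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)",
                  title = sprintf("Humphrey 30-2 (%s eye, %s)",
                                  attr(object, "eye"), attr(object, "session")))
}

#' @rdname neuroreserve-plots
#' @method autoplot neural_perimetry_map
#' @export
autoplot.neural_perimetry_map <- function(object, ...) {
  d <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x_deg, .data$y_deg,
                                       fill = .data$value)) +
    ggplot2::geom_tile(width = 6, height = 6, colour = "grey30") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "coverage") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)", title = "Neural perimetry")
  if ("covered" %in% names(d)) {
    p <- p + ggplot2::geom_point(data = d[d$covered == 0, ], shape = 4,
                                 size = 3, colour = "white")
  }
  p
}

#' @rdname neuroreserve-plots
#' @method autoplot np_classification
#' @export
autoplot.np_classification <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$x_deg, .data$y_deg,
                               fill = .data$category)) +
    ggplot2::geom_tile(width = 6, height = 6, colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(
      HumP_RetP = "#4daf4a", HumP_RetM = "#984ea3",
      HumM_RetP = "#377eb8", HumM_RetM = "#e41a1c",
      excluded = "grey70"), drop = FALSE, name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)",
                  title = "Humphrey / retinotopy mismatch categories")
}

#' @rdname neuroreserve-plots
#' @method autoplot np_permutation
#' @export
autoplot.np_permutation <- function(object, ...) {
  d <- object$comparisons
  ggplot2::ggplot(d, ggplot2::aes(.data$category, .data$observed_diff)) +
    ggplot2::geom_col(fill = "#377eb8") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$null_mean,
                                        ymax = .data$null_q95),
                           width = 0.25, colour = "grey40") +
    ggplot2::labs(x = NULL, y = "difference in mean dB change",
                  title = sprintf("%s minus other categories (p: %s)",
                                  object$reference,
                                  paste(signif(d$p_value, 2),
                                        collapse = ", ")))
}

#' @rdname neuroreserve-plots
#' @param effects A [category_effects()] tibble.
#' @export
plot_category_effects <- function(effects, ...) {
  stopifnot(inherits(effects, "category_effects"))
  d <- effects[!is.na(effects$mean_change), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$category, .data$mean_change)) +
    ggplot2::geom_col(fill = "#377eb8") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_change - .data$se,
                                        ymax = .data$mean_change + .data$se),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "mean dB change",
                  title = sprintf("Training effect by category (%s)",
                                  attr(effects, "variant")))
}
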