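#' Visual-field coverage map from pRF estimates
#'
#' At every raster pixel the coverage value is the maximum over voxels of the
#' voxel's Gaussian pRF profile at unit peak amplitude,
#' `exp(-((px-x0)^2+(py-y0)^2)/(2 sigma^2))`. Amplitudes (`beta`) do not
#' weight the profiles: only the spatial footprint of responsive tissue
#' matters, which keeps values in `[0, 1]` by construction.
#'
#' @param estimates A (typically [filter_estimates()]-ed) tibble with columns
#'   `x0`, `y0`, `sigma`.
#' @param raster A [vf_raster()] (default 181 x 181 at 0.5 deg).
#' @return A `coverage_map`: list with `values` (one per pixel, aligned with
#'   [raster_coords()]), `raster`, `n_voxels` and the `ve_min` provenance when
#'   present on `estimates`. An empty estimate set yields an all-zero map with
#'   a warning.
#' @export
coverage_from_estimates <- function(estimates, raster = vf_raster()) {
  stopifnot(is.data.frame(estimates), inherits(raster, "vf_raster"),
            all(c("x0", "y0", "sigma") %in% names(estimates)))
  co <- raster_coords(raster)
  values <- numeric(nrow(co))
  if (nrow(estimates) == 0) {
    warning("no pRF estimates: returning an all-zero coverage map",
            call. = FALSE)
  } else {
    for (i in seq_len(nrow(estimates))) {
      g <- exp(-((co$px - estimates$x0[i])^2 + (co$py - estimates$y0[i])^2) /
                 (2 * estimates$sigma[i]^2))
      values <- pmax(values, g)
    }
  }
  structure(list(values = values, raster = raster,
                 n_voxels = nrow(estimates),
                 ve_min = attr(estimates, "ve_min")),
            class = "coverage_map")
}

#' @export
print.coverage_map <- function(x, ...) {
  cat(sprintf("<coverage_map> %d voxels, max %.3f\n", x$n_voxels,
              max(x$values)))
  print(x$raster)
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble coverage_map
#' @export
as_tibble.coverage_map <- function(x, ...) {
  out <- raster_coords(x$raster)
  out$value <- x$values
  out
}

#' Downsample a coverage map to the perimetric grid
#'
#' Each 30-2 test location owns the half-open 6 x 6 deg cell
#' `[x-3, x+3) x [y-3, y+3)`; cells partition the plane so no pixel is counted
#' twice. The per-location value is the maximum (default) coverage inside the
#' cell, after which all location values are renormalised by their global
#' maximum (when positive) so the map ranges 0-1 across locations.
#'
#' @param coverage A [coverage_from_estimates()] result.
#' @param grid A [make_302_grid()].
#' @param aggregate Cell aggregation, `"max"` (default, the coverage reading)
#'   or `"mean"` (for sensitivity analysis).
#' @return A tibble of class `neural_perimetry_map`: grid columns plus
#'   `value_raw` (pre-renormalisation) and `value`.
#' @export
downsample_to_grid <- function(coverage, grid = make_302_grid(),
                               aggregate = c("max", "mean")) {
  stopifnot(inherits(coverage, "coverage_map"),
            inherits(grid, "perimetric_grid"))
  aggregate <- match.arg(aggregate)
  co <- raster_coords(coverage$raster)
  he <- coverage$raster$half_extent
  if (any(abs(grid$x_deg) + 3 > he + 1e-9) ||
      any(abs(grid$y_deg) + 3 > he + 1e-9)) {
    stop("a 6x6 deg grid cell lies outside the raster", call. = FALSE)
  }
  agg <- if (aggregate == "max") max else mean
  value_raw <- vapply(seq_len(nrow(grid)), function(i) {
    sel <- co$px >= grid$x_deg[i] - 3 & co$px < grid$x_deg[i] + 3 &
      co$py >= grid$y_deg[i] - 3 & co$py < grid$y_deg[i] + 3
    if (!any(sel)) stop("empty grid cell on this raster", call. = FALSE)
    agg(coverage$values[sel])
  }, 1)
  mx <- max(value_raw)
  out <- grid
  out$value_raw <- value_raw
  out$value <- if (mx > 0) value_raw / mx else value_raw
  class(out) <- unique(c("neural_perimetry_map", class(out)))
  attr(out, "aggregate") <- aggregate
  attr(out, "n_voxels") <- coverage$n_voxels
  attr(out, "ve_min") <- coverage$ve_min
  out
}

#' Construct a neural perimetry map directly from per-location values
#'
#' Entry point for simulated or externally computed per-location coverage:
#' applies the same global-maximum renormalisation as [downsample_to_grid()].
#'
#' @param values Numeric coverage values in `[0, 1]`, one per grid location.
#' @param grid A [make_302_grid()].
#' @return A `neural_perimetry_map` tibble.
#' @export
neural_perimetry_from_values <- function(values, grid = make_302_grid()) {
  stopifnot(is.numeric(values), length(values) == nrow(grid),
            all(values >= 0), all(values <= 1))
  out <- grid
  out$value_raw <- values
  mx <- max(values)
  out$value <- if (mx > 0) values / mx else values
  class(out) <- unique(c("neural_perimetry_map", class(out)))
  out
}

#' Binarise a neural perimetry map
#'
#' A location counts as neurally covered (Ret+) when its renormalised value
#' strictly exceeds `threshold`. When the pre-renormalisation values would
#' binarise differently, a message notes the discrepancy (the two
#' normalisation readings of the coverage pipeline differ only in that case).
#'
#' @param npmap A `neural_perimetry_map`.
#' @param threshold Coverage threshold in (0, 1), default 0.5 (0.25 and 0.75
#'   probe robustness).
#' @return `npmap` with an integer `covered` column and a `threshold`
#'   attribute.
#' @export
binarize_coverage <- function(npmap, threshold = 0.5) {
  stopifnot(inherits(npmap, "neural_perimetry_map"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  covered <- as.integer(npmap$value > threshold)
  raw <- as.integer(npmap$value_raw > threshold)
  if (any(covered != raw)) {
    message(sprintf(paste0("binarize_coverage: renormalisation changes %d ",
                           "location(s) at threshold %g"),
                    sum(covered != raw), threshold))
  }
  npmap$covered <- covered
  attr(npmap, "threshold") <- threshold
  npmap
}
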