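#' Visual-field region primitives
#'
#' Composable regions in visual-field coordinates used to describe behavioural
#' scotomas and spared islands: hemifields, quadrants, polar-angle sectors and
#' circles, plus unions. Every primitive supports a membership test and an
#' interior "depth" (distance to the region border, 0 outside), which
#' implements the reserve-margin mechanism (a neural scotoma strictly inside
#' the behavioural one).
#'
#' @param side `"left"`, `"right"`, `"upper"` or `"lower"` (visual field).
#' @return A `vf_region` object.
#' @export
region_hemifield <- function(side = c("left", "right", "upper", "lower")) {
  side <- match.arg(side)
  structure(list(type = "hemifield", side = side), class = "vf_region")
}

#' @rdname region_hemifield
#' @param which Quadrant name, e.g. `"upper_left"`.
#' @export
region_quadrant <- function(which = c("upper_left", "upper_right",
                                      "lower_left", "lower_right")) {
  which <- match.arg(which)
  structure(list(type = "quadrant", which = which), class = "vf_region")
}

#' @rdname region_hemifield
#' @param start_angle,end_angle Sector limits in degrees, counterclockwise
#'   from the positive x axis; the sector runs counterclockwise from start to
#'   end.
#' @export
region_sector <- function(start_angle, end_angle) {
  structure(list(type = "sector", start = start_angle %% 360,
                 end = end_angle %% 360), class = "vf_region")
}

#' @rdname region_hemifield
#' @param x,y,radius Circle centre and radius in degrees.
#' @export
region_circle <- function(x, y, radius) {
  stopifnot(radius > 0)
  structure(list(type = "circle", x = x, y = y, radius = radius),
            class = "vf_region")
}

#' @rdname region_hemifield
#' @param ... `vf_region`s to combine.
#' @export
region_union <- function(...) {
  members <- list(...)
  stopifnot(length(members) >= 1,
            all(vapply(members, inherits, TRUE, "vf_region")))
  structure(list(type = "union", members = members), class = "vf_region")
}

#' Region membership and interior depth
#'
#' @param region A `vf_region` (or `NULL`, treated as the empty region).
#' @param x,y Coordinates in degrees (vectorised).
#' @return `region_contains()`: logical vector. `region_depth()`: distance
#'   from each interior point to the region border in degrees (0 outside; a
#'   lower bound for unions).
#' @export
region_contains <- function(region, x, y) {
  if (is.null(region)) return(rep(FALSE, length(x)))
  stopifnot(inherits(region, "vf_region"))
  switch(region$type,
    hemifield = switch(region$side,
      left = x < 0, right = x > 0, upper = y > 0, lower = y < 0),
    quadrant = switch(region$which,
      upper_left = x < 0 & y > 0, upper_right = x > 0 & y > 0,
      lower_left = x < 0 & y < 0, lower_right = x > 0 & y < 0),
    sector = {
      ang <- (atan2(y, x) * 180 / pi) %% 360
      span <- (region$end - region$start) %% 360
      (ang - region$start) %% 360 <= span & (x != 0 | y != 0)
    },
    circle = (x - region$x)^2 + (y - region$y)^2 <= region$radius^2,
    union = Reduce(`|`, lapply(region$members, region_contains, x = x, y = y))
  )
}

#' @rdname region_contains
#' @export
region_depth <- function(region, x, y) {
  if (is.null(region)) return(rep(0, length(x)))
  stopifnot(inherits(region, "vf_region"))
  inside <- region_contains(region, x, y)
  d <- switch(region$type,
    hemifield = switch(region$side,
      left = -x, right = x, upper = y, lower = -y),
    quadrant = switch(region$which,
      upper_left = pmin(-x, y), upper_right = pmin(x, y),
      lower_left = pmin(-x, -y), lower_right = pmin(x, -y)),
    sector = {
      ang <- (atan2(y, x) * 180 / pi) %% 360
      span <- (region$end - region$start) %% 360
      off <- (ang - region$start) %% 360
      ecc <- sqrt(x^2 + y^2)
      pmin(off, span - off) * pi / 180 * ecc # arc distance to either edge
    },
    circle = region$radius - sqrt((x - region$x)^2 + (y - region$y)^2),
    union = Reduce(pmax, lapply(region$members, region_depth, x = x, y = y))
  )
  ifelse(inside, pmax(d, 0), 0)
}

#' Lesion specification
#'
#' A behavioural scotoma region with optional spared islands of responsive
#' tissue inside it and an optional reserve margin. Neural reserve arises from
#' both mechanisms: voxels inside a spared island survive although the
#' location is behaviourally blind, and with `reserve_margin > 0` the neural
#' scotoma is the behavioural scotoma eroded by that margin, so a band just
#' inside the behavioural border remains cortically responsive.
#'
#' @param scotoma A `vf_region` (or `NULL` for no lesion).
#' @param islands Optional tibble with columns `x`, `y`, `radius`: spared
#'   islands; centres must lie inside the scotoma.
#' @param reserve_margin Erosion depth in degrees (default 0).
#' @return A `lesion_spec` object.
#' @export
lesion_spec <- function(scotoma = NULL, islands = NULL, reserve_margin = 0) {
  stopifnot(is.null(scotoma) || inherits(scotoma, "vf_region"),
            reserve_margin >= 0)
  if (!is.null(islands)) {
    stopifnot(is.data.frame(islands),
              all(c("x", "y", "radius") %in% names(islands)))
    if (!is.null(scotoma) &&
        !all(region_contains(scotoma, islands$x, islands$y))) {
      stop("island centres must lie inside the scotoma", call. = FALSE)
    }
  }
  structure(list(scotoma = scotoma, islands = islands,
                 reserve_margin = reserve_margin),
            class = "lesion_spec")
}

#' Behavioural and neural scotoma membership
#'
#' @param lesion A [lesion_spec()].
#' @param x,y Coordinates in degrees.
#' @return Logical vectors: `in_behavioral_scotoma()` tests the perimetric
#'   (awareness) scotoma; `in_neural_scotoma()` tests where cortex is actually
#'   silent (behavioural scotoma minus islands and minus the reserve margin).
#' @export
in_behavioral_scotoma <- function(lesion, x, y) {
  stopifnot(inherits(lesion, "lesion_spec"))
  region_contains(lesion$scotoma, x, y)
}

#' @rdname in_behavioral_scotoma
#' @export
in_neural_scotoma <- function(lesion, x, y) {
  stopifnot(inherits(lesion, "lesion_spec"))
  inside <- region_contains(lesion$scotoma, x, y)
  if (!any(inside)) return(inside)
  deep <- region_depth(lesion$scotoma, x, y) > lesion$reserve_margin
  in_island <- rep(FALSE, length(x))
  if (!is.null(lesion$islands)) {
    for (i in seq_len(nrow(lesion$islands))) {
      in_island <- in_island |
        ((x - lesion$islands$x[i])^2 + (y - lesion$islands$y[i])^2 <=
           lesion$islands$radius[i]^2)
    }
  }
  inside & deep & !in_island
}
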