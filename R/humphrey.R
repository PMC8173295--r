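#' Construct the SITA 30-2 perimetric grid
#'
#' The Humphrey 30-2 pattern tests 76 locations (38 per hemifield) on a 10x10
#' lattice at x, y in {+/-3, +/-9, +/-15, +/-21, +/-27} degrees; the six
#' corner points per quadrant with eccentricity > 30 deg or with both
#' |x| >= 21 and |y| >= 21 are not tested. The physiological blind spot
#' candidate is the single temporal location (15, -3) mirrored for the tested
#' eye (x = +15 for the right eye, -15 for the left).
#'
#' @param eye Tested eye, `"right"` or `"left"`.
#' @return A tibble of class `perimetric_grid` with 76 rows in raster order
#'   (y descending, x ascending): `x_deg`, `y_deg`, `ecc`, `hemifield`
#'   (`"left"`/`"right"` visual field) and `blind_spot`.
#' @examples
#' nrow(make_302_grid()) # 76
#' @export
make_302_grid <- function(eye = c("right", "left")) {
  eye <- match.arg(eye)
  vals <- c(-27, -21, -15, -9, -3, 3, 9, 15, 21, 27)
  g <- tidyr::expand_grid(y_deg = rev(vals), x_deg = vals)
  g$ecc <- sqrt(g$x_deg^2 + g$y_deg^2)
  g <- g[!(g$ecc > 30 | (abs(g$x_deg) >= 21 & abs(g$y_deg) >= 21)), ]
  g$hemifield <- ifelse(g$x_deg < 0, "left", "right")
  bs_x <- if (eye == "right") 15 else -15
  g$blind_spot <- g$x_deg == bs_x & g$y_deg == -3
  g <- g[c("x_deg", "y_deg", "ecc", "hemifield", "blind_spot")]
  attr(g, "eye") <- eye
  class(g) <- c("perimetric_grid", class(g))
  g
}

#' Assemble a Humphrey perimetry map
#'
#' Bundles per-location dB sensitivities with the 30-2 grid and session
#' metadata. Sensitivities below 0 dB (device output "<0") are coerced to 0
#' with a warning; values above the 50 dB sanity cap are rejected.
#'
#' @param db Numeric vector of sensitivities, one per grid location, in grid
#'   row order.
#' @param grid A [make_302_grid()] result (defines the tested eye).
#' @param session Session label, e.g. `"pre"` or `"post"`.
#' @param reliability Named list of reliability indices as fractions in
#'   `[0, 1]`: `fixation_losses`, `false_positive`, `false_negative`,
#'   `blindspot_fp` (false detections during blind-spot probing).
#' @param subject Optional subject identifier.
#' @return A tibble of class `perimetry_map`: the grid plus a `db` column,
#'   with `eye`, `session`, `reliability` and `subject` attributes.
#' @export
perimetry_map <- function(db, grid = make_302_grid(), session = "pre",
                          reliability = NULL, subject = NULL) {
  stopifnot(inherits(grid, "perimetric_grid"), is.numeric(db),
            length(db) == nrow(grid))
  if (any(db > 50)) stop("dB sensitivity above the 50 dB sanity cap",
                         call. = FALSE)
  if (any(db < 0)) {
    warning("negative dB sensitivities coerced to 0", call. = FALSE)
    db <- pmax(db, 0)
  }
  if (!is.null(reliability)) {
    fr <- unlist(reliability)
    if (any(fr < 0 | fr > 1)) {
      stop("reliability indices must be fractions in [0, 1]", call. = FALSE)
    }
  }
  out <- grid
  out$db <- db
  attr(out, "eye") <- attr(grid, "eye")
  attr(out, "session") <- session
  attr(out, "reliability") <- reliability
  attr(out, "subject") <- subject
  class(out) <- unique(c("perimetry_map", class(out)))
  out
}

#' Reliability quality control of a perimetry map
#'
#' Applies the standard clinical exclusion criterion: a session fails when
#' more than `max_blindspot_fp` (default 20%) of blind-spot probes were
#' falsely detected. Other indices (fixation losses, false
#' positives/negatives) are reported but do not gate.
#'
#' @param map A [perimetry_map()].
#' @param max_blindspot_fp Gate on blind-spot false detections; failure is
#'   strictly greater than this fraction (default 0.20).
#' @return One-row tibble: `pass` (logical, `NA` when indices are missing),
#'   `status` (`"pass"`, `"fail"`, `"indeterminate"`), `blindspot_fp`, the
#'   other indices, and `reason`.
#' @export
qc_reliability <- function(map, max_blindspot_fp = 0.20) {
  stopifnot(inherits(map, "perimetry_map"))
  rel <- attr(map, "reliability")
  get <- function(nm) if (!is.null(rel[[nm]])) rel[[nm]] else NA_real_
  bs <- get("blindspot_fp")
  if (is.na(bs)) {
    return(tibble::tibble(pass = NA, status = "indeterminate",
                          blindspot_fp = NA_real_,
                          fixation_losses = get("fixation_losses"),
                          false_positive = get("false_positive"),
                          false_negative = get("false_negative"),
                          reason = "blind-spot false-detection index missing"))
  }
  fail <- bs > max_blindspot_fp
  tibble::tibble(
    pass = !fail,
    status = if (fail) "fail" else "pass",
    blindspot_fp = bs,
    fixation_losses = get("fixation_losses"),
    false_positive = get("false_positive"),
    false_negative = get("false_negative"),
    reason = if (fail) {
      sprintf("blind-spot false detection %.0f%% exceeds %.0f%%",
              100 * bs, 100 * max_blindspot_fp)
    } else NA_character_
  )
}

#' Per-location dB change between two sessions
#'
#' `change = post - pre` at every test location. The blind-spot location is
#' marked excluded; it never enters downstream summaries or category
#' statistics.
#'
#' @param pre,post [perimetry_map()]s on the same grid and eye.
#' @return A tibble of class `perimetry_change`: grid columns plus `change`
#'   and `excluded`.
#' @export
change_map <- function(pre, post) {
  stopifnot(inherits(pre, "perimetry_map"), inherits(post, "perimetry_map"))
  same <- identical(pre$x_deg, post$x_deg) && identical(pre$y_deg, post$y_deg) &&
    identical(attr(pre, "eye"), attr(post, "eye"))
  if (!same) stop("pre and post maps are not on the same grid/eye",
                  call. = FALSE)
  out <- tibble::tibble(
    x_deg = pre$x_deg, y_deg = pre$y_deg, ecc = pre$ecc,
    hemifield = pre$hemifield, blind_spot = pre$blind_spot,
    change = post$db - pre$db,
    excluded = pre$blind_spot
  )
  class(out) <- c("perimetry_change", class(out))
  attr(out, "eye") <- attr(pre, "eye")
  out
}

#' Summarise a dB change map
#'
#' Mean dB change and the count of locations that improved by at least
#' `improvement_threshold` dB (inclusive), over non-excluded locations.
#'
#' @param change A [change_map()] result, or a bare numeric change vector.
#' @param improvement_threshold Improvement cutoff in dB (default 1).
#' @return One-row tibble: `mean_change`, `n_improved`, `n_locations`.
#' @export
summarize_change <- function(change, improvement_threshold = 1) {
  if (is.data.frame(change)) {
    v <- change$change[!change$excluded]
  } else {
    v <- as.numeric(change)
  }
  tibble::tibble(
    mean_change = mean(v),
    n_improved = sum(v >= improvement_threshold),
    n_locations = length(v)
  )
}

#' Read / write a perimetry map as CSV plus JSON sidecar
#'
#' The CSV holds `x_deg`, `y_deg`, `db` in raster order (y descending, x
#' ascending); the sidecar `<path>.json` holds eye, session, reliability
#' indices and subject id. Round-tripping is exact on the tabular
#' representation.
#'
#' @param map A [perimetry_map()].
#' @param path CSV path.
#' @return `write_perimetry_csv()` returns `path` invisibly;
#'   `read_perimetry_csv()` returns the `perimetry_map`.
#' @export
write_perimetry_csv <- function(map, path) {
  stopifnot(inherits(map, "perimetry_map"))
  readr::write_csv(tibble::tibble(x_deg = map$x_deg, y_deg = map$y_deg,
                                  db = map$db), path)
  jsonlite::write_json(
    list(eye = attr(map, "eye"), session = attr(map, "session"),
         reliability = attr(map, "reliability"),
         subject = attr(map, "subject")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_perimetry_csv
#' @export
read_perimetry_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- make_302_grid(meta$eye)
  key_in <- paste(tab$x_deg, tab$y_deg)
  db <- tab$db[match(paste(grid$x_deg, grid$y_deg), key_in)]
  if (anyNA(db)) stop("CSV does not cover the full 30-2 grid", call. = FALSE)
  rel <- meta$reliability
  if (length(rel) == 0) rel <- NULL
  perimetry_map(db, grid, session = meta$session, reliability = rel,
                subject = meta$subject)
}
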