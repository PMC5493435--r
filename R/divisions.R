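# Asymmetric-division outcome statistics: daughter-cell segregation ratios
# and signed division angles relative to the anterior-posterior body axis.

#' Daughter-cell segregation ratio
#'
#' Ratio of the smaller to the larger daughter-cell reporter intensity
#' (pII_min / pII_max) after an asymmetric division. Ratios approach 1 for
#' equal (failed asymmetric) segregation and 0 for complete segregation
#' into one daughter. Symmetric in the two daughters and invariant to a
#' common intensity rescaling. Vectorized over records.
#'
#' @param intensity_a,intensity_b Nonnegative grey values of the two
#'   daughter cells (daughter labels are interchangeable).
#' @return Numeric vector of ratios in (0, 1]; equal intensities
#'   (including the degenerate 0/0-avoiding tie) give exactly 1.
#' @examples
#' segregation_ratio(5, 10)
#' segregation_ratio(c(10, 10), c(10, 5))
#' @export
segregation_ratio <- function(intensity_a, intensity_b) {
  stopifnot(length(intensity_a) == length(intensity_b))
  if (any(intensity_a < 0 | intensity_b < 0)) {
    abort("daughter intensities must be nonnegative", class = "crescentr_error")
  }
  hi <- pmax(intensity_a, intensity_b)
  lo <- pmin(intensity_a, intensity_b)
  if (any(hi == 0)) {
    abort("both daughter intensities are zero; ratio undefined",
      class = "crescentr_error")
  }
  ifelse(lo == hi, 1, lo / hi)
}

#' Signed division angle relative to the anterior-posterior axis
#'
#' Signed angle from the anterior-posterior reference axis (0 degrees) to
#' the daughter-daughter displacement axis, in degrees in (-180, 180].
#' Rotations that appear clockwise in the viewer's frame (image
#' coordinates, y increasing downward) are positive; counterclockwise
#' rotations are negative. Computed by `atan2` of the cross and dot
#' products, never by modular arithmetic on raw degrees. Note that negating
#' the daughter axis (swapping which daughter is called anterior) shifts
#' the angle by 180 degrees.
#'
#' @param axis_dx,axis_dy Components of the displacement vector from the
#'   anterior to the posterior daughter centroid (image coordinates).
#' @param ap_dx,ap_dy Components of the anterior-posterior reference axis
#'   (default `(1, 0)`). Vectorized over records.
#' @return Numeric vector of degrees in (-180, 180], reported to 0.01
#'   degree precision.
#' @examples
#' division_angle(1, 0) # aligned with the A-P axis
#' division_angle(0, 1) # 90 degrees clockwise in the viewer frame
#' @export
division_angle <- function(axis_dx, axis_dy, ap_dx = 1, ap_dy = 0) {
  n <- max(length(axis_dx), length(axis_dy))
  axis_dx <- rep_len(axis_dx, n); axis_dy <- rep_len(axis_dy, n)
  ap_dx <- rep_len(ap_dx, n); ap_dy <- rep_len(ap_dy, n)
  if (any(axis_dx == 0 & axis_dy == 0)) {
    abort("daughter axis has zero length; angle undefined",
      class = "crescentr_error")
  }
  if (any(ap_dx == 0 & ap_dy == 0)) {
    abort("anterior-posterior axis has zero length", class = "crescentr_error")
  }
  # in the y-down image frame, a positive z-component of ap x axis is a
  # clockwise rotation as seen by the viewer
  cross <- ap_dx * axis_dy - ap_dy * axis_dx
  dot <- ap_dx * axis_dx + ap_dy * axis_dy
  round(wrap_degrees(atan2(cross, dot) * 180 / pi), 2)
}

#' Dispersion of signed division angles
#'
#' Summarizes the angular scatter of a population of divisions. The
#' primary statistic is the arithmetic sample standard deviation (n - 1
#' denominator) of the signed angles — the convention under which a
#' perfectly aligned population scores 0 and a uniformly randomized one
#' about 104 degrees; the circular standard deviation
#' `sqrt(-2 log R) * 180/pi` (R the mean resultant length) is reported
#' alongside as the wrap-safe companion.
#'
#' @param angles Numeric vector (>= 2) of signed angles in degrees.
#' @return A one-row tibble: `n`, `mean_deg` (circular mean), `sd_arith`,
#'   `sd_circ`.
#' @examples
#' angle_dispersion(c(-30, 0, 30))
#' @export
angle_dispersion <- function(angles) {
  angles <- as.numeric(angles)
  if (length(angles) < 2) {
    abort("at least 2 angles are needed for a dispersion estimate",
      class = "crescentr_error")
  }
  rad <- angles * pi / 180
  rbar <- sqrt(mean(cos(rad))^2 + mean(sin(rad))^2)
  tibble(
    n = length(angles),
    mean_deg = wrap_degrees(atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi),
    sd_arith = sd(angles),
    sd_circ = if (rbar > 0) sqrt(-2 * log(rbar)) * 180 / pi else Inf
  )
}

#' Polarization coefficient of a division record's crescent
#'
#' Convenience re-export of [polarization_coefficient()] for use in
#' division-level reports (the per-cell crescent profile travels with the
#' division record in populations from [simulate_divisions()]).
#'
#' @inheritParams polarization_coefficient
#' @return A `polarity_score`.
#' @export
polarization_of_crescent <- function(profile) polarization_coefficient(profile)

#' Per-cell division outcomes and group summary
#'
#' Computes the segregation ratio and signed division angle for every
#' record of a division table, and (via [glance()]) the group-level
#' summary: n, mean ratio, arithmetic and circular angle SD. When records
#' carry a cortical `profile` list column, each cell's polarization
#' coefficient P is added.
#'
#' @param records Data frame with columns `intensity_a`, `intensity_b`,
#'   `axis_dx`, `axis_dy` and optionally `ap_dx`, `ap_dy` (default axis
#'   `(1, 0)`), `cell_id`, and a `profile` list column.
#' @return A tibble of class `division_summary`: one row per cell with
#'   `ratio` and `angle_deg` (and `P` when profiles are present).
#' @examples
#' pop <- simulate_divisions(division_spec(n_cells = 10, seed = 1))
#' per_cell <- summarize_divisions(pop)
#' glance(per_cell)
#' @export
summarize_divisions <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("intensity_a", "intensity_b", "axis_dx", "axis_dy")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort(paste0("division table lacks column(s): ",
      paste(missing, collapse = ", ")), class = "crescentr_error")
  }
  ap_dx <- if ("ap_dx" %in% names(records)) records$ap_dx else 1
  ap_dy <- if ("ap_dy" %in% names(records)) records$ap_dy else 0
  out <- tibble(
    cell_id = if ("cell_id" %in% names(records)) records$cell_id else
      sprintf("cell%03d", seq_len(nrow(records))),
    ratio = segregation_ratio(records$intensity_a, records$intensity_b),
    angle_deg = division_angle(records$axis_dx, records$axis_dy, ap_dx, ap_dy)
  )
  if ("profile" %in% names(records)) {
    out$P <- purrr::map_dbl(records$profile,
      function(p) polarization_coefficient(p)$P)
  }
  structure(out, class = c("division_summary", class(tibble())))
}

#' @export
glance.division_summary <- function(x, ...) {
  disp <- angle_dispersion(x$angle_deg)
  res <- tibble(
    n = nrow(x),
    mean_ratio = mean(x$ratio),
    sd_ratio = sd(x$ratio),
    angle_mean_deg = disp$mean_deg,
    angle_sd_arith = disp$sd_arith,
    angle_sd_circ = disp$sd_circ
  )
  if ("P" %in% names(x)) {
    res$mean_P <- mean(x$P)
    res$sd_P <- sd(x$P)
  }
  res
}

#' @export
tidy.division_summary <- function(x, ...) as_tibble(x)
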