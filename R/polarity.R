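# Circular harmonic polarity statistics.
#
# Both statistics place sample k at angle theta_k = 2*pi*k/N around the cell
# perimeter and project the mean-normalized intensities onto the first
# (unipolar crescent) or second (bipolar, axis-like) circular harmonic. The
# magnitudes are invariant to the start index and traversal direction of the
# outline; only the reported phase depends on them.

harmonic_components <- function(values, harmonic) {
  n <- length(values)
  theta <- harmonic * 2 * pi * seq_len(n) / n
  c(
    cos = sum(values * cos(theta)) / n,
    sin = sum(values * sin(theta)) / n
  )
}

# map degrees into (-180, 180]
wrap_degrees <- function(deg) {
  out <- deg - 360 * floor(deg / 360 + 0.5)
  ifelse(out <= -180, out + 360, out)
}

prepare_normalized <- function(profile, min_n) {
  profile <- as_profile(profile)
  if (nrow(profile) < min_n) {
    abort(sprintf("profile has N = %d samples; at least %d are required",
      nrow(profile), min_n), class = "crescentr_error")
  }
  if (!is_normalized(profile)) profile <- normalize_profile(profile)
  profile
}

#' Polarization coefficient of a cortical intensity profile
#'
#' Measures how strongly a cortical signal is concentrated in a single
#' crescent. With mean-normalized intensities \eqn{I_k} at angles
#' \eqn{\theta_k = 2\pi k/N}, the first-harmonic components are
#' \deqn{a = \frac{1}{N}\sum_{k=1}^{N} I_k \cos\theta_k, \quad
#'       b = \frac{1}{N}\sum_{k=1}^{N} I_k \sin\theta_k,}
#' and the polarization coefficient is \eqn{P = \sqrt{a^2 + b^2}}. A
#' uniform cortical distribution gives P = 0; a single-sample concentration
#' gives P = 1. The magnitude is invariant to cyclic shifts of the profile
#' and to intensity rescaling; raw profiles are normalized internally.
#'
#' No noise-bias correction is applied: like any resultant-length
#' estimator, P is positively biased on noisy near-uniform profiles (see
#' the methods vignette for the characterization).
#'
#' @param profile A [intensity_profile()] or numeric vector, N >= 3.
#' @return A `polarity_score` object with fields `P`, `a`, `b`,
#'   `phase_deg` (crescent center, degrees in (-180, 180]) and `N`.
#'   [tidy()] and [glance()] return it as a one-row tibble.
#' @examples
#' theta <- 2 * pi * (1:36) / 36
#' polarization_coefficient(1 + cos(theta)) # P = 0.5, phase 0
#' polarization_coefficient(rep(7, 36)) # uniform: P = 0
#' @seealso [nematic_order()] for bipolar (axis-like) patterns.
#' @export
polarization_coefficient <- function(profile) {
  profile <- prepare_normalized(profile, min_n = 3)
  h <- harmonic_components(profile$grey_value, harmonic = 1)
  p <- sqrt(h[["cos"]]^2 + h[["sin"]]^2)
  structure(
    list(
      P = p, a = h[["cos"]], b = h[["sin"]],
      phase_deg = wrap_degrees(atan2(h[["sin"]], h[["cos"]]) * 180 / pi),
      N = nrow(profile)
    ),
    class = "polarity_score"
  )
}

#' Nematic order parameter of a cortical intensity profile
#'
#' Measures bipolar (180-degree periodic, axis-like) cortical patterns such
#' as junctional planar-cell-polarity receptors, using the second circular
#' harmonic of the mean-normalized intensities:
#' \deqn{c = \frac{1}{N}\sum_{k=1}^{N} I_k \cos 2\theta_k, \quad
#'       d = \frac{1}{N}\sum_{k=1}^{N} I_k \sin 2\theta_k, \quad
#'       S = \sqrt{c^2 + d^2}.}
#' A uniform distribution gives S = 0, and by harmonic orthogonality a pure
#' unipolar crescent also gives S = 0. The reported `axis_deg` is the
#' orientation of the bipolar axis, defined modulo 180 degrees.
#'
#' @param profile A [intensity_profile()] or numeric vector.
#' @param min_n Minimum sample count, default 8: at very small N the second
#'   harmonic is poorly resolved against the first, so the default refuses
#'   profiles below 8 samples. Lower it explicitly (>= 3) at your own risk.
#' @return A `nematic_score` object with fields `S`, `c`, `d`, `axis_deg`
#'   (degrees in (-90, 90]) and `N`.
#' @examples
#' theta <- 2 * pi * (1:36) / 36
#' nematic_order(1 + cos(2 * theta)) # S = 0.5
#' nematic_order(1 + cos(theta)) # pure crescent: S = 0
#' @export
nematic_order <- function(profile, min_n = 8) {
  stopifnot(min_n >= 3)
  profile <- prepare_normalized(profile, min_n = min_n)
  h <- harmonic_components(profile$grey_value, harmonic = 2)
  s <- sqrt(h[["cos"]]^2 + h[["sin"]]^2)
  axis <- wrap_degrees(atan2(h[["sin"]], h[["cos"]]) * 180 / pi) / 2
  if (axis <= -90) axis <- axis + 180
  structure(
    list(S = s, c = h[["cos"]], d = h[["sin"]], axis_deg = axis,
         N = nrow(profile)),
    class = "nematic_score"
  )
}

#' @export
print.polarity_score <- function(x, ...) {
  cat(sprintf("Polarization coefficient P = %.4f (phase %.2f deg, N = %d)\n",
    x$P, x$phase_deg, x$N))
  invisible(x)
}

#' @export
print.nematic_score <- function(x, ...) {
  cat(sprintf("Nematic order parameter S = %.4f (axis %.2f deg, N = %d)\n",
    x$S, x$axis_deg, x$N))
  invisible(x)
}

#' @export
tidy.polarity_score <- function(x, ...) {
  tibble(N = x$N, P = x$P, a = x$a, b = x$b, phase_deg = x$phase_deg)
}

#' @export
glance.polarity_score <- function(x, ...) tidy(x)

#' @export
tidy.nematic_score <- function(x, ...) {
  tibble(N = x$N, S = x$S, c = x$c, d = x$d, axis_deg = x$axis_deg)
}

#' @export
glance.nematic_score <- function(x, ...) tidy(x)

#' Normalized cortical intensity
#'
#' Cortical enrichment of a signal relative to the cytoplasm: the mean of
#' the raw cortical grey values divided by the mean grey value of a
#' cytoplasmic sample region. Values near 1 mean no cortical enrichment.
#'
#' @param cortex_profile Raw (not mean-normalized) [intensity_profile()] or
#'   numeric vector of cortical grey values.
#' @param cytoplasm_mean Positive mean grey value of a cytoplasmic sample
#'   region in the same cell.
#' @return Dimensionless ratio (scalar).
#' @examples
#' normalized_cortical_intensity(c(18, 22, 20), cytoplasm_mean = 10)
#' @export
normalized_cortical_intensity <- function(cortex_profile, cytoplasm_mean) {
  stopifnot(is.numeric(cytoplasm_mean), length(cytoplasm_mean) == 1)
  if (!is.finite(cytoplasm_mean) || cytoplasm_mean <= 0) {
    abort("`cytoplasm_mean` must be a positive grey value",
      class = "crescentr_error")
  }
  mean(profile_values(cortex_profile)) / cytoplasm_mean
}

#' Crescent enrichment ratio
#'
#' Enrichment of a signal along a crescent relative to the remaining
#' membrane: the mean raw grey value over the crescent samples divided by
#' the mean over the complement of the profile. The crescent extent is
#' caller-provided (e.g. traced from a co-stained marker), mirroring manual
#' region selection; no automatic crescent detection is attempted.
#'
#' @param profile Raw [intensity_profile()] or numeric vector.
#' @param crescent_samples Integer indices (subset of 1..N) of the samples
#'   lying on the crescent; must be a nonempty proper subset.
#' @return Dimensionless ratio (scalar).
#' @examples
#' crescent_enrichment_ratio(c(12, 12, 4, 4, 4, 4), crescent_samples = 1:2)
#' @export
crescent_enrichment_ratio <- function(profile, crescent_samples) {
  values <- profile_values(profile)
  n <- length(values)
  idx <- unique(as.integer(crescent_samples))
  if (length(idx) == 0 || any(idx < 1 | idx > n)) {
    abort("`crescent_samples` must be a nonempty subset of 1..N",
      class = "crescentr_error")
  }
  if (length(idx) == n) {
    abort("`crescent_samples` covers the whole outline; no remaining membrane",
      class = "crescentr_error")
  }
  rest <- mean(values[-idx])
  if (rest <= 0) {
    abort("remaining-membrane mean is zero; enrichment ratio undefined",
      class = "crescentr_degenerate")
  }
  mean(values[idx]) / rest
}

#' Score a batch of profiles
#'
#' Computes the polarization coefficient P and the nematic order parameter
#' S for every cell in a long-format profile table, the shape written by
#' [write_profiles_csv()] and produced by the simulators.
#'
#' @param profiles A data frame with columns `cell_id`, `k`, `grey_value`
#'   (and optionally `arc_position`).
#' @param min_n Minimum samples per cell; cells below it are scored as NA
#'   with a warning.
#' @return A tibble with one row per cell: `cell_id`, `N`, `P`, `a`, `b`,
#'   `phase_deg`, `S`, `c`, `d`, `axis_deg`.
#' @examples
#' prof <- simulate_profile(36, kappa = 4, seed = 1)
#' score_profiles(dplyr::mutate(prof, cell_id = "cell1"))
#' @export
score_profiles <- function(profiles, min_n = 8) {
  stopifnot(is.data.frame(profiles))
  required <- c("cell_id", "grey_value")
  missing <- setdiff(required, names(profiles))
  if (length(missing) > 0) {
    abort(paste0("profiles table lacks column(s): ",
      paste(missing, collapse = ", ")), class = "crescentr_error")
  }
  profiles |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < min_n || mean(df$grey_value) <= 0) {
        warn(sprintf("cell '%s' skipped: degenerate or too short profile",
          as.character(key$cell_id)))
        return(tibble(N = nrow(df), P = NA_real_, a = NA_real_, b = NA_real_,
          phase_deg = NA_real_, S = NA_real_, c = NA_real_, d = NA_real_,
          axis_deg = NA_real_))
      }
      prof <- intensity_profile(df$grey_value)
      dplyr::bind_cols(
        tidy(polarization_coefficient(prof)),
        tidy(nematic_order(prof, min_n = min_n))[-1]
      )
    }) |>
    dplyr::ungroup()
}
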