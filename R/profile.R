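#' Cortical intensity profiles
#'
#' An intensity profile is the ordered set of grey values sampled at `N`
#' equally spaced positions along a closed cortical outline. It is the
#' common currency of the package: the profile extractor produces one per
#' cell and the circular harmonic statistics ([polarization_coefficient()],
#' [nematic_order()]) consume it. Profiles are stored as tibbles with
#' columns `k` (sample index, 1..N), `arc_position` (cumulative arc length,
#' px unless a pixel scale was applied) and `grey_value`, plus a
#' `normalized` attribute recording whether division by the mean has been
#' applied.
#'
#' @param grey_value Numeric vector of nonnegative grey values, length >= 3.
#' @param arc_position Optional numeric vector of cumulative arc-length
#'   positions, same length as `grey_value`. Defaults to the sample index.
#' @param normalized Logical; has the profile been divided by its mean?
#'
#' @return A tibble of class `crescent_profile` with columns `k`,
#'   `arc_position`, `grey_value`.
#' @examples
#' p <- intensity_profile(c(1, 2, 3, 2, 1, 0.5))
#' polarization_coefficient(p)
#' @export
intensity_profile <- function(grey_value, arc_position = NULL,
                              normalized = FALSE) {
  grey_value <- as.numeric(grey_value)
  n <- length(grey_value)
  if (n < 3) {
    abort("an intensity profile needs at least 3 samples", class = "crescentr_error")
  }
  if (anyNA(grey_value)) {
    abort("grey values must not contain NA", class = "crescentr_error")
  }
  if (any(grey_value < 0)) {
    abort("grey values must be nonnegative", class = "crescentr_error")
  }
  if (is.null(arc_position)) arc_position <- seq_len(n) - 1
  stopifnot(length(arc_position) == n)
  out <- tibble(
    k = seq_len(n),
    arc_position = as.numeric(arc_position),
    grey_value = grey_value
  )
  new_crescent_profile(out, normalized = normalized)
}

new_crescent_profile <- function(df, normalized = FALSE) {
  structure(df,
    class = c("crescent_profile", class(tibble())),
    normalized = normalized
  )
}

#' @export
print.crescent_profile <- function(x, ...) {
  cat(sprintf(
    "<cortical intensity profile: N = %d, %s>\n", nrow(x),
    if (is_normalized(x)) "mean-normalized" else "raw grey values"
  ))
  NextMethod()
}

#' Test or assert the profile contract
#'
#' @param x Object to test.
#' @return `is_profile()` returns a logical scalar; `is_normalized()`
#'   reports the normalization flag.
#' @export
is_profile <- function(x) inherits(x, "crescent_profile")

#' @rdname is_profile
#' @export
is_normalized <- function(x) isTRUE(attr(x, "normalized"))

# Accept a crescent_profile, a plain numeric vector, or a data frame with a
# grey_value column; used by every consumer so the tidy API stays permissive.
as_profile <- function(x, arg = "profile") {
  if (is_profile(x)) return(x)
  if (is.numeric(x)) return(intensity_profile(x))
  if (is.data.frame(x) && "grey_value" %in% names(x)) {
    return(intensity_profile(x$grey_value,
      arc_position = if ("arc_position" %in% names(x)) x$arc_position
    ))
  }
  abort(sprintf("`%s` must be an intensity profile or numeric vector", arg),
    class = "crescentr_error")
}

profile_values <- function(x) as_profile(x)$grey_value

#' Background-correct a profile
#'
#' Subtracts a scalar background estimate from every grey value, clipping
#' at zero; arc positions are unchanged. Correction is applied before
#' mean-normalization throughout the package (pass `background = 0` for
#' the uncorrected variant).
#'
#' @param profile A [intensity_profile()] (or numeric vector).
#' @param background Nonnegative scalar grey-value estimate, e.g. from
#'   [estimate_background()].
#' @return A raw (non-normalized) `crescent_profile`.
#' @examples
#' background_correct(intensity_profile(c(10, 20, 30)), 10)$grey_value
#' @export
background_correct <- function(profile, background) {
  profile <- as_profile(profile)
  stopifnot(is.numeric(background), length(background) == 1)
  if (background < 0) {
    abort("`background` must be nonnegative", class = "crescentr_error")
  }
  out <- profile
  out$grey_value <- pmax(out$grey_value - background, 0)
  new_crescent_profile(out, normalized = FALSE)
}

#' Mean-normalize a profile
#'
#' Divides every grey value by the profile mean, the normalization
#' I_k = (grey value k) / (mean of grey values) that both harmonic
#' statistics assume. Idempotent; the output mean is 1.
#'
#' @param profile A [intensity_profile()] (or numeric vector).
#' @return A `crescent_profile` with the `normalized` attribute set.
#' @examples
#' normalize_profile(intensity_profile(c(2, 2, 2, 2)))$grey_value
#' @export
normalize_profile <- function(profile) {
  profile <- as_profile(profile)
  m <- mean(profile$grey_value)
  if (m <= 0) {
    abort("degenerate profile: all grey values are zero, polarity undefined",
      class = "crescentr_degenerate")
  }
  out <- profile
  out$grey_value <- out$grey_value / m
  new_crescent_profile(out, normalized = TRUE)
}

#' @describeIn intensity_profile line plot of grey value over arc position.
#' @param object,... A `crescent_profile`; further arguments are ignored.
#' @export
autoplot.crescent_profile <- function(object, ...) {
  ylab <- if (is_normalized(object)) "normalized intensity I[k]" else "grey value"
  ggplot2::ggplot(object, ggplot2::aes(.data$arc_position, .data$grey_value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::labs(x = "arc position along cortex", y = ylab) +
    ggplot2::theme_minimal()
}
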