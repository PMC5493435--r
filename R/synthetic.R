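# Synthetic fluorescence data with the statistical structure the analysis
# assumes: elliptical cells with a cortical ring carrying a von Mises shaped
# crescent, division-event populations with wrapped-normal angles and
# beta-distributed daughter asymmetry, and multinomial defect tables.

#' Closed-form crescent intensity law
#'
#' Expected cortical intensity at angular position `theta` for a unimodal
#' crescent: `baseline + amplitude * exp(kappa * (cos(theta - mu) - 1))`,
#' a von Mises shaped bump normalized to peak `amplitude` at the crescent
#' center `mu`. `kappa = 0` is the uniform limit (`baseline + amplitude`
#' everywhere); larger `kappa` concentrates the crescent.
#'
#' @param theta Angular positions in radians, measured clockwise (in the
#'   y-down image frame) from the anterior-posterior axis.
#' @param center_angle Crescent center in degrees, same convention.
#' @param kappa Angular concentration >= 0 (dimensionless).
#' @param amplitude Peak crescent intensity above baseline (grey values).
#' @param baseline Cortical baseline intensity (grey values).
#' @return Numeric vector of expected grey values.
#' @export
crescent_intensity <- function(theta, center_angle = 0, kappa = 2,
                               amplitude = 1, baseline = 0) {
  stopifnot(kappa >= 0, amplitude >= 0, baseline >= 0)
  mu <- center_angle * pi / 180
  baseline + amplitude * exp(kappa * (cos(theta - mu) - 1))
}

#' Parameterize a synthetic cell image
#'
#' Full parameterization of one generated cell: an axis-aligned elliptical
#' cell whose cortex is a ring of width `ring_width` just inside the
#' ellipse boundary, carrying a [crescent_intensity()] modulation over a
#' cytoplasmic interior and a flat background, plus additive Gaussian noise
#' clipped at zero.
#'
#' @param image_size Image height and width in pixels, `c(h, w)`.
#' @param center Subpixel cell center `c(x, y)` (0-based, y down); defaults
#'   to the image center.
#' @param semi_axes Ellipse semi-axes `c(a, b)` in px (a along x, b along
#'   y); both must be at least `2 * ring_width`.
#' @param ring_width Cortical ring width in px.
#' @param crescent_center_angle Crescent center, degrees in (-180, 180].
#' @param crescent_kappa Angular concentration >= 0; 0 gives a uniform ring.
#' @param crescent_amplitude Peak crescent grey value above the baseline.
#' @param cortex_baseline,cytoplasm_level,background_level Grey values of
#'   the unmodulated ring, the interior and the exterior.
#' @param noise_sd Additive Gaussian noise SD (grey values); images are
#'   clipped at 0 after noise.
#' @param seed Integer seed; identical specs and seeds give identical images.
#' @return A validated list of class `cell_spec`.
#' @examples
#' spec <- cell_spec(crescent_kappa = 4, seed = 7)
#' sim <- simulate_cell_image(spec)
#' dim(sim$image)
#' @export
cell_spec <- function(image_size = c(128, 128), center = NULL,
                      semi_axes = c(34, 26), ring_width = 4,
                      crescent_center_angle = 0, crescent_kappa = 2,
                      crescent_amplitude = 200, cortex_baseline = 120,
                      cytoplasm_level = 60, background_level = 20,
                      noise_sd = 0, seed = NULL) {
  if (is.null(center)) center <- c(image_size[2], image_size[1]) / 2 - 0.5
  spec <- structure(
    list(
      image_size = as.integer(image_size), center = as.numeric(center),
      semi_axes = as.numeric(semi_axes), ring_width = as.numeric(ring_width),
      crescent_center_angle = as.numeric(crescent_center_angle),
      crescent_kappa = as.numeric(crescent_kappa),
      crescent_amplitude = as.numeric(crescent_amplitude),
      cortex_baseline = as.numeric(cortex_baseline),
      cytoplasm_level = as.numeric(cytoplasm_level),
      background_level = as.numeric(background_level),
      noise_sd = as.numeric(noise_sd),
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "cell_spec"
  )
  validate_cell_spec(spec)
}

validate_cell_spec <- function(spec) {
  with(spec, {
    if (length(image_size) != 2 || any(image_size < 8)) {
      abort("image_size must be c(height, width), both >= 8",
        class = "crescentr_error")
    }
    if (ring_width <= 0 || any(semi_axes < 2 * ring_width)) {
      abort("both semi-axes must be at least twice the ring width",
        class = "crescentr_error")
    }
    if (crescent_kappa < 0 || crescent_amplitude < 0 || cortex_baseline < 0 ||
        cytoplasm_level < 0 || background_level < 0 || noise_sd < 0) {
      abort("intensity parameters, kappa and noise_sd must be nonnegative",
        class = "crescentr_error")
    }
    if (crescent_center_angle <= -180 || crescent_center_angle > 180) {
      abort("crescent_center_angle must lie in (-180, 180]",
        class = "crescentr_error")
    }
    # the full ring plus one px of anti-aliased edge must fit in the frame
    lo <- center - semi_axes - 1
    hi <- center + semi_axes + 1
    if (any(lo < 0) || hi[1] > image_size[2] - 1 || hi[2] > image_size[1] - 1) {
      abort("degenerate geometry: cortical ring extends outside the image",
        class = "crescentr_geometry")
    }
  })
  spec
}

# Signed distance (px, first order) from each pixel center to the ellipse
# boundary; negative inside. Rows are y, columns x, both 0-based.
ellipse_signed_distance <- function(image_size, center, semi_axes) {
  h <- image_size[1]; w <- image_size[2]
  x <- matrix(rep(0:(w - 1), each = h), nrow = h)
  y <- matrix(rep(0:(h - 1), times = w), nrow = h)
  dx <- x - center[1]
  dy <- y - center[2]
  rho <- sqrt((dx / semi_axes[1])^2 + (dy / semi_axes[2])^2)
  grad <- sqrt((dx / semi_axes[1]^2)^2 + (dy / semi_axes[2]^2)^2)
  d <- ifelse(grad > 0, rho * (rho - 1) / grad, -min(semi_axes))
  list(d = d, theta = atan2(dy, dx))
}

#' Render a synthetic cell image
#'
#' Rasterizes the cell described by a [cell_spec()]: exterior pixels at
#' `background_level`, interior at `cytoplasm_level`, and the cortical ring
#' (the band within `ring_width` px inside the ellipse boundary) at the
#' [crescent_intensity()] law. Region edges are blended linearly over one
#' pixel (signed-distance anti-aliasing) to avoid aliasing artifacts that
#' would bias the harmonic statistics at high concentration. Gaussian noise
#' of SD `noise_sd` is then added everywhere and the image clipped at 0.
#'
#' @param spec A [cell_spec()].
#' @return A list of class `crescent_image`: `image` (numeric matrix,
#'   rows = y), `mask` (logical matrix, TRUE inside the cell including the
#'   ring) and `spec`.
#' @export
simulate_cell_image <- function(spec) {
  spec <- validate_cell_spec(spec)
  geo <- ellipse_signed_distance(spec$image_size, spec$center, spec$semi_axes)
  ring_value <- crescent_intensity(
    geo$theta, spec$crescent_center_angle, spec$crescent_kappa,
    spec$crescent_amplitude, spec$cortex_baseline
  )
  # coverage fractions: w_out = inside ellipse, w_in = inside inner ellipse
  w_out <- pmin(pmax(0.5 - geo$d, 0), 1)
  w_in <- pmin(pmax(0.5 - (geo$d + spec$ring_width), 0), 1)
  img <- spec$background_level * (1 - w_out) +
    ring_value * (w_out - w_in) +
    spec$cytoplasm_level * w_in
  if (spec$noise_sd > 0) {
    img <- img + with_sim_seed(spec$seed,
      rnorm(length(img), sd = spec$noise_sd))
    img <- pmax(img, 0)
  }
  dim(img) <- dim(geo$d)
  structure(
    list(image = img, mask = geo$d <= 0, spec = spec),
    class = "crescent_image"
  )
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_sim_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

#' Simulate a cortical intensity profile directly
#'
#' Draws a profile of `n_samples` grey values from the [crescent_intensity()]
#' law at angles `theta_k = 2*pi*k/N` plus Gaussian noise clipped at zero,
#' bypassing image rendering and extraction. Useful for testing the harmonic
#' statistics at scale.
#'
#' @param n_samples Number of samples N >= 3.
#' @param kappa,amplitude,baseline,center_angle Crescent law parameters,
#'   see [crescent_intensity()].
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed for reproducibility.
#' @return A raw [intensity_profile()] with `arc_position` the angle
#'   theta_k in radians.
#' @examples
#' polarization_coefficient(simulate_profile(100, kappa = 4))
#' @export
simulate_profile <- function(n_samples, kappa = 2, amplitude = 1,
                             baseline = 0.5, noise_sd = 0,
                             center_angle = 0, seed = NULL) {
  if (n_samples < 3) {
    abort("n_samples must be at least 3 (harmonics undefined below that)",
      class = "crescentr_error")
  }
  stopifnot(noise_sd >= 0)
  theta <- 2 * pi * seq_len(n_samples) / n_samples
  values <- crescent_intensity(theta, center_angle, kappa, amplitude, baseline)
  if (noise_sd > 0) {
    values <- pmax(values + with_sim_seed(seed,
      rnorm(n_samples, sd = noise_sd)), 0)
  }
  intensity_profile(values, arc_position = theta)
}

# wrap degrees into (-180, 180]
wrap_angle_deg <- function(deg) wrap_degrees(deg)

#' Parameterize a synthetic division population
#'
#' Describes a population of asymmetric division events: signed division
#' angles are wrapped-normal around `angle_mean` with dispersion
#' `angle_sd`, the daughter-intensity segregation ratio (min/max) is
#' Beta(`segregation_shape[1]`, `segregation_shape[2]`) distributed with
#' closed-form mean `s1/(s1+s2)`, and each cell optionally carries a
#' cortical profile with crescent concentration `polarization_kappa`
#' centered on its division angle.
#'
#' @param n_cells Number of division events, >= 1.
#' @param angle_mean Mean division angle in degrees (0 = along the
#'   anterior-posterior axis).
#' @param angle_sd Wrapped-normal angular dispersion in degrees, >= 0.
#' @param segregation_shape Two positive Beta shape parameters for the
#'   min/max daughter intensity ratio. The default `c(2, 8)` (mean ratio
#'   0.2) mimics strongly asymmetric segregation.
#' @param polarization_kappa Crescent concentration of each cell's cortical
#'   profile; `NULL` skips profile generation.
#' @param seed Integer seed.
#' @return A validated list of class `division_spec`.
#' @export
division_spec <- function(n_cells = 60, angle_mean = 0, angle_sd = 35,
                          segregation_shape = c(2, 8),
                          polarization_kappa = 4, seed = NULL) {
  spec <- structure(
    list(
      n_cells = as.integer(n_cells), angle_mean = as.numeric(angle_mean),
      angle_sd = as.numeric(angle_sd),
      segregation_shape = as.numeric(segregation_shape),
      polarization_kappa = if (!is.null(polarization_kappa))
        as.numeric(polarization_kappa),
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "division_spec"
  )
  with(spec, {
    if (n_cells < 1) abort("n_cells must be >= 1", class = "crescentr_error")
    if (angle_sd < 0) abort("angle_sd must be >= 0", class = "crescentr_error")
    if (length(segregation_shape) != 2 || any(segregation_shape <= 0)) {
      abort("segregation_shape must be two positive Beta parameters",
        class = "crescentr_error")
    }
  })
  spec
}

#' Simulate a population of asymmetric division events
#'
#' Draws `n_cells` division records per a [division_spec()]: signed
#' division angles (wrapped normal, mapped into (-180, 180]), daughter
#' intensity pairs whose min/max ratio follows the Beta law of the spec,
#' the daughter-axis displacement vector realizing each angle, and the
#' anterior-posterior reference axis. With `polarization_kappa` set, each
#' record carries a cortical profile (list column) whose crescent is
#' centered on the division angle.
#'
#' @param spec A [division_spec()].
#' @param profile_samples Samples per cortical profile (default 100).
#' @param profile_noise_sd Gaussian noise SD on the profiles, as a grey
#'   value on the default amplitude-1, baseline-0.5 law.
#' @return A tibble with one row per division: `cell_id`, `intensity_a`,
#'   `intensity_b`, `axis_dx`, `axis_dy`, `ap_dx`, `ap_dy`, `angle_deg`
#'   (the realized angle) and, if requested, a `profile` list column.
#' @examples
#' pop <- simulate_divisions(division_spec(n_cells = 5, seed = 1))
#' summarize_divisions(pop)
#' @export
simulate_divisions <- function(spec, profile_samples = 100,
                               profile_noise_sd = 0.1) {
  stopifnot(inherits(spec, "division_spec"))
  with_sim_seed(spec$seed, {
    n <- spec$n_cells
    angles <- wrap_angle_deg(spec$angle_mean + rnorm(n, sd = spec$angle_sd))
    ratio <- rbeta(n, spec$segregation_shape[1], spec$segregation_shape[2])
    ratio <- pmin(pmax(ratio, 1e-6), 1)
    big <- rep(1000, n)
    small <- ratio * big
    # which daughter inherits more is itself random
    flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
    rad <- angles * pi / 180
    out <- tibble(
      cell_id = sprintf("cell%03d", seq_len(n)),
      intensity_a = ifelse(flip, big, small),
      intensity_b = ifelse(flip, small, big),
      axis_dx = cos(rad), axis_dy = sin(rad),
      ap_dx = 1, ap_dy = 0,
      angle_deg = angles
    )
    if (!is.null(spec$polarization_kappa)) {
      out$profile <- purrr::map(angles, function(mu) {
        simulate_profile(profile_samples, kappa = spec$polarization_kappa,
          amplitude = 1, baseline = 0.5, noise_sd = profile_noise_sd,
          center_angle = mu)
      })
    }
    out
  })
}

#' Simulate a defect-category contingency table
#'
#' Draws one multinomial sample per genotype and assembles the counts
#' row-wise into an r x c contingency table, emulating per-wing or per-fly
#' bristle-defect scoring (e.g. categories none / duplicated / missing /
#' split counted over 100 wings per genotype).
#'
#' @param probs Matrix (rows = groups) or list of per-group probability
#'   vectors; each row must sum to 1.
#' @param n Integer vector of per-group totals (recycled if scalar).
#' @param labels Optional row (group) names.
#' @param categories Optional column (defect category) names.
#' @param seed Integer seed.
#' @return An integer matrix with group rownames and category colnames.
#' @examples
#' simulate_defect_table(rbind(c(0.9, 0.1), c(0.5, 0.5)), n = 100, seed = 1)
#' @export
simulate_defect_table <- function(probs, n, labels = NULL, categories = NULL,
                                  seed = NULL) {
  if (is.list(probs)) probs <- do.call(rbind, probs)
  probs <- as.matrix(probs)
  if (any(probs < 0)) {
    abort("probabilities must be nonnegative", class = "crescentr_error")
  }
  if (any(abs(rowSums(probs) - 1) > 1e-8)) {
    abort("each group's probability vector must sum to 1",
      class = "crescentr_error")
  }
  n <- as.integer(rep(n, length.out = nrow(probs)))
  if (any(n < 0)) abort("counts must be nonnegative", class = "crescentr_error")
  counts <- with_sim_seed(seed, {
    t(vapply(seq_len(nrow(probs)), function(i) {
      if (n[i] == 0) return(integer(ncol(probs)))
      as.integer(rmultinom(1, n[i], probs[i, ]))
    }, integer(ncol(probs))))
  })
  rownames(counts) <- labels %||% rownames(probs) %||%
    paste0("group", seq_len(nrow(counts)))
  colnames(counts) <- categories %||% colnames(probs) %||%
    paste0("category", seq_len(ncol(counts)))
  counts
}
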