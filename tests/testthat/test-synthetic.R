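# Synthetic-data generators: determinism, the closed-form crescent law on
# the rendered ring, and the statistical structure of the division and
# contingency simulators.

test_that("identical specs and seeds give identical outputs", {
  spec <- cell_spec(crescent_kappa = 3, noise_sd = 15, seed = 11)
  expect_identical(simulate_cell_image(spec)$image,
    simulate_cell_image(spec)$image)
  expect_identical(
    simulate_profile(50, kappa = 2, noise_sd = 0.2, seed = 5)$grey_value,
    simulate_profile(50, kappa = 2, noise_sd = 0.2, seed = 5)$grey_value)
  dspec <- division_spec(n_cells = 12, seed = 3)
  expect_identical(simulate_divisions(dspec)$angle_deg,
    simulate_divisions(dspec)$angle_deg)
  expect_identical(
    simulate_defect_table(rbind(c(0.7, 0.3), c(0.4, 0.6)), 50, seed = 9),
    simulate_defect_table(rbind(c(0.7, 0.3), c(0.4, 0.6)), 50, seed = 9))
})

# pixels on the cortical ring centerline of a noiseless rendered cell,
# with their angular positions
ring_centerline <- function(sim) {
  spec <- sim$spec
  h <- spec$image_size[1]; w <- spec$image_size[2]
  x <- matrix(rep(0:(w - 1), each = h), nrow = h) - spec$center[1]
  y <- matrix(rep(0:(h - 1), times = w), nrow = h) - spec$center[2]
  rho <- sqrt((x / spec$semi_axes[1])^2 + (y / spec$semi_axes[2])^2)
  grad <- sqrt((x / spec$semi_axes[1]^2)^2 + (y / spec$semi_axes[2]^2)^2)
  d <- rho * (rho - 1) / pmax(grad, 1e-9)
  sel <- abs(d + spec$ring_width / 2) < 0.5
  list(value = sim$image[sel], theta = atan2(y, x)[sel])
}

test_that("the rendered ring follows the crescent law on its centerline", {
  spec <- cell_spec(crescent_kappa = 4, crescent_center_angle = 30,
    noise_sd = 0)
  sim <- simulate_cell_image(spec)
  ring <- ring_centerline(sim)
  expected <- crescent_intensity(ring$theta, 30, 4, spec$crescent_amplitude,
    spec$cortex_baseline)
  expect_lt(max(abs(ring$value - expected) / expected), 0.02)
})

test_that("kappa = 0 yields an angularly uniform ring; amplitude 0 the baseline", {
  flat <- simulate_cell_image(cell_spec(crescent_kappa = 0, noise_sd = 0))
  ring <- ring_centerline(flat)
  expect_equal(ring$value,
    rep(flat$spec$cortex_baseline + flat$spec$crescent_amplitude,
      length(ring$value)), tolerance = 1e-6)
  bare <- simulate_cell_image(cell_spec(crescent_amplitude = 0, noise_sd = 0))
  expect_equal(ring_centerline(bare)$value,
    rep(bare$spec$cortex_baseline, length(ring_centerline(bare)$value)),
    tolerance = 1e-6)
})

test_that("ring intensity peaks at the crescent center and dips at the antipode", {
  spec <- cell_spec(crescent_kappa = 4, crescent_center_angle = 0,
    noise_sd = 0)
  sim <- simulate_cell_image(spec)
  ring <- ring_centerline(sim)
  at_center <- ring$value[abs(ring$theta) < 0.15]
  at_antipode <- ring$value[abs(abs(ring$theta) - pi) < 0.15]
  law_peak <- spec$cortex_baseline + spec$crescent_amplitude
  law_dip <- crescent_intensity(pi, 0, 4, spec$crescent_amplitude,
    spec$cortex_baseline)
  expect_equal(mean(at_center), law_peak, tolerance = 0.02)
  expect_equal(mean(at_antipode), law_dip, tolerance = 0.02)
  expect_gt(min(at_center), max(at_antipode))
})

test_that("interior and exterior sit at cytoplasm and background levels", {
  spec <- cell_spec(noise_sd = 0)
  sim <- simulate_cell_image(spec)
  center_px <- sim$image[round(spec$center[2]) + 1, round(spec$center[1]) + 1]
  expect_equal(center_px, spec$cytoplasm_level)
  expect_equal(sim$image[1, 1], spec$background_level)
  expect_true(sim$mask[round(spec$center[2]) + 1, round(spec$center[1]) + 1])
  expect_false(sim$mask[1, 1])
})

test_that("degenerate geometry and invalid specs are rejected", {
  expect_error(cell_spec(image_size = c(40, 40), semi_axes = c(30, 25)),
    class = "crescentr_geometry")
  expect_error(cell_spec(semi_axes = c(5, 5), ring_width = 4),
    class = "crescentr_error")
  expect_error(cell_spec(crescent_kappa = -1), class = "crescentr_error")
  expect_error(cell_spec(crescent_center_angle = 270),
    class = "crescentr_error")
})

test_that("noise is clipped at zero and grey values stay nonnegative", {
  spec <- cell_spec(background_level = 5, noise_sd = 50, seed = 2)
  expect_true(all(simulate_cell_image(spec)$image >= 0))
})

test_that("simulated profiles follow the law and its uniform limit", {
  flat <- simulate_profile(36, kappa = 0, amplitude = 1, baseline = 1)
  expect_equal(flat$grey_value, rep(2, 36))
  peaked <- simulate_profile(36, kappa = 2, amplitude = 1, baseline = 0.5,
    center_angle = 40)
  th <- 2 * pi * (1:36) / 36
  expect_equal(peaked$grey_value, crescent_intensity(th, 40, 2, 1, 0.5))
  # strictly unimodal around the center sample
  expect_equal(which.max(peaked$grey_value), 4) # theta_4 = 40 deg
  expect_error(simulate_profile(2), class = "crescentr_error")
})

test_that("division angles honor angle_sd = 0 and the wrapped-normal spread", {
  frozen <- simulate_divisions(division_spec(n_cells = 20, angle_mean = 25,
    angle_sd = 0, seed = 1))
  expect_equal(frozen$angle_deg, rep(25, 20))
  # sample SDs of 35 vs 68 deg populations separate cleanly at n = 60
  sds <- vapply(1:50, function(i) {
    tight <- simulate_divisions(division_spec(n_cells = 60, angle_sd = 35,
      polarization_kappa = NULL, seed = i))
    broad <- simulate_divisions(division_spec(n_cells = 60, angle_sd = 68,
      polarization_kappa = NULL, seed = i + 1000))
    c(sd(tight$angle_deg), sd(broad$angle_deg))
  }, numeric(2))
  expect_equal(mean(sds[1, ]), 35, tolerance = 0.2)
  expect_equal(mean(sds[2, ]), 68, tolerance = 0.2)
  expect_true(all(sds[2, ] > sds[1, ]))
})

test_that("segregation ratios follow the Beta law of the spec", {
  pop <- simulate_divisions(division_spec(n_cells = 1e4,
    segregation_shape = c(2, 8), polarization_kappa = NULL, seed = 4))
  ratios <- segregation_ratio(pop$intensity_a, pop$intensity_b)
  expect_equal(mean(ratios), 2 / (2 + 8), tolerance = 0.02)
  # near-perfect asymmetry: mass piles up at the low-ratio mode
  extreme <- simulate_divisions(division_spec(n_cells = 1e4,
    segregation_shape = c(0.5, 50), polarization_kappa = NULL, seed = 5))
  r2 <- segregation_ratio(extreme$intensity_a, extreme$intensity_b)
  expect_equal(mean(r2), 0.5 / 50.5, tolerance = 0.1)
  expect_gt(mean(r2 < 0.05), 0.9)
})

test_that("division records carry per-cell crescent profiles when asked", {
  pop <- simulate_divisions(division_spec(n_cells = 5, seed = 6),
    profile_samples = 36)
  expect_true("profile" %in% names(pop))
  expect_equal(nrow(pop$profile[[1]]), 36)
  bare <- simulate_divisions(division_spec(n_cells = 5,
    polarization_kappa = NULL, seed = 6))
  expect_false("profile" %in% names(bare))
})

test_that("contingency rows converge to their probability vectors", {
  probs <- rbind(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2))
  tab <- simulate_defect_table(probs, n = 1e5, seed = 8)
  frac <- sweep(tab, 1, rowSums(tab), "/")
  expect_lt(max(abs(frac - probs)), 0.01)
  expect_lt(max(abs(frac[1, ] - frac[2, ])), 0.01)
})

test_that("contingency edge cases: zero rows, validation", {
  tab <- simulate_defect_table(rbind(c(0.5, 0.5), c(0.5, 0.5)), n = c(0, 10),
    seed = 1)
  expect_equal(unname(tab[1, ]), c(0L, 0L))
  expect_equal(sum(tab[2, ]), 10L)
  expect_error(simulate_defect_table(rbind(c(0.5, 0.4), c(0.5, 0.5)), 10),
    class = "crescentr_error")
  expect_error(simulate_defect_table(rbind(c(-0.1, 1.1), c(0.5, 0.5)), 10),
    class = "crescentr_error")
})

test_that("a uniform cell passed through the full pipeline scores P below 0.05", {
  sim <- simulate_cell_image(cell_spec(crescent_kappa = 0, noise_sd = 0))
  prof <- extract_cortical_profile(sim$image, sim$mask, offset = -2)
  expect_lt(polarization_coefficient(prof)$P, 0.05)
})
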