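# Circular harmonic polarity statistics: closed-form anchors, oracle
# equivalence, and the invariances that make P and S comparable across
# cells regardless of where the outline trace happened to start.

theta_n <- function(n) 2 * pi * seq_len(n) / n

test_that("uniform profiles score zero on both harmonics", {
  expect_equal(polarization_coefficient(rep(7, 36))$P, 0, tolerance = 1e-12)
  expect_equal(nematic_order(rep(7, 36))$S, 0, tolerance = 1e-12)
  # any constant value, any N
  for (n in c(8, 19, 100)) {
    expect_lt(polarization_coefficient(rep(3.14, n))$P, 1e-12)
    expect_lt(nematic_order(rep(251, n))$S, 1e-12)
  }
})

test_that("pure-harmonic profiles give magnitude one half, at the right phase", {
  th <- theta_n(36)
  p <- polarization_coefficient(1 + cos(th))
  expect_equal(p$P, 0.5, tolerance = 1e-9)
  expect_equal(p$phase_deg, 0, tolerance = 1e-9)
  expect_equal(p$P, naive_harmonic_magnitude(1 + cos(th), 1), tolerance = 1e-12)

  s <- nematic_order(1 + cos(2 * th))
  expect_equal(s$S, 0.5, tolerance = 1e-9)
  expect_equal(s$S, naive_harmonic_magnitude(1 + cos(2 * th), 2),
    tolerance = 1e-12)

  # a shifted crescent moves the phase, not the magnitude
  p90 <- polarization_coefficient(1 + cos(th - pi / 2))
  expect_equal(p90$P, 0.5, tolerance = 1e-9)
  expect_equal(p90$phase_deg, 90, tolerance = 1e-6)
})

test_that("a single-sample delta reaches the P = 1 extreme", {
  values <- c(8, rep(0, 7)) # value N at k = 1
  p <- polarization_coefficient(values)
  expect_equal(p$P, 1, tolerance = 1e-12)
  expect_equal(p$a, cos(2 * pi / 8), tolerance = 1e-12)
  expect_equal(p$b, sin(2 * pi / 8), tolerance = 1e-12)
  expect_equal(p$phase_deg, 45, tolerance = 1e-9)
})

test_that("first and second harmonics are mutually blind (orthogonality)", {
  th <- theta_n(36)
  expect_lt(polarization_coefficient(1 + cos(2 * th))$P, 1e-12)
  expect_lt(nematic_order(1 + cos(th))$S, 1e-12)
})

test_that("P and S match the loop-summation oracle on random profiles", {
  set.seed(41)
  for (n in c(3, 5, 8, 11, 12)) {
    for (rep in 1:5) {
      values <- random_profile(n, c(5, 2)) + 0.1
      if (n >= 8) {
        expect_equal(nematic_order(values)$S,
          naive_harmonic_magnitude(values, 2), tolerance = 1e-12)
      }
      expect_equal(polarization_coefficient(values)$P,
        naive_harmonic_magnitude(values, 1), tolerance = 1e-12)
    }
  }
})

test_that("magnitudes are invariant to cyclic shifts and rescaling, and bounded", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(8:64, 1)
    values <- random_profile(n, c(3, 3)) + 1e-3
    p <- polarization_coefficient(values)
    s <- nematic_order(values)
    expect_true(p$P >= 0 && p$P <= 1)
    expect_true(s$S >= 0 && s$S <= 1)
    shift <- sample(n - 1, 1)
    shifted <- c(values[-(1:shift)], values[1:shift])
    expect_equal(polarization_coefficient(shifted)$P, p$P,
      tolerance = 1e-9)
    expect_equal(nematic_order(shifted)$S, s$S, tolerance = 1e-9)
    scale <- stats::runif(1, 0.01, 100)
    expect_equal(polarization_coefficient(values * scale)$P, p$P,
      tolerance = 1e-12)
    expect_equal(nematic_order(values * scale)$S, s$S, tolerance = 1e-12)
  }
})

test_that("cyclic shift moves the reported phase by the matching angle step", {
  th <- theta_n(36)
  values <- 1 + cos(th)
  shift <- 5 # values[k] <- old[k + 5]: crescent peak moves 5 steps earlier
  shifted <- c(values[-(1:shift)], values[1:shift])
  p <- polarization_coefficient(shifted)
  expect_equal(p$phase_deg, -shift * 10, tolerance = 1e-6)
})

test_that("raw and pre-normalized profiles score identically", {
  set.seed(7)
  values <- random_profile(24, c(10, 4)) + 1
  raw <- intensity_profile(values)
  norm <- normalize_profile(raw)
  expect_equal(polarization_coefficient(raw)$P,
    polarization_coefficient(norm)$P, tolerance = 1e-14)
})

test_that("degenerate and undersized profiles are rejected", {
  expect_error(polarization_coefficient(c(0, 0, 0)),
    class = "crescentr_degenerate")
  expect_error(intensity_profile(c(1, 2)), class = "crescentr_error")
  expect_error(nematic_order(rep(1, 5)), class = "crescentr_error") # N < 8
  expect_silent(nematic_order(rep(1, 5), min_n = 3))
})

test_that("normalized cortical intensity is the cortex/cytoplasm mean ratio", {
  expect_equal(normalized_cortical_intensity(c(18, 22, 20), 10), 2)
  expect_equal(normalized_cortical_intensity(rep(10, 5), 10), 1)
  expect_error(normalized_cortical_intensity(c(1, 2, 3), 0),
    class = "crescentr_error")
})

test_that("crescent enrichment ratio compares crescent to remaining membrane", {
  expect_equal(crescent_enrichment_ratio(c(12, 12, 4, 4, 4, 4), 1:2), 3)
  expect_equal(crescent_enrichment_ratio(rep(5, 10), 3:6), 1)
  expect_error(crescent_enrichment_ratio(rep(5, 10), integer(0)),
    class = "crescentr_error")
  expect_error(crescent_enrichment_ratio(rep(5, 10), 1:10),
    class = "crescentr_error")
  expect_error(crescent_enrichment_ratio(c(0, 0, 0, 5), 4),
    class = "crescentr_degenerate")
})

test_that("enrichment ratio grows with crescent concentration", {
  # baseline 0: the ratio compares crescent signal to remaining membrane
  # directly; a cortical baseline would dilute both sides of the ratio
  n <- 72
  within60 <- which(abs(wrap_degrees_for_test(360 * (1:n) / n)) <= 60)
  ratios <- vapply(c(1, 2, 4, 8), function(kappa) {
    prof <- simulate_profile(n, kappa = kappa, amplitude = 1, baseline = 0)
    crescent_enrichment_ratio(prof, within60)
  }, numeric(1))
  expect_true(all(ratios > 1))
  expect_true(all(diff(ratios) > 0))
})

test_that("batch scoring reproduces single-profile results per cell", {
  th <- theta_n(36)
  df <- dplyr::bind_rows(
    tibble::tibble(cell_id = "uniform", k = 1:36, grey_value = 5),
    tibble::tibble(cell_id = "cosine", k = 1:36, grey_value = 1 + cos(th))
  )
  res <- score_profiles(df)
  expect_equal(nrow(res), 2)
  expect_equal(res$P[res$cell_id == "uniform"], 0, tolerance = 1e-12)
  expect_equal(res$P[res$cell_id == "cosine"], 0.5, tolerance = 1e-9)
  expect_equal(res$S[res$cell_id == "cosine"], 0, tolerance = 1e-12)
  # degenerate cells are skipped with a warning, not an error
  bad <- tibble::tibble(cell_id = "zero", k = 1:10, grey_value = 0)
  expect_warning(res2 <- score_profiles(dplyr::bind_rows(df, bad)),
    "degenerate")
  expect_true(is.na(res2$P[res2$cell_id == "zero"]))
})
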