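---
title: "Quantifying cortical polarity crescents: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical polarity crescents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crescentr)
library(dplyr)
```

## The measurement problem

Asymmetrically dividing epithelial cells — the canonical example being the
*Drosophila* sensory organ precursor (SOP) on the pupal notum — concentrate
polarity scaffolds and cell-fate determinants into a cortical *crescent*
covering part of the cell perimeter before mitosis. Whether that crescent
forms, how concentrated it is, whether the division axis aligns with the
anterior–posterior (A–P) tissue axis, and whether the determinant ends up
in one daughter cell are the quantities that distinguish a wild-type
division from a mutant one. crescentr turns each of those questions into a
number computed from an intensity profile, a pair of daughter intensities,
or a pair of 2-D vectors, and provides the two group-comparison tests such
experiments conventionally use.

## The cortical intensity profile

Everything starts from the profile: `N` grey values sampled at equally
spaced arc-length positions along the closed cell outline. Sample `k` is
assigned the angle $\theta_k = 2\pi k/N$, and profiles are mean-normalized
before harmonic analysis,

$$ I_k = \frac{\text{grey value}_k}{\text{mean of grey values}} , $$

so that all harmonic statistics are invariant to illumination and exposure
scaling. Background correction (`background_correct()`, subtracting a
scalar estimate and clipping at zero) is applied *before* normalization,
uniformly for all downstream statistics; passing `background = 0` gives
the uncorrected variant. The background estimator itself
(`estimate_background()`) is the median of pixels outside a 3-px dilation
of the cell mask — a robust choice that ignores the blurred cortical rim.

`sample_profile()` replaces manual freehand tracing with a reproducible
geometric procedure: the outline is a subpixel marching-squares
iso-contour of the mask (`extract_outline()`), traversed clockwise in the
y-down image frame, and the profile starts at a fixed geometric phase
origin — the intersection of the outline with the ray from the cell
centroid along the A–P axis. The harmonic *magnitudes* below are provably
invariant to the start point and traversal direction (the package
property-tests this); fixing the origin only standardizes the reported
*phases*, so crescent positions are comparable across cells. Each sample
averages bilinear interpolation at `line_width` one-pixel-spaced offsets
normal to the outline (default 3 px; the single-pixel line of a typical
plot-profile tool is available with `line_width = 1`, but a wider band is
more robust to tracing error). The `offset` argument shifts the whole band
along the outline normal — useful to sit on the cortex centerline rather
than the segmentation boundary.

## Polarization coefficient P and nematic order parameter S

The polarization coefficient is the magnitude of the first circular
harmonic of the normalized profile:

$$ a = \frac{1}{N}\sum_{k=1}^{N} I_k \cos\theta_k,\qquad
   b = \frac{1}{N}\sum_{k=1}^{N} I_k \sin\theta_k,\qquad
   P = \sqrt{a^2+b^2} . $$

A uniform cortical distribution gives $P = 0$ exactly (for any $N \ge 3$,
$\sum_k \cos m\theta_k = 0$ whenever $N \nmid m$), and a single-sample
concentration gives $P = 1$; intermediate crescents fall in between, e.g.
$I = 1 + \cos\theta$ gives exactly $P = 1/2$. The nematic order parameter
$S$ is the same construction at the second harmonic ($2\theta_k$), and
detects bipolar, axis-like patterns (such as junctional planar-polarity
receptors on anterior *and* posterior cortex) that are invisible to $P$ —
and conversely, by orthogonality, a pure unipolar crescent has $S = 0$.

```{r anchors}
theta <- 2 * pi * (1:36) / 36
polarization_coefficient(rep(7, 36))$P    # uniform: 0
polarization_coefficient(1 + cos(theta))$P # pure crescent: 0.5
nematic_order(1 + cos(2 * theta))$S        # pure bipolar: 0.5
nematic_order(1 + cos(theta))$S            # crescent is invisible to S
```

Numerical choices: summation in double precision; the uniform null is zero
to rounding (~1e-16); equality assertions in the test-suite use 1e-9
relative tolerance. `nematic_order()` refuses $N < 8$ by default — at very
small $N$ the second harmonic is poorly resolved — while $P$ accepts
$N \ge 3$. The default profile length in extraction and simulation is
$N = 100$; since the statistics are discrete Fourier coefficients, results
are insensitive to $N$ once the profile resolves the crescent (tests run
$N$ from 8 to 100 without material change).

**Known bias, deliberately uncorrected.** $P$ and $S$ are resultant-length
estimators, hence positively biased on noisy near-uniform profiles (a
uniform profile plus noise has $E[P] \sim \sigma/\sqrt{N/2}$, not 0). The
package mirrors the plain definition rather than subtracting a bias term;
comparisons between groups measured at similar noise are unaffected.

## Division outcomes

`segregation_ratio()` is $\min(i_a, i_b)/\max(i_a, i_b)$ of the two
daughter intensities — 1 for equal inheritance, near 0 for clean
segregation — symmetric in the daughters and scale-free. Ties are defined
as exactly 1 regardless of labels.

`division_angle()` reports the signed angle from the A–P axis to the
daughter–daughter displacement, in $(-180, 180]$: rotations that appear
clockwise to the viewer (y-down image coordinates) are positive,
counterclockwise negative, computed via `atan2` of cross and dot products.
Negating the daughter axis (relabeling which daughter is anterior) shifts
the angle by 180°; daughter identity is caller-declared metadata, not
inferred. One angular convention is shared package-wide: the synthetic
generator, the profile phase origin, and the division angles all measure
from the A–P axis, clockwise-positive in the viewer frame.

`angle_dispersion()` reports the *arithmetic* sample SD (n − 1
denominator) of the signed angles as the primary statistic — the
convention under which a well-aligned population scores in the 30s of
degrees and a randomized one roughly doubles that — with the circular SD
($\sqrt{-2\ln \bar R}\cdot 180/\pi$) alongside as the wrap-safe companion.
The arithmetic SD of wrapped data is mildly biased downward once the
dispersion is large enough for mass to wrap at ±180°; at a true scale of
68° the bias is under 10% (characterized in the tests), and at 35° it is
negligible. The n − 1 denominator is a choice the data cannot distinguish
from n at sixty cells (<1% difference).

## Group comparisons

`mann_whitney()` computes U from midranks. For untied samples with
$n_a+n_b \le 16$ it enumerates all $\binom{n_a+n_b}{n_a}$ labelings and
reports the exact p, with the two-sided value defined as
$2\min(\text{tails})$ capped at 1 (commercial packages differ subtly in
this convention across versions; this one is fixed and documented).
Otherwise it uses the normal approximation with tie-corrected variance and
a 0.5 continuity correction. An all-tied comparison returns p = 1.

`freeman_halton()` extends Fisher's exact test to r×c defect-category
tables: under fixed margins each table has multivariate hypergeometric
probability, and p sums the probabilities of all tables no more probable
than the observed one. Probability ties are compared with a 1e-12 relative
tolerance so floating-point ordering noise cannot split exact ties; all
weights are computed with log-factorials (`lgamma`), safe at hundreds of
observations. The fixed-margin table space is enumerated by recursive
margin-constrained fill (the last row is forced, and the size bound counts
only free rows); above `monte_carlo_threshold` (default 5e6) a seeded
Monte Carlo over margin-preserving tables (Patefield's algorithm) applies
the same criterion with the observed table included in the estimate. A
table with an all-zero row or column is returned as degenerate with p = 1
rather than an error. On 2×2 tables the procedure reduces exactly to
two-sided Fisher; the tests verify this against the closed-form
hypergeometric on every 2×2 table with margins ≤ 12, and verify
conservativeness (null rejection ≤ 6% at α = 0.05) by simulation.

## The synthetic-data generator

No public microscopy accompanies this problem domain, so the package
ships a generator whose outputs have the statistical structure the
analysis assumes; its defaults are fixed study conditions, not tuning
knobs.

A synthetic cell (`cell_spec()`, `simulate_cell_image()`) is an
axis-aligned ellipse (default semi-axes 34 × 26 px in a 128×128 16-bit
frame, i.e. a cell of roughly 60 px diameter — the field does not dictate
a pixel scale, so this is an exposed, arbitrary default) with a cortical
ring of width 4 px just inside its boundary. Ring intensity follows a
von-Mises-shaped crescent law normalized to peak amplitude:

$$ \text{ring}(\theta) = \text{baseline} +
   A\,\exp\!\big(\kappa(\cos(\theta-\mu) - 1)\big), $$

one concentration knob $\kappa$ with an exact uniform limit at
$\kappa = 0$. Region edges are blended linearly over one pixel using a
first-order signed distance to the ellipse — without anti-aliasing, the
staircase rim would leak a spurious angular signal into $P$ at high
$\kappa$. Noise is additive Gaussian clipped at zero (shot noise is not
modeled); masks are the exact inside-or-ring region.

One consequence of holding the *peak* (rather than the integrated mass) of
the crescent fixed: with a nonzero cortical baseline, the crescent's share
of the total cortical signal shrinks as it narrows, so $P$ as a function
of $\kappa$ rises and then falls (for baseline 0.5 and amplitude 1 it
peaks near $\kappa = 2$). For a pure crescent (baseline 0) the closed form
is $P = I_1(\kappa)/I_0(\kappa)$, strictly increasing from 0 toward 1, and
that is the regime in which the package's monotone-recovery checks run.
This is a property of the generative model, not of the statistic.

Division populations (`division_spec()`, `simulate_divisions()`) draw
angles wrapped-normal (mean 0°, SD 35° by default, matching a well-aligned
population; 68° emulates a randomized one), segregation ratios from a
Beta(2, 8) law (mean 0.2, strongly asymmetric inheritance), and
per-cell crescent profiles at concentration `polarization_kappa` centered
on each cell's division angle. Populations default to n = 60 cells, the
scale at which such experiments are typically reported. Defect tables
(`simulate_defect_table()`) are per-genotype multinomial draws, typically
100 scored wings per genotype.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: optical blur and the microscope PSF, uneven
illumination, neighboring cells touching the outline, segmentation error
beyond the half-pixel contour quantization, photobleaching, z-projection
artifacts, and any actual polarity biology (no protein dynamics or
mutual antagonism between cortical domains). The generator validates the
*measurement machinery*; it cannot validate image acquisition.

## Scaled experiment sizes

The validation suite runs, on one CPU in a few minutes: 1000-replicate
angle-SD recovery at n = 60; an exhaustive 2×2 sweep (margins ≤ 12)
against the closed-form Fisher oracle; 2000 null tables for the type-I
check (2×3, 20 per genotype); and 200 replicates of a two-genotype,
60-cells-each polarization comparison (wild-type-like κ = 4, SD 35° vs
mutant-like κ = 0.5, SD 68°, profile noise 10% of peak) in which the
Mann–Whitney p falls below 0.001 in at least 95% of replicates. These
sizes are the package's chosen validation scale; the functions themselves
have no such limits.

## Degenerate inputs, tie-breaks, tolerances

* All-zero profiles (e.g. background exceeding every grey value) raise a
  degeneracy error at normalization; batch scoring skips such cells with a
  warning instead of failing the batch.
* Equal daughter intensities define ratio 1; both-zero daughters are an
  error.
* Empty masks, fragmented masks (>1 component), components under 9 px,
  and outlines leaving the image are named errors.
* Probability ties in the exact tests: 1e-12 relative tolerance.
* Angles are reported to 0.01°; the wrap into $(-180, 180]$ maps −180 to
  +180.

## Worked example

```{r example}
sim <- simulate_cell_image(cell_spec(crescent_kappa = 4,
  crescent_center_angle = 30, noise_sd = 10, seed = 7))
prof <- extract_cortical_profile(sim$image, sim$mask, offset = -2)
polarization_coefficient(prof)

pop_wt <- simulate_divisions(division_spec(n_cells = 60, angle_sd = 35,
  polarization_kappa = 4, seed = 1), profile_samples = 36)
pop_mut <- simulate_divisions(division_spec(n_cells = 60, angle_sd = 68,
  polarization_kappa = 0.5, seed = 2), profile_samples = 36)
wt <- summarize_divisions(pop_wt); mut <- summarize_divisions(pop_mut)
glance(wt); glance(mut)
tidy(mann_whitney(wt$P, mut$P))
```
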