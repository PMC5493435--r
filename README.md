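# crescentr

Quantification of cortical polarity crescents in asymmetrically dividing
cells.

Before an asymmetric cell division — the *Drosophila* sensory organ
precursor (SOP) is the textbook case — polarity scaffolds and cell-fate
determinants accumulate in a *crescent* covering part of the cell cortex.
Experiments on such divisions keep asking the same four quantitative
questions: how concentrated is the crescent, is the cortical pattern
unipolar or bipolar, did the determinant segregate into one daughter cell,
and did the division axis align with the anterior–posterior (A–P) tissue
axis? crescentr answers them with a small set of reproducible statistics
computed from cortical intensity profiles, daughter-cell intensity pairs
and division-axis vectors, plus the two exact group-comparison tests such
datasets conventionally call for. It is written for cell and developmental
biologists quantifying polarity from fluorescence microscopy, and ships a
synthetic-data generator so every stage of the pipeline can be tested
without microscopes.

## The statistics

A cortical intensity profile is `N` grey values sampled at equally spaced
arc-length positions along the closed cell outline, mean-normalized as
`I_k = grey value_k / mean(grey values)` and assigned angles
`θ_k = 2πk/N`. The **polarization coefficient** is the first circular
harmonic magnitude

    a = (1/N) Σ I_k cos θ_k ,  b = (1/N) Σ I_k sin θ_k ,  P = √(a² + b²)

— 0 for a uniform cortical distribution, 1 for a single-point
concentration, ½ for `I = 1 + cos θ`. The **nematic order parameter**
`S = √(c² + d²)` is the same construction at the second harmonic (`2θ_k`)
and detects bipolar, axis-like patterns; by orthogonality a pure unipolar
crescent has `S = 0`. Per-division statistics are the **segregation
ratio** `min(i_a, i_b)/max(i_a, i_b)` of the daughter intensities (1 =
equal inheritance) and the **signed division angle** relative to the A–P
axis (clockwise in the viewer's frame positive, in (−180°, 180°]),
summarized by arithmetic and circular SD. Cortical enrichment is measured
as cortex/cytoplasm and crescent/remaining-membrane mean-intensity
ratios. Group comparisons: an exact/approximate **Mann–Whitney** test and
the **Freeman–Halton** extension of Fisher's exact test for r×c
defect-category tables, both implemented from first principles and
verified against enumeration oracles.

## Worked example

Simulate a cell with a concentrated crescent at 30°, extract its cortical
profile, and score it:

```r
library(crescentr)

sim  <- simulate_cell_image(cell_spec(crescent_kappa = 4,
  crescent_center_angle = 30, noise_sd = 10, seed = 7))
prof <- extract_cortical_profile(sim$image, sim$mask, offset = -2)
polarization_coefficient(prof)
#> Polarization coefficient P = 0.2582 (phase 30.42 deg, N = 100)
```

The recovered phase (30.42°) matches the simulated crescent center, and P
is far above the uniform null of 0. Now a scaled two-genotype experiment:
60 divisions each of a wild-type-like population (concentrated crescents,
tight angles) and a mutant-like one (weak crescents, near-randomized
angles):

```r
pop_wt  <- simulate_divisions(division_spec(n_cells = 60, angle_sd = 35,
  polarization_kappa = 4, seed = 1), profile_samples = 36)
pop_mut <- simulate_divisions(division_spec(n_cells = 60, angle_sd = 68,
  polarization_kappa = 0.5, seed = 2), profile_samples = 36)
wt <- summarize_divisions(pop_wt)
mut <- summarize_divisions(pop_mut)
glance(wt)[, c("n", "mean_ratio", "angle_sd_arith", "mean_P")]
#> # A tibble: 1 × 4
#>       n mean_ratio angle_sd_arith mean_P
#>   <int>      <dbl>          <dbl>  <dbl>
#> 1    60      0.211           29.9  0.253
glance(mut)[, c("n", "mean_ratio", "angle_sd_arith", "mean_P")]
#> # A tibble: 1 × 4
#>       n mean_ratio angle_sd_arith mean_P
#>   <int>      <dbl>          <dbl>  <dbl>
#> 1    60      0.195           78.8  0.138
tidy(mann_whitney(wt$P, mut$P))$p_value
#> [1] 3.556571e-21
```

The mutant-like group shows roughly doubled angular scatter (78.8° vs
29.9°) and a collapsed polarization coefficient, and the Mann–Whitney
comparison of P separates the groups decisively. Defect-category tables
are tested the same way:

```r
tab <- simulate_defect_table(rbind(c(0.9, 0.1), c(0.5, 0.5)),
  n = 100, labels = c("control", "mutant"),
  categories = c("none", "duplicated"), seed = 1)
freeman_halton(tab)
#> exact: statistic = 8.67882e-11, p = 1.907e-10
```

A shell front end wraps the same functions
(`inst/cli/crescentr simulate-profiles | extract | score | divisions |
compare ...`), with seeded, byte-reproducible outputs.

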