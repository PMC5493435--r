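# Independent oracles, deliberately naive: explicit loops and full
# enumeration, sharing no code with the implementation they check.

# circular harmonic magnitude by plain loop summation
naive_harmonic_magnitude <- function(values, harmonic) {
  values <- values / mean(values)
  n <- length(values)
  a <- 0
  b <- 0
  for (k in seq_len(n)) {
    a <- a + values[k] * cos(harmonic * k * 2 * pi / n) / n
    b <- b + values[k] * sin(harmonic * k * 2 * pi / n) / n
  }
  sqrt(a^2 + b^2)
}

# exact two-sided Mann-Whitney p by brute force over all group labelings,
# counting greater/tied pairs directly (no ranks)
perm_mw_p <- function(x, y, alternative = "two.sided") {
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) {
      u <- u + (ai > bi) + 0.5 * (ai == bi)
    }
    u
  }
  pooled <- c(x, y)
  na <- length(x)
  idx <- utils::combn(length(pooled), na)
  u_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  u_obs <- u_of(x, y)
  lower <- mean(u_all <= u_obs)
  upper <- mean(u_all >= u_obs)
  switch(alternative,
    two.sided = min(1, 2 * min(lower, upper)),
    less = lower,
    greater = upper)
}

# two-sided Fisher exact p for a 2x2 table from the closed-form
# hypergeometric, with the same 1e-12 relative tie tolerance
fisher_2x2_p <- function(tab) {
  m <- sum(tab[1, ]) # row 1 total
  n <- sum(tab[2, ])
  k <- sum(tab[, 1]) # column 1 total
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

wrap_degrees_for_test <- function(deg) ((deg + 180) %% 360) - 180

# deterministic pseudo-random nonnegative profile for property loops
random_profile <- function(n, rng) {
  abs(stats::rnorm(n, mean = rng[1], sd = rng[2]))
}
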