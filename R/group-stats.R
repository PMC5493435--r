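# Group-comparison tests implemented from first principles: the
# Mann-Whitney U test (exact by full enumeration for small untied samples,
# normal approximation with tie and continuity corrections otherwise) and
# the Freeman-Halton extension of Fisher's exact test to r x c tables.

new_crescent_test <- function(statistic, p_value, method, n_used,
                              alternative = NA_character_,
                              degenerate = FALSE) {
  structure(
    list(statistic = statistic, p_value = min(max(p_value, 0), 1),
         method = method, n_tables_or_perms = n_used,
         alternative = alternative, degenerate = degenerate),
    class = "crescent_test"
  )
}

#' @export
print.crescent_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %.4g%s\n", x$method,
    format(x$statistic, digits = 6), x$p_value,
    if (isTRUE(x$degenerate)) " (degenerate margins)" else ""))
  invisible(x)
}

#' @export
tidy.crescent_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, method = x$method,
         alternative = x$alternative, n_tables_or_perms = x$n_tables_or_perms,
         degenerate = x$degenerate)
}

#' @export
glance.crescent_test <- function(x, ...) tidy(x)

#' Mann-Whitney U test
#'
#' Unpaired nonparametric comparison of two samples via the Mann-Whitney U
#' statistic computed from midranks. For untied samples with
#' `n_a + n_b <= 16` the p value is exact, by full enumeration of all
#' `choose(n_a + n_b, n_a)` group labelings of the pooled values; the
#' two-sided exact p is `2 * min(lower tail, upper tail)` capped at 1.
#' Larger or tied samples use the normal approximation with the tie
#' correction to the variance and a 0.5 continuity correction. An
#' all-tied comparison carries no evidence and returns p = 1.
#'
#' @param x,y Numeric samples (both nonempty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (directional alternatives refer to `x` relative to `y`).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the enumeration path;
#'   default `NULL` auto-selects as above.
#' @return A `crescent_test` with the U statistic of the first sample,
#'   the p value, the path taken (`method`) and the enumeration size.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         exact = NULL) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be nonempty", class = "crescentr_error")
  }
  na <- length(x); nb <- length(y); n <- na + nb
  pooled <- c(x, y)
  r <- rank(pooled) # midranks
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  use_exact <- exact %||% (!has_ties && n <= 16)
  if (use_exact && has_ties) {
    warn("exact enumeration requested with ties present; using midrank U over labelings")
  }
  if (use_exact) {
    labelings <- combn(n, na)
    u_all <- colSums(matrix(r[labelings], nrow = na)) - na * (na + 1) / 2
    n_lab <- ncol(labelings)
    p <- switch(alternative,
      two.sided = 2 * min(mean(u_all <= u), mean(u_all >= u)),
      less = mean(u_all <= u),
      greater = mean(u_all >= u)
    )
    return(new_crescent_test(c(U = u), p, "exact", n_lab, alternative))
  }
  mu <- na * nb / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(new_crescent_test(c(U = u), 1, "normal-approximation", NA_real_,
      alternative))
  }
  sigma <- sqrt(sigma2)
  cc <- 0.5
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm((abs(u - mu) - cc) / sigma,
      lower.tail = FALSE),
    less = stats::pnorm((u - mu + cc) / sigma),
    greater = stats::pnorm((u - mu - cc) / sigma, lower.tail = FALSE)
  )
  new_crescent_test(c(U = u), p, "normal-approximation", NA_real_, alternative)
}

log_table_prob <- function(counts, log_margin_const) {
  log_margin_const - sum(lgamma(counts + 1))
}

# all r x c tables with the given margins, visited by recursive
# margin-constrained fill; f is called with each complete table's counts
enumerate_margin_tables <- function(row_sums, col_sums, f) {
  r <- length(row_sums)
  fill_row <- function(i, col_left, acc) {
    if (i == r) { # last row forced by the column margins
      f(c(acc, col_left))
      return(invisible(NULL))
    }
    compositions(row_sums[i], col_left, function(row) {
      fill_row(i + 1, col_left - row, c(acc, row))
    })
  }
  fill_row(1, col_sums, numeric(0))
}

# all ways to write `total` as an ordered sum bounded above by `caps`
compositions <- function(total, caps, f) {
  k <- length(caps)
  cell <- integer(k)
  recurse <- function(j, left) {
    if (j == k) {
      if (left <= caps[k]) {
        cell[k] <<- left
        f(cell)
      }
      return(invisible(NULL))
    }
    for (v in 0:min(left, caps[j])) {
      cell[j] <<- v
      recurse(j + 1, left - v)
    }
  }
  recurse(1, total)
}

#' Freeman-Halton exact test for r x c contingency tables
#'
#' Extension of Fisher's exact test to r x c tables of defect-category
#' counts per genotype. Under fixed margins each table has the multivariate
#' hypergeometric probability
#' \deqn{P(T) = \frac{\prod_i R_i! \, \prod_j C_j!}{n! \, \prod_{ij} n_{ij}!},}
#' and the p value sums P(T) over every table with the observed margins
#' whose probability does not exceed that of the observed table (with a
#' 1e-12 relative tolerance on probability ties, so floating-point
#' ordering noise cannot split exactly tied tables). Weights are computed
#' with log-factorials, so totals of hundreds of observations are safe.
#'
#' The fixed-margin table space is enumerated exhaustively when an upper
#' bound on its size is below `monte_carlo_threshold`; otherwise the same
#' criterion is evaluated by seeded Monte Carlo over margin-preserving
#' tables (Patefield's algorithm, [stats::r2dtable()]), with the observed
#' table included in the estimate. A table with an all-zero row or column
#' is degenerate (that margin admits only one configuration of itself) and
#' returns p = 1 with the `degenerate` flag set.
#'
#' @param table Matrix of nonnegative integer counts, at least 2 x 2
#'   (rows = genotypes, columns = defect categories).
#' @param monte_carlo_threshold Table-space size above which Monte Carlo
#'   replaces enumeration (default 5e6).
#' @param n_mc Number of Monte Carlo tables (default 1e5).
#' @param seed Integer seed for the Monte Carlo path.
#' @return A `crescent_test`; `statistic` is the observed table
#'   probability, `n_tables_or_perms` the number of tables visited.
#' @examples
#' freeman_halton(rbind(c(3, 0), c(0, 3)))
#' @export
freeman_halton <- function(table, monte_carlo_threshold = 5e6, n_mc = 1e5,
                           seed = NULL) {
  counts <- as.matrix(table)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("contingency table must hold nonnegative integer counts",
      class = "crescentr_error")
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    abort("contingency table must be at least 2 x 2", class = "crescentr_error")
  }
  row_sums <- rowSums(counts); col_sums <- colSums(counts)
  n <- sum(counts)
  if (n < 1) {
    abort("contingency table is empty", class = "crescentr_error")
  }
  if (any(row_sums == 0) || any(col_sums == 0)) {
    return(new_crescent_test(c(p_table = NA_real_), 1, "exact", 0,
      degenerate = TRUE))
  }
  log_margin_const <- sum(lgamma(row_sums + 1)) + sum(lgamma(col_sums + 1)) -
    lgamma(n + 1)
  log_p_obs <- log_table_prob(counts, log_margin_const)
  tie_tol <- log1p(1e-12)
  # the last row is forced by the column margins, so only the free rows
  # contribute to the table-space bound
  bound <- prod(choose(row_sums[-length(row_sums)] + length(col_sums) - 1,
    length(col_sums) - 1))
  if (is.finite(bound) && bound <= monte_carlo_threshold) {
    total_p <- 0
    n_tables <- 0L
    enumerate_margin_tables(row_sums, col_sums, function(cells) {
      lp <- log_table_prob(cells, log_margin_const)
      n_tables <<- n_tables + 1L
      if (lp <= log_p_obs + tie_tol) total_p <<- total_p + exp(lp)
    })
    return(new_crescent_test(c(p_table = exp(log_p_obs)), total_p, "exact",
      n_tables))
  }
  sims <- with_sim_seed(seed,
    stats::r2dtable(n_mc, row_sums, col_sums))
  hits <- vapply(sims, function(tab) {
    log_table_prob(tab, log_margin_const) <= log_p_obs + tie_tol
  }, logical(1))
  p <- (1 + sum(hits)) / (1 + n_mc)
  new_crescent_test(c(p_table = exp(log_p_obs)), p, "monte-carlo", n_mc)
}

#' Tabulate defect records and test genotypes against each other
#'
#' Aggregates long-format defect records (one row per wing/fly) into a
#' genotype x category contingency table and runs [freeman_halton()] on it.
#'
#' @param records Data frame with one row per scored unit.
#' @param genotype,category Column names (strings) holding the genotype
#'   and the defect category of each record.
#' @param categories Optional vector of allowed category labels; records
#'   with labels outside it raise an error (misspelled categories would
#'   otherwise silently become new table columns).
#' @param ... Passed on to [freeman_halton()].
#' @return A list of class `genotype_comparison`: `table` (the counts) and
#'   `test` (the `crescent_test`).
#' @examples
#' records <- data.frame(
#'   genotype = rep(c("control", "mutant"), each = 6),
#'   defect = c(rep("none", 5), "duplicated", rep("none", 2),
#'     rep("duplicated", 4))
#' )
#' compare_genotypes(records, "genotype", "defect")
#' @export
compare_genotypes <- function(records, genotype = "genotype",
                              category = "category", categories = NULL, ...) {
  stopifnot(is.data.frame(records))
  if (!all(c(genotype, category) %in% names(records))) {
    abort("records lack the genotype/category columns named",
      class = "crescentr_error")
  }
  g <- as.character(records[[genotype]])
  cat_col <- as.character(records[[category]])
  if (length(unique(g)) < 2) {
    abort("at least 2 genotypes are required", class = "crescentr_error")
  }
  if (!is.null(categories)) {
    unknown <- setdiff(unique(cat_col), categories)
    if (length(unknown) > 0) {
      abort(paste0("unknown defect category label(s): ",
        paste(unknown, collapse = ", ")), class = "crescentr_error")
    }
    cat_col <- factor(cat_col, levels = categories)
  }
  counts <- unclass(table(g, cat_col))
  names(dimnames(counts)) <- NULL
  structure(
    list(table = counts, test = freeman_halton(counts, ...)),
    class = "genotype_comparison"
  )
}

#' @export
print.genotype_comparison <- function(x, ...) {
  print(x$table)
  print(x$test)
  invisible(x)
}

#' @export
tidy.genotype_comparison <- function(x, ...) tidy(x$test)

#' @export
glance.genotype_comparison <- function(x, ...) tidy(x$test)
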