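#' Binomial proportion with confidence interval
#'
#' Default method is the continuity-corrected Wilson score interval (the
#' interval behind `stats::prop.test`), which reproduces the intervals
#' printed alongside the cohort proportions in the source tables; plain
#' Wilson and Clopper-Pearson are selectable.
#'
#' @param k Number of successes.
#' @param n Number of trials (>= 1).
#' @param method `"wilson_cc"` (default), `"wilson"`, or
#'   `"clopper_pearson"`.
#' @param level Confidence level.
#' @return Object of class `hrd_proportion`: list `successes`, `trials`,
#'   `proportion`, `lower`, `upper`, `level`, `method`.
#' @export
proportion_ci <- function(k, n, method = c("wilson_cc", "wilson",
                                           "clopper_pearson"),
                          level = 0.95) {
  method <- match.arg(method)
  stopifnot(length(k) == 1, length(n) == 1)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  ci <- switch(method,
    wilson_cc = stats::prop.test(k, n, conf.level = level,
                                 correct = TRUE)$conf.int,
    clopper_pearson = stats::binom.test(k, n, conf.level = level)$conf.int,
    wilson = {
      z <- stats::qnorm(1 - (1 - level) / 2)
      p <- k / n
      center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      c(max(0, center - half), min(1, center + half))
    })
  out <- list(successes = k, trials = n, proportion = k / n,
              lower = ci[1], upper = ci[2], level = level, method = method)
  class(out) <- "hrd_proportion"
  out
}

#' @export
print.hrd_proportion <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%g%% CI %.1f-%.1f, %s)\n",
              x$successes, x$trials, 100 * x$proportion, 100 * x$level,
              100 * x$lower, 100 * x$upper, x$method))
  invisible(x)
}

phi_correlation <- function(a, b) {
  # phi of the paired 2x2 table; 0 when any margin is empty
  t11 <- sum(a & b); t10 <- sum(a & !b); t01 <- sum(!a & b); t00 <- sum(!a & !b)
  den <- (t11 + t10) * (t01 + t00) * (t11 + t01) * (t10 + t00)
  if (den <= 0) return(0)
  (t11 * t00 - t10 * t01) / sqrt(den)
}

#' Partially overlapping samples z-test for two proportions
#'
#' Compares the proportion of successes under condition A versus condition B
#' when some observations are measured under both conditions (paired) and
#' some under only one. The pooled-variance z statistic down-weights the
#' variance by the phi correlation of the paired 2x2 table (Derrick et al.
#' 2015, the dichotomous-variables variant); with no paired observations it
#' reduces exactly to the classical pooled two-proportion z-test.
#'
#' @param paired_a,paired_b Logical outcomes of the paired observations
#'   under condition A and B (equal length, possibly length 0).
#' @param only_a,only_b Logical outcomes of the observations seen under only
#'   one condition.
#' @param alternative `"greater"` (prop A > prop B), `"less"`, or
#'   `"two.sided"`.
#' @return List `z`, `p`, `prop_a`, `prop_b`, `phi`, `degenerate`. When all
#'   outcomes are identical the variance is zero and the test is degenerate:
#'   `z = 0`, one-sided `p = 0.5` (two-sided `p = 1`).
#' @export
overlap_z_test <- function(paired_a, paired_b, only_a = logical(0),
                           only_b = logical(0),
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(paired_a) == length(paired_b))
  paired_a <- as.logical(paired_a); paired_b <- as.logical(paired_b)
  only_a <- as.logical(only_a); only_b <- as.logical(only_b)
  n12 <- length(paired_a)
  n1 <- n12 + length(only_a)
  n2 <- n12 + length(only_b)
  if (n1 == 0 || n2 == 0) {
    stop("both conditions need at least one observation", call. = FALSE)
  }
  x1 <- sum(paired_a) + sum(only_a)
  x2 <- sum(paired_b) + sum(only_b)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  phi <- if (n12 > 0) phi_correlation(paired_a, paired_b) else 0
  v <- pool * (1 - pool) * (1 / n1 + 1 / n2 - 2 * phi * n12 / (n1 * n2))
  if (!is.finite(v) || v <= 0) {
    p <- if (alternative == "two.sided") 1 else 0.5
    return(list(z = 0, p = p, prop_a = p1, prop_b = p2, phi = phi,
                degenerate = TRUE))
  }
  z <- (p1 - p2) / sqrt(v)
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(z = z, p = p, prop_a = p1, prop_b = p2, phi = phi, degenerate = FALSE)
}

#' Pairwise one-sided Fisher exact tests with Bonferroni correction
#'
#' Tests every pair of groups on a 2x2 success/failure table via the
#' hypergeometric tail (`stats::fisher.test`); adjusted p-values are
#' Bonferroni over the number of pairs.
#'
#' @param successes,failures Nonnegative integer vectors, one entry per
#'   group; names (or `groups`) label the groups.
#' @param groups Optional group labels.
#' @param alternative Passed to `fisher.test`; for pair (g1, g2) the
#'   alternative refers to the odds of success in g1 relative to g2.
#' @param correction `"bonferroni"` (family = number of pairs) or `"none"`.
#' @return Data frame `group1`, `group2`, `p`, `p_adj`; a pair involving a
#'   group with zero total has `NA` p-values.
#' @export
pairwise_fisher <- function(successes, failures, groups = NULL,
                            alternative = c("greater", "less", "two.sided"),
                            correction = c("bonferroni", "none")) {
  alternative <- match.arg(alternative)
  correction <- match.arg(correction)
  stopifnot(length(successes) == length(failures), length(successes) >= 2)
  if (is.null(groups)) {
    groups <- names(successes)
    if (is.null(groups)) groups <- as.character(seq_along(successes))
  }
  pairs <- utils::combn(seq_along(groups), 2)
  n_pairs <- ncol(pairs)
  res <- data.frame(group1 = groups[pairs[1, ]], group2 = groups[pairs[2, ]],
                    p = NA_real_, p_adj = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n_pairs)) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    if (successes[g1] + failures[g1] == 0 || successes[g2] + failures[g2] == 0) {
      next
    }
    tab <- matrix(c(successes[g1], failures[g1],
                    successes[g2], failures[g2]), nrow = 2, byrow = TRUE)
    res$p[i] <- stats::fisher.test(tab, alternative = alternative)$p.value
  }
  res$p_adj <- if (correction == "bonferroni") {
    bonferroni_adjust(res$p, family = n_pairs)
  } else {
    res$p
  }
  res
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), via
#' `stats::cor(method = "spearman")`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho, or `NA` when either vector is constant.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Bonferroni adjustment
#'
#' Multiplies each p-value by the family size and caps at 1. `NA` entries
#' are preserved.
#'
#' @param p Numeric p-values in \[0,1\].
#' @param family Family size (default: number of p-values).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, family = length(p)) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)), family >= 1)
  pmin(1, p * family)
}
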