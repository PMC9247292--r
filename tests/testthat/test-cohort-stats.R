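test_that("proportion intervals bracket k/n, shrink with n, and mirror", {
  p <- proportion_ci(5, 34)
  expect_lte(p$lower, p$proportion)
  expect_gte(p$upper, p$proportion)
  expect_equal(proportion_ci(0, 10)$lower, 0)
  expect_equal(proportion_ci(10, 10)$upper, 1)

  # mirror symmetry of the score interval around 1/2
  for (m in c("wilson_cc", "wilson", "clopper_pearson")) {
    a <- proportion_ci(7, 25, method = m)
    b <- proportion_ci(18, 25, method = m)
    expect_equal(a$lower, 1 - b$upper, tolerance = 1e-10)
    expect_equal(a$upper, 1 - b$lower, tolerance = 1e-10)
  }

  # widths shrink as n grows at fixed k/n
  w <- vapply(c(20, 80, 320), function(n) {
    ci <- proportion_ci(n / 4, n)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(w) < 0))

  expect_error(proportion_ci(1, 0), "at least 1")
  expect_error(proportion_ci(5, 3), "\\[0, n\\]")
})

test_that("the default interval reproduces the published cohort CIs", {
  p1 <- proportion_ci(5, 34)
  expect_equal(round(100 * p1$proportion, 1), 14.7)
  expect_equal(round(100 * p1$lower, 1), 5.5)
  expect_equal(round(100 * p1$upper, 1), 31.8)

  p2 <- proportion_ci(20, 71)
  expect_equal(round(100 * p2$proportion, 1), 28.2)
  expect_equal(round(100 * p2$lower, 1), 18.4)
  expect_equal(round(100 * p2$upper, 1), 40.3)
})

test_that("overlap z-test reduces to the classical test without pairs", {
  oa <- rep(c(TRUE, FALSE), c(12, 18))
  ob <- rep(c(TRUE, FALSE), c(6, 24))
  got <- overlap_z_test(logical(0), logical(0), oa, ob, "two.sided")
  # z^2 equals the uncorrected chi-square statistic of the pooled 2x2 test
  ref <- suppressWarnings(
    stats::prop.test(c(12, 6), c(30, 30), correct = FALSE))
  expect_equal(got$z^2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(got$phi, 0)
})

test_that("overlap z-test degenerates gracefully and uses pairing", {
  same <- overlap_z_test(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(same$z, 0)
  expect_equal(same$p, 0.5)

  const <- overlap_z_test(rep(TRUE, 5), rep(TRUE, 5))
  expect_true(const$degenerate)

  # positively correlated pairs reduce the variance: |z| grows with phi
  pa <- rep(c(TRUE, FALSE), c(12, 28))
  withr::with_seed(7, {
    pb_indep <- rep(c(FALSE, TRUE, FALSE), c(6, 6, 28))[sample(40)]
    pb_corr <- pa
    flip <- sample(which(pa), 6)
    pb_corr[flip] <- FALSE
  })
  z_corr <- abs(overlap_z_test(pa, pb_corr, alternative = "two.sided")$z)
  z_ind <- abs(overlap_z_test(pa, pb_indep, alternative = "two.sided")$z)
  expect_gt(z_corr, z_ind)
})

test_that("overlap z-test p agrees with the permutation reference", {
  make_instance <- function(seed) {
    set.seed(seed)
    base <- runif(40) < 0.4
    pa <- ifelse(runif(40) < 0.7, base, runif(40) < 0.4)
    pb <- ifelse(runif(40) < 0.7, base, runif(40) < 0.45)
    list(pa = pa, pb = pb, oa = runif(10) < 0.4, ob = runif(10) < 0.45)
  }
  for (seed in c(2, 5)) {
    inst <- make_instance(seed)
    p_normal <- overlap_z_test(inst$pa, inst$pb, inst$oa, inst$ob,
                               "greater")$p
    p_perm <- perm_overlap_p(inst$pa, inst$pb, inst$oa, inst$ob,
                             replicates = 2e4, alternative = "greater",
                             seed = seed)
    # discreteness of n = 60 binary outcomes bounds achievable agreement
    expect_lt(abs(p_normal - p_perm), 0.08)
  }
})

test_that("pairwise Fisher matches enumeration and the published contrast", {
  # identical groups are never distinguishable
  res <- pairwise_fisher(c(5, 5), c(10, 10), alternative = "two.sided")
  expect_equal(res$p, 1)

  # extreme table has the closed-form single-tail probability
  res2 <- pairwise_fisher(c(0, 10), c(10, 0), alternative = "less",
                          correction = "none")
  expect_equal(res2$p, 1 / choose(20, 10), tolerance = 1e-12)

  # hypergeometric enumeration oracle across random tables (n <= 200)
  set.seed(141)
  for (i in 1:20) {
    s <- sample(0:60, 2, replace = TRUE)
    f <- sample(1:40, 2, replace = TRUE)
    for (alt in c("greater", "less")) {
      got <- pairwise_fisher(s, f, alternative = alt, correction = "none")$p
      expect_equal(got, fisher_tail_oracle(s[1], f[1], s[2], f[2], alt),
                   tolerance = 1e-10)
    }
  }

  # breast vs pancreas unexplained contrast, Bonferroni over 3 pairs
  res3 <- pairwise_fisher(c(breast = 11, ovary = 11, pancreas = 20),
                          c(breast = 76, ovary = 30, pancreas = 51),
                          alternative = "less")
  bp <- res3[res3$group1 == "breast" & res3$group2 == "pancreas", ]
  expect_equal(round(bp$p_adj, 3), 0.037, tolerance = 1e-8)

  # zero-total group yields an NA marker
  res4 <- pairwise_fisher(c(0, 3), c(0, 4))
  expect_true(is.na(res4$p))
})

test_that("spearman correlation equals mid-rank Pearson, with tie handling", {
  x <- c(1, 4, 2, 9, 3)
  expect_equal(spearman_corr(x, x), 1)
  expect_equal(spearman_corr(x, -x), -1)
  set.seed(151)
  x <- sample(1:5, 15, replace = TRUE)  # heavy ties
  y <- x + sample(0:3, 15, replace = TRUE)
  expect_equal(spearman_corr(x, y), stats::cor(rank(x), rank(y)))
  expect_true(is.na(spearman_corr(rep(1, 5), 1:5)))
})

test_that("Bonferroni adjustment multiplies, caps, and never decreases", {
  expect_equal(bonferroni_adjust(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(0.6), 0.6)
  expect_equal(bonferroni_adjust(c(0.4, 0.9)), c(0.8, 1))
  set.seed(161)
  p <- runif(20)
  adj <- bonferroni_adjust(p, family = 7)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(adj, pmin(1, p * 7))
})
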