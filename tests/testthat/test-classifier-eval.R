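test_that("AUC equals the exhaustive pair-counting probability", {
  expect_equal(compute_roc(c(0.9, 0.8, 0.1), c(TRUE, TRUE, FALSE))$auc, 1)
  expect_equal(compute_roc(rep(0.4, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE,
                                          FALSE))$auc, 0.5)
  set.seed(21)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(compute_roc(scores, labels)$auc,
                 auc_pair_oracle(scores, labels))
  }
  expect_error(compute_roc(c(0.1, 0.9), c(TRUE, TRUE)), "degenerate")
})

test_that("ROC points are monotone and invariant to monotone transforms", {
  set.seed(31)
  scores <- runif(40)
  labels <- runif(40) < 0.5
  roc <- compute_roc(scores, labels)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_equal(range(roc$points$fpr), c(0, 1))
  for (f in list(function(x) x^3, function(x) exp(2 * x),
                 function(x) qlogis(pmin(pmax(x, 1e-6), 1 - 1e-6)))) {
    tr <- compute_roc(f(scores), labels)
    expect_equal(tr$auc, roc$auc)
    expect_equal(tr$points[c("fpr", "tpr")], roc$points[c("fpr", "tpr")])
  }
})

test_that("stratified bootstrap CI is reproducible, sane, and covers", {
  # perfect separation pins the interval at 1
  s <- c(0.9, 0.95, 0.99, 0.1, 0.05, 0.2)
  l <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(auc_bootstrap_ci(s, l, replicates = 50, seed = 1),
               c(1, 1), ignore_attr = TRUE)

  set.seed(41)
  scores <- c(rbeta(30, 6, 2), rbeta(70, 2, 6))
  labels <- rep(c(TRUE, FALSE), c(30, 70))
  ci1 <- auc_bootstrap_ci(scores, labels, replicates = 300, seed = 7)
  ci2 <- auc_bootstrap_ci(scores, labels, replicates = 300, seed = 7)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], ci1[2])
  expect_true(all(ci1 >= 0 & ci1 <= 1))

  # coverage of the analytic AUC (~0.96) of the generative Beta mixture
  target <- beta_auc_analytic(c(5, 2), c(2, 5))
  covered <- vapply(1:60, function(i) {
    set.seed(1000 + i)
    sc <- c(rbeta(60, 5, 2), rbeta(140, 2, 5))
    lb <- rep(c(TRUE, FALSE), c(60, 140))
    ci <- auc_bootstrap_ci(sc, lb, replicates = 400, seed = i)
    ci[1] <= target && target <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("average precision matches baselines and the dense-sweep oracle", {
  expect_equal(compute_pr(c(0.9, 0.8, 0.1), c(TRUE, TRUE, FALSE))$auprc, 1)
  # all-tied scores give the prevalence
  expect_equal(compute_pr(rep(0.3, 10), rep(c(TRUE, FALSE), c(3, 7)))$auprc,
               0.3)
  set.seed(51)
  for (i in 1:10) {
    n <- 20
    scores <- round(runif(n), 2)
    labels <- runif(n) < 0.5
    if (!any(labels)) next
    pr <- compute_pr(scores, labels)
    expect_lt(abs(pr$auprc - pr_grid_oracle(scores, labels)), 0.02)
  }
  expect_error(compute_pr(c(0.2, 0.4), c(FALSE, FALSE)), "degenerate")
})

test_that("DeLong test is antisymmetric and agrees with pROC", {
  set.seed(61)
  labels <- runif(50) < 0.4
  a <- plogis(2 * labels + rnorm(50))
  b <- plogis(1.5 * labels + rnorm(50))

  same <- delong_paired_test(a, a, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  d1 <- delong_paired_test(a, b, labels)
  d2 <- delong_paired_test(b, a, labels)
  expect_equal(d1$z, -d2$z)
  expect_equal(d1$p, d2$p)

  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(
    pROC::roc(labels, a, quiet = TRUE, direction = "<"),
    pROC::roc(labels, b, quiet = TRUE, direction = "<"),
    method = "delong", paired = TRUE)
  expect_equal(d1$p, ref$p.value, tolerance = 1e-8)
  expect_equal(d1$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-10)
})

test_that("confusion tables partition the cohort at any threshold", {
  scores <- c(0.9, 0.3)
  labels <- c(TRUE, FALSE)
  ct <- confusion_at_threshold(scores, labels, 0.5)
  expect_equal(unlist(ct[c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 0, fn = 0, tn = 1))
  expect_equal(confusion_at_threshold(scores, labels, 0)$fn +
                 confusion_at_threshold(scores, labels, 0)$tn, 0)
  high <- confusion_at_threshold(scores, labels, 0.91)
  expect_equal(high$tp + high$fp, 0)
  # exact-threshold score is called positive under >=, negative under strict
  expect_equal(confusion_at_threshold(c(0.5), c(TRUE), 0.5)$tp, 1)
  expect_equal(confusion_at_threshold(c(0.5), c(TRUE), 0.5, strict = TRUE)$tp,
               0)

  set.seed(71)
  scores <- runif(30)
  labels <- runif(30) < 0.5
  for (thr in c(0, 0.25, 0.5, 0.99)) {
    ct <- confusion_at_threshold(scores, labels, thr)
    expect_equal(ct$tp + ct$fp + ct$fn + ct$tn, 30)
  }
  # sensitivity nonincreasing, specificity nondecreasing in the threshold
  thr_grid <- seq(0, 1, by = 0.05)
  m <- vapply(thr_grid, function(t)
    table_metrics(confusion_at_threshold(scores, labels, t)), numeric(3))
  expect_true(all(diff(m["sensitivity", ]) <= 1e-12))
  expect_true(all(diff(m["specificity", ]) >= -1e-12))
})

test_that("table metrics reproduce the published ovarian accuracies", {
  chord_default <- list(tp = 29, fp = 5, fn = 1, tn = 31)
  expect_equal(round(table_metrics(chord_default)["accuracy"], 2), 0.91,
               ignore_attr = TRUE)
  hrdetect_default <- list(tp = 30, fp = 11, fn = 0, tn = 25)
  expect_equal(round(table_metrics(hrdetect_default)["accuracy"], 2), 0.83,
               ignore_attr = TRUE)
  # degenerate denominators yield NA markers, not errors
  m <- table_metrics(list(tp = 5, fp = 0, fn = 0, tn = 0))
  expect_equal(unname(m["accuracy"]), 1)
  expect_equal(unname(m["sensitivity"]), 1)
  expect_true(is.na(m["specificity"]))
})
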