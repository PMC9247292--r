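check_scores_labels <- function(scores, labels, need_both = TRUE,
                                need_pos = FALSE) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (need_both && (!any(labels) || all(labels))) {
    stop("degenerate input: both a positive and a negative label are required",
         call. = FALSE)
  }
  if (need_pos && !any(labels)) {
    stop("degenerate input: at least one positive label is required",
         call. = FALSE)
  }
  labels
}

# Mann-Whitney AUC via mid-ranks; ties count 1/2, matching pair counting.
auc_mw <- function(scores, labels) {
  r <- rank(scores)
  np <- sum(labels)
  nn <- sum(!labels)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Receiver operating characteristic of a continuous score
#'
#' Computes the ROC curve of `scores` against binary `labels` (predicted
#' positive when score >= threshold), with thresholds at the unique observed
#' score values. The AUC is the Mann-Whitney pair-counting probability
#' (equivalently, the trapezoidal area under the tie-aware curve); ties
#' contribute 1/2.
#'
#' @param scores Numeric classifier scores.
#' @param labels Logical (or 0/1) truth labels; both classes required.
#' @param ci_replicates If not `NULL`, number of stratified bootstrap
#'   replicates for a percentile AUC confidence interval.
#' @param ci_level Confidence level for the bootstrap interval.
#' @param seed Seed for the bootstrap (required when `ci_replicates` set).
#' @return An object of class `hrd_roc`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`, and `ci`
#'   (`NULL` or `c(lower, upper)` with attributes).
#' @export
compute_roc <- function(scores, labels, ci_replicates = NULL,
                        ci_level = 0.95, seed = NULL) {
  labels <- check_scores_labels(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels)
  nn <- sum(!labels)
  tp <- vapply(thr, function(t) sum(scores >= t & labels), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & !labels), numeric(1))
  pts <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / nn),
                    tpr = c(0, tp / np))
  out <- list(points = pts, auc = auc_mw(scores, labels),
              n_pos = np, n_neg = nn, ci = NULL)
  if (!is.null(ci_replicates)) {
    out$ci <- auc_bootstrap_ci(scores, labels, replicates = ci_replicates,
                               level = ci_level, seed = seed)
  }
  class(out) <- "hrd_roc"
  out
}

#' @export
print.hrd_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  if (!is.null(x$ci)) {
    cat(sprintf("  %g%% bootstrap CI [%.4f, %.4f] (%d replicates)\n",
                100 * attr(x$ci, "level"), x$ci[1], x$ci[2],
                attr(x$ci, "replicates")))
  }
  invisible(x)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Percentile interval over AUCs of bootstrap resamples drawn within each
#' class (positives resampled among positives, negatives among negatives),
#' so every resample retains both classes.
#'
#' @inheritParams compute_roc
#' @param replicates Number of bootstrap resamples (the analysis default is
#'   2000).
#' @param level Confidence level.
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @return `c(lower, upper)` with attributes `level`, `replicates`, `seed`.
#' @export
auc_bootstrap_ci <- function(scores, labels, replicates = 2000,
                             level = 0.95, seed = NULL) {
  labels <- check_scores_labels(scores, labels)
  stopifnot(replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  pos <- scores[labels]
  neg <- scores[!labels]
  np <- length(pos)
  nn <- length(neg)
  aucs <- vapply(seq_len(replicates), function(i) {
    sp <- pos[sample.int(np, np, replace = TRUE)]
    sn <- neg[sample.int(nn, nn, replace = TRUE)]
    auc_mw(c(sp, sn), c(rep(TRUE, np), rep(FALSE, nn)))
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(aucs, c(alpha, 1 - alpha), type = 7))
  attr(ci, "level") <- level
  attr(ci, "replicates") <- replicates
  attr(ci, "seed") <- seed
  ci
}

#' Precision-recall curve and average precision
#'
#' Sweeps thresholds over the unique score values (highest first, tied
#' scores handled as one block) and computes average precision:
#' the sum of precision times the recall increment at each threshold step.
#' A score vector with all values tied yields the positive prevalence, the
#' area of the baseline classifier.
#'
#' @inheritParams compute_roc
#' @return An object of class `hrd_pr`: list with `points` (data frame
#'   `threshold`, `recall`, `precision`) and `auprc`.
#' @export
compute_pr <- function(scores, labels) {
  labels <- check_scores_labels(scores, labels, need_both = FALSE,
                                need_pos = TRUE)
  thr <- sort(unique(scores), decreasing = TRUE)
  np <- sum(labels)
  tp <- vapply(thr, function(t) sum(scores >= t & labels), numeric(1))
  pred <- vapply(thr, function(t) sum(scores >= t), numeric(1))
  recall <- tp / np
  precision <- tp / pred
  ap <- sum(diff(c(0, recall)) * precision)
  out <- list(points = data.frame(threshold = thr, recall = recall,
                                  precision = precision),
              auprc = ap, n_pos = np, n_neg = sum(!labels))
  class(out) <- "hrd_pr"
  out
}

#' @export
print.hrd_pr <- function(x, ...) {
  cat(sprintf("PR: average precision = %.4f (%d positives, %d negatives)\n",
              x$auprc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two classifiers scored on the same samples using
#' DeLong's structural components: per-sample placement values whose
#' empirical covariance gives the variance of the AUC difference. The
#' two-sided p comes from the normal reference distribution.
#'
#' @param scores_a,scores_b Score vectors aligned to the same samples.
#' @param labels Truth labels; both classes required.
#' @return List with `auc_a`, `auc_b`, `z`, `p`. When the variance of the
#'   difference is zero (e.g. identical scores), `z = 0`, `p = 1`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  labels <- check_scores_labels(scores_a, labels)
  stopifnot(length(scores_b) == length(scores_a))
  pos_a <- scores_a[labels]; neg_a <- scores_a[!labels]
  pos_b <- scores_b[labels]; neg_b <- scores_b[!labels]
  m <- length(pos_a); n <- length(neg_a)
  placement <- function(pos, neg) {
    # V10[i]: fraction of negatives below positive i (ties 1/2); V01[j] dual
    v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n,
                  numeric(1))
    v01 <- vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / m,
                  numeric(1))
    list(v10 = v10, v01 = v01)
  }
  pa <- placement(pos_a, neg_a)
  pb <- placement(pos_b, neg_b)
  auc_a <- mean(pa$v10)
  auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  s <- s10 / m + s01 / n
  var_diff <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  if (!is.finite(var_diff) || var_diff <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- (auc_a - auc_b) / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = auc_a, auc_b = auc_b, z = z, p = p)
}

#' Confusion table of a score at a threshold
#'
#' Samples are called HRD-positive when score >= threshold (set
#' `strict = TRUE` for a strict > rule).
#'
#' @inheritParams compute_roc
#' @param threshold Score cutoff.
#' @param strict Call positives with `>` instead of `>=`.
#' @return Object of class `hrd_confusion`: list `tp`, `fp`, `fn`, `tn`,
#'   `threshold`; counts partition the cohort.
#' @export
confusion_at_threshold <- function(scores, labels, threshold, strict = FALSE) {
  labels <- check_scores_labels(scores, labels, need_both = FALSE)
  pred <- if (strict) scores > threshold else scores >= threshold
  out <- list(tp = sum(pred & labels), fp = sum(pred & !labels),
              fn = sum(!pred & labels), tn = sum(!pred & !labels),
              threshold = threshold)
  class(out) <- "hrd_confusion"
  out
}

#' Accuracy, sensitivity and specificity of a confusion table
#'
#' @param ct An `hrd_confusion` object or list with `tp`, `fp`, `fn`, `tn`.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`;
#'   a metric with a zero denominator is `NA` (undefined), not an error.
#' @export
table_metrics <- function(ct) {
  n <- ct$tp + ct$fp + ct$fn + ct$tn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  c(accuracy = safe_div(ct$tp + ct$tn, n),
    sensitivity = safe_div(ct$tp, ct$tp + ct$fn),
    specificity = safe_div(ct$tn, ct$tn + ct$fp))
}
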