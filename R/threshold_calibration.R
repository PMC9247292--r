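#' Candidate decision thresholds for a score vector
#'
#' Midpoints between consecutive distinct sorted scores, plus one cutoff
#' strictly below the minimum and one strictly above the maximum (half the
#' smallest positive gap beyond the range), so that every achievable
#' confusion table is reachable under the >= decision rule. With `k`
#' distinct scores this yields exactly `k + 1` candidates.
#'
#' @param scores Numeric scores, at least one value.
#' @return Ascending numeric vector of cutoffs. If all scores are identical
#'   a single degenerate candidate (the common value) is returned, with
#'   attribute `degenerate = TRUE`.
#' @export
candidate_thresholds <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1) {
    out <- u
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  gaps <- diff(u)
  pad <- min(gaps) / 2
  c(u[1] - pad, u[-length(u)] + gaps / 2, u[length(u)] + pad)
}

threshold_criterion <- function(scores, labels, cuts,
                                criterion = c("accuracy", "youden"),
                                strict = FALSE) {
  criterion <- match.arg(criterion)
  pred <- if (strict) outer(scores, cuts, `>`) else outer(scores, cuts, `>=`)
  if (criterion == "accuracy") {
    colMeans(pred == labels)
  } else {
    sens <- colSums(pred & labels) / sum(labels)
    spec <- colSums(!pred & !labels) / sum(!labels)
    sens + spec - 1
  }
}

#' Best single threshold for a score vector
#'
#' Exhaustive sweep over [candidate_thresholds()], maximizing classification
#' accuracy (default) or Youden's J. Ties are broken toward the smallest
#' cutoff, which favors sensitivity.
#'
#' @param scores Numeric scores.
#' @param labels Truth labels; both classes required.
#' @param criterion `"accuracy"` (default) or `"youden"`.
#' @param strict Use a strict `>` positive-call rule.
#' @return The optimal cutoff, with attribute `criterion_value`.
#' @export
best_threshold <- function(scores, labels, criterion = "accuracy",
                           strict = FALSE) {
  labels <- check_scores_labels(scores, labels)
  cuts <- candidate_thresholds(scores)
  crit <- threshold_criterion(scores, labels, cuts, criterion, strict)
  best <- which(crit >= max(crit) - 1e-12)[1]
  out <- cuts[best]
  attributes(out) <- NULL
  attr(out, "criterion_value") <- crit[best]
  out
}

#' Stratified k-fold assignment
#'
#' Assigns fold indices 1..k so that within each class the per-fold counts
#' differ by at most one. Uses the current RNG state for shuffling.
#'
#' @param labels Logical class labels.
#' @param k Number of folds.
#' @return Integer vector of fold indices aligned to `labels`.
#' @export
stratified_folds <- function(labels, k) {
  labels <- as.logical(labels)
  fold <- integer(length(labels))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(labels == cls)
    if (length(idx) == 0) next
    fold[idx[sample.int(length(idx))]] <-
      rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Cancer-type-specific threshold by tenfold nested cross-validation
#'
#' The cohort is split into `outer_k` stratified folds. For each outer fold,
#' the remaining samples (the outer-training set) are split into `inner_k`
#' stratified folds; on each inner-training portion the accuracy-optimal
#' threshold is fit by exhaustive sweep, and the `inner_k` thresholds are
#' averaged. That averaged threshold is then scored on the held-out outer
#' fold. The reported optimal threshold is the mean of the `outer_k`
#' averaged thresholds, and the reported accuracy the mean of the held-out
#' fold accuracies.
#'
#' @param scores Numeric scores.
#' @param labels Truth labels; each class must contain at least `outer_k`
#'   samples so that stratified folds keep both classes everywhere.
#' @param outer_k,inner_k Fold counts (default tenfold at both levels).
#' @param seed Integer seed controlling the fold shuffles.
#' @param criterion Threshold criterion, see [best_threshold()].
#' @return Object of class `hrd_calibration`: list with `optimal_threshold`,
#'   `outer_thresholds`, `outer_accuracies`, `mean_accuracy`, `fold_map`,
#'   `seed`, `outer_k`, `inner_k`, `criterion`.
#' @export
nested_cv_calibrate <- function(scores, labels, outer_k = 10, inner_k = 10,
                                seed = 1L, criterion = "accuracy") {
  labels <- check_scores_labels(scores, labels)
  np <- sum(labels)
  nn <- sum(!labels)
  if (min(np, nn) < outer_k) {
    stop(sprintf(paste0("nested cross-validation needs at least %d samples ",
                        "in each class (outer_k); got %d positives and %d ",
                        "negatives"), outer_k, np, nn), call. = FALSE)
  }
  set.seed(seed)
  fold <- stratified_folds(labels, outer_k)
  outer_thr <- numeric(outer_k)
  outer_acc <- numeric(outer_k)
  for (i in seq_len(outer_k)) {
    tr <- fold != i
    s_tr <- scores[tr]
    l_tr <- labels[tr]
    inner <- stratified_folds(l_tr, inner_k)
    inner_thr <- vapply(seq_len(inner_k), function(j) {
      keep <- inner != j
      if (!any(l_tr[keep]) || all(l_tr[keep])) {
        stop("an inner-training fold lost one class; increase the cohort ",
             "or lower inner_k", call. = FALSE)
      }
      as.numeric(best_threshold(s_tr[keep], l_tr[keep], criterion))
    }, numeric(1))
    outer_thr[i] <- mean(inner_thr)
    outer_acc[i] <- mean((scores[!tr] >= outer_thr[i]) == labels[!tr])
  }
  out <- list(optimal_threshold = mean(outer_thr),
              outer_thresholds = outer_thr,
              outer_accuracies = outer_acc,
              mean_accuracy = mean(outer_acc),
              fold_map = fold,
              seed = seed, outer_k = outer_k, inner_k = inner_k,
              criterion = criterion)
  class(out) <- "hrd_calibration"
  out
}

#' @export
print.hrd_calibration <- function(x, ...) {
  cat(sprintf(paste0("Nested CV calibration (%dx%d folds, criterion %s, ",
                     "seed %d):\n  optimal threshold %.4f, held-out mean ",
                     "accuracy %.4f\n"),
              x$outer_k, x$inner_k, x$criterion, x$seed,
              x$optimal_threshold, x$mean_accuracy))
  invisible(x)
}
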