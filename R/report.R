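#' Analysis parameters for the full benchmarking pipeline
#'
#' @param default_thresholds Named vector of the classifiers' published
#'   universal cutoffs (CHORD 0.5, HRDetect 0.7).
#' @param outer_k,inner_k Nested cross-validation fold counts.
#' @param bootstrap_replicates Bootstrap replicates for AUC intervals.
#' @param ci_method Proportion CI method, see [proportion_ci()].
#' @param level Confidence level.
#' @param seed Master integer seed for calibration and bootstrap.
#' @param fisher_alternative One-sided direction for the pairwise Fisher
#'   tests on unexplained counts across cancer types (for pair (g1, g2):
#'   odds of being unexplained in g1 relative to g2).
#' @param overlap_alternative One-sided direction for the overlap z-test
#'   comparing unexplained proportions (condition A = CHORD, B = HRDetect).
#' @return A named list of class `hrd_params`.
#' @export
hrd_params <- function(default_thresholds = c(chord = 0.5, hrdetect = 0.7),
                       outer_k = 10, inner_k = 10,
                       bootstrap_replicates = 2000,
                       ci_method = "wilson_cc", level = 0.95, seed = 1L,
                       fisher_alternative = "less",
                       overlap_alternative = "less") {
  out <- list(default_thresholds = default_thresholds, outer_k = outer_k,
              inner_k = inner_k, bootstrap_replicates = bootstrap_replicates,
              ci_method = ci_method, level = level, seed = as.integer(seed),
              fisher_alternative = fisher_alternative,
              overlap_alternative = overlap_alternative)
  class(out) <- "hrd_params"
  out
}

classifier_scores <- function(samples, classifier) {
  switch(classifier,
         chord = samples$chord_score,
         hrdetect = samples$hrdetect_score,
         stop("unknown classifier: ", classifier, call. = FALSE))
}

#' Evidence among HRD-classified samples, per cancer type and classifier
#'
#' For each cancer type and classifier, restricts to the samples called HRD
#' (score >= threshold) and counts those with and without biallelic
#' evidence, with confidence intervals on both proportions.
#'
#' @param evidence Labeled cohort from [label_cohort()].
#' @param samples Cohort data frame aligned to `evidence`.
#' @param thresholds Named vector of score cutoffs per classifier.
#' @param include_methylation Use `hrd_truth` (default) or
#'   `hrd_truth_no_meth` as the evidence flag.
#' @param ci_method,level Proportion CI settings.
#' @return Data frame, one row per classifier x cancer type: counts,
#'   percentage proportions and CI bounds; an empty stratum (no classified
#'   samples) has `NA` proportions.
#' @export
build_table1 <- function(evidence, samples,
                         thresholds = c(chord = 0.5, hrdetect = 0.7),
                         include_methylation = TRUE,
                         ci_method = "wilson_cc", level = 0.95) {
  stopifnot(identical(evidence$sample_id, samples$sample_id))
  truth <- if (include_methylation) evidence$hrd_truth else
    evidence$hrd_truth_no_meth
  rows <- list()
  for (cl in names(thresholds)) {
    sc <- classifier_scores(samples, cl)
    for (ct in unique(samples$cancer_type)) {
      in_ct <- samples$cancer_type == ct
      called <- in_ct & sc >= thresholds[[cl]]
      n_called <- sum(called)
      k <- sum(called & truth)
      if (n_called > 0) {
        ci_ev <- proportion_ci(k, n_called, ci_method, level)
        ci_no <- proportion_ci(n_called - k, n_called, ci_method, level)
        prop <- c(100 * k / n_called, 100 * ci_ev$lower, 100 * ci_ev$upper,
                  100 * (n_called - k) / n_called,
                  100 * ci_no$lower, 100 * ci_no$upper)
      } else {
        prop <- rep(NA_real_, 6)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = cl, cancer_type = ct, threshold = thresholds[[cl]],
        n_classified = n_called,
        evidence_count = k, evidence_pct = prop[1],
        evidence_ci_lower = prop[2], evidence_ci_upper = prop[3],
        no_evidence_count = n_called - k, no_evidence_pct = prop[4],
        no_evidence_ci_lower = prop[5], no_evidence_ci_upper = prop[6],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Confusion tables at default and calibrated thresholds
#'
#' Reproduces the layout of the benchmark's confusion-matrix summary: per
#' cancer type and classifier, the counts of HRD-classified samples with and
#' without biallelic evidence (tp / fp) and HRP-classified samples with and
#' without evidence (fn / tn), at both the default universal threshold and
#' the cancer-type-specific calibrated one, with accuracy.
#'
#' @param evidence Labeled cohort from [label_cohort()].
#' @param samples Aligned cohort data frame.
#' @param default_thresholds Named cutoffs per classifier.
#' @param calibration Data frame with columns `classifier`, `cancer_type`,
#'   `optimal_threshold` (e.g. assembled from [nested_cv_calibrate()] runs).
#' @param include_methylation Evidence flag selection, as in
#'   [build_table1()].
#' @return Data frame, one row per cancer type x classifier x threshold
#'   kind.
#' @export
build_table2 <- function(evidence, samples,
                         default_thresholds = c(chord = 0.5, hrdetect = 0.7),
                         calibration, include_methylation = TRUE) {
  stopifnot(identical(evidence$sample_id, samples$sample_id))
  truth <- if (include_methylation) evidence$hrd_truth else
    evidence$hrd_truth_no_meth
  rows <- list()
  for (cl in names(default_thresholds)) {
    sc <- classifier_scores(samples, cl)
    for (ct in unique(samples$cancer_type)) {
      in_ct <- samples$cancer_type == ct
      cal <- calibration[calibration$classifier == cl &
                           calibration$cancer_type == ct, , drop = FALSE]
      thr <- c(default = unname(default_thresholds[[cl]]),
               optimal = if (nrow(cal)) cal$optimal_threshold[1] else NA_real_)
      for (kind in names(thr)) {
        if (is.na(thr[[kind]])) next
        ctab <- confusion_at_threshold(sc[in_ct], truth[in_ct], thr[[kind]])
        rows[[length(rows) + 1L]] <- data.frame(
          cancer_type = ct, classifier = cl, threshold_kind = kind,
          threshold = thr[[kind]],
          tp = ctab$tp, fp = ctab$fp, fn = ctab$fn, tn = ctab$tn,
          accuracy = unname(table_metrics(ctab)["accuracy"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled sensitivity and unexplained proportions across cancer types
#'
#' Sums the confusion counts of [build_table2()] over cancer types and
#' reports, per classifier and threshold kind, the pooled sensitivity to
#' known biallelic events (tp / (tp + fn)) and the pooled proportion of
#' HRD-classified samples without evidence (fp / (tp + fp)), both as
#' percentages.
#'
#' @param table2 Output of [build_table2()].
#' @return Data frame per classifier x threshold kind with pooled counts and
#'   percentages; strata with no predicted positives yield `NA` rather than
#'   an error.
#' @export
pooled_summaries <- function(table2) {
  rows <- list()
  for (cl in unique(table2$classifier)) {
    for (kind in unique(table2$threshold_kind)) {
      t <- table2[table2$classifier == cl & table2$threshold_kind == kind, ]
      if (nrow(t) == 0) next
      tp <- sum(t$tp); fp <- sum(t$fp); fn <- sum(t$fn); tn <- sum(t$tn)
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = cl, threshold_kind = kind,
        evidence_total = tp + fn, classified_total = tp + fp,
        tp = tp, fp = fp, fn = fn, tn = tn,
        sensitivity_pct = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
        unexplained_pct = if (tp + fp > 0) 100 * fp / (tp + fp) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

eval_strata <- function(evidence, samples, params, include_methylation) {
  truth <- if (include_methylation) evidence$hrd_truth else
    evidence$hrd_truth_no_meth
  rows <- list()
  roc_pts <- list()
  pr_pts <- list()
  mode <- if (include_methylation) "with_methylation" else "no_methylation"
  for (cl in names(params$default_thresholds)) {
    sc <- classifier_scores(samples, cl)
    for (ct in unique(samples$cancer_type)) {
      i <- samples$cancer_type == ct
      if (!any(truth[i]) || all(truth[i])) next
      roc <- compute_roc(sc[i], truth[i],
                         ci_replicates = params$bootstrap_replicates,
                         seed = params$seed)
      pr <- compute_pr(sc[i], truth[i])
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = cl, cancer_type = ct, evidence_mode = mode,
        n = sum(i), n_pos = roc$n_pos,
        auc = roc$auc, auc_ci_lower = roc$ci[1], auc_ci_upper = roc$ci[2],
        auprc = pr$auprc, stringsAsFactors = FALSE)
      roc_pts[[length(roc_pts) + 1L]] <-
        cbind(classifier = cl, cancer_type = ct, evidence_mode = mode,
              roc$points, stringsAsFactors = FALSE)
      pr_pts[[length(pr_pts) + 1L]] <-
        cbind(classifier = cl, cancer_type = ct, evidence_mode = mode,
              pr$points, stringsAsFactors = FALSE)
    }
  }
  list(metrics = do.call(rbind, rows),
       roc_points = do.call(rbind, roc_pts),
       pr_points = do.call(rbind, pr_pts))
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full benchmarking analysis on a cohort
#'
#' Orchestrates the pipeline: validation, evidence labeling, ROC/PR
#' evaluation with and without methylation evidence, DeLong comparisons of
#' the two classifiers, nested-CV threshold calibration per cancer type,
#' the summary tables, pooled statistics, and the inferential block
#' (overlap z-test on unexplained proportions between classifiers, pairwise
#' Fisher tests across cancer types, Spearman correlation of the scores).
#' All randomness derives from `params$seed`; re-running with the same
#' inputs reproduces the report exactly.
#'
#' @param samples Cohort data frame ([read_cohort()] columns).
#' @param alterations Alteration data frame.
#' @param params [hrd_params()] settings.
#' @param outdir Optional directory; when given, writes `table1.tsv`,
#'   `table2.tsv`, `roc_points.tsv`, `pr_points.tsv`, `calibration.tsv`,
#'   `evidence.tsv` and `report.json`.
#' @return A list of class `hrd_report` with elements `validation`,
#'   `evidence_summary`, `evaluation`, `delong`, `calibration`, `table1`,
#'   `table1_no_meth`, `table2`, `pooled`, `stats`, `params`.
#' @export
run_full_analysis <- function(samples, alterations, params = hrd_params(),
                              outdir = NULL) {
  validation <- validate_cohort(samples, alterations)
  if (nrow(validation) > 0) {
    stop("cohort validation failed:\n",
         paste(sprintf("  [%s] %s", validation$issue, validation$detail),
               collapse = "\n"), call. = FALSE)
  }
  stage_log("validate", "cohort clean: %d samples, %d alteration rows",
            nrow(samples), nrow(alterations))

  evidence <- label_cohort(samples, alterations)
  ev_sum <- summarize_evidence(evidence)
  stage_log("label", "%d/%d samples with biallelic evidence (%d without methylation)",
            ev_sum$n_biallelic, ev_sum$n_samples, ev_sum$n_biallelic_no_meth)

  eval_meth <- eval_strata(evidence, samples, params, TRUE)
  eval_nometh <- eval_strata(evidence, samples, params, FALSE)
  evaluation <- rbind(eval_meth$metrics, eval_nometh$metrics)
  stage_log("evaluate", "%d strata evaluated (seed %d, %d bootstrap replicates)",
            nrow(evaluation), params$seed, params$bootstrap_replicates)

  delong <- do.call(rbind, lapply(unique(samples$cancer_type), function(ct) {
    i <- samples$cancer_type == ct
    if (!any(evidence$hrd_truth[i]) || all(evidence$hrd_truth[i])) return(NULL)
    d <- delong_paired_test(samples$chord_score[i], samples$hrdetect_score[i],
                            evidence$hrd_truth[i])
    data.frame(cancer_type = ct, auc_chord = d$auc_a, auc_hrdetect = d$auc_b,
               z = d$z, p = d$p, stringsAsFactors = FALSE)
  }))

  calibration <- list()
  for (cl in names(params$default_thresholds)) {
    sc <- classifier_scores(samples, cl)
    for (ct in unique(samples$cancer_type)) {
      i <- samples$cancer_type == ct
      truth_i <- evidence$hrd_truth[i]
      if (min(sum(truth_i), sum(!truth_i)) < params$outer_k) {
        stage_log("calibrate", "skipping %s/%s: too few samples per class",
                  cl, ct)
        next
      }
      cal <- nested_cv_calibrate(sc[i], truth_i, outer_k = params$outer_k,
                                 inner_k = params$inner_k, seed = params$seed)
      calibration[[length(calibration) + 1L]] <- data.frame(
        classifier = cl, cancer_type = ct,
        optimal_threshold = cal$optimal_threshold,
        mean_accuracy = cal$mean_accuracy,
        threshold_sd = stats::sd(cal$outer_thresholds),
        seed = cal$seed, stringsAsFactors = FALSE)
    }
  }
  calibration <- do.call(rbind, calibration)
  stage_log("calibrate", "%d classifier/cancer strata calibrated (%dx%d folds)",
            if (is.null(calibration)) 0L else nrow(calibration),
            params$outer_k, params$inner_k)

  table1 <- build_table1(evidence, samples, params$default_thresholds,
                         TRUE, params$ci_method, params$level)
  table1_nm <- build_table1(evidence, samples, params$default_thresholds,
                            FALSE, params$ci_method, params$level)
  table2 <- build_table2(evidence, samples, params$default_thresholds,
                         calibration)
  pooled <- pooled_summaries(table2)

  stats_block <- cohort_tests(evidence, samples, params)
  stage_log("report", "tables built; pooled evidence total %d",
            pooled$evidence_total[1])

  report <- list(validation = validation, evidence_summary = ev_sum,
                 evaluation = evaluation, delong = delong,
                 calibration = calibration,
                 table1 = table1, table1_no_meth = table1_nm,
                 table2 = table2, pooled = pooled, stats = stats_block,
                 params = unclass(params))
  class(report) <- "hrd_report"

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    wt <- function(df, name) utils::write.table(
      df, file.path(outdir, name), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(table1, "table1.tsv")
    wt(table2, "table2.tsv")
    wt(rbind(eval_meth$roc_points, eval_nometh$roc_points), "roc_points.tsv")
    wt(rbind(eval_meth$pr_points, eval_nometh$pr_points), "pr_points.tsv")
    if (!is.null(calibration)) wt(calibration, "calibration.tsv")
    write_evidence(evidence, file.path(outdir, "evidence.tsv"))
    jsonlite::write_json(
      report[c("evidence_summary", "evaluation", "delong", "calibration",
               "table1", "table1_no_meth", "table2", "pooled", "stats",
               "params")],
      file.path(outdir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  }
  report
}

# Inferential block: overlap z-test between classifiers on unexplained
# proportions among HRD-classified samples, pairwise Fisher across cancer
# types within each classifier, Spearman of the two scores.
cohort_tests <- function(evidence, samples, params) {
  thr <- params$default_thresholds
  called_a <- samples$chord_score >= thr[["chord"]]
  called_b <- samples$hrdetect_score >= thr[["hrdetect"]]
  unexp <- !evidence$hrd_truth
  both <- called_a & called_b
  oz <- overlap_z_test(paired_a = unexp[both], paired_b = unexp[both],
                       only_a = unexp[called_a & !called_b],
                       only_b = unexp[called_b & !called_a],
                       alternative = params$overlap_alternative)
  fisher <- lapply(names(thr), function(cl) {
    sc <- classifier_scores(samples, cl)
    called <- sc >= thr[[cl]]
    cts <- unique(samples$cancer_type)
    un <- vapply(cts, function(ct)
      sum(called & unexp & samples$cancer_type == ct), numeric(1))
    ex <- vapply(cts, function(ct)
      sum(called & !unexp & samples$cancer_type == ct), numeric(1))
    if (length(cts) < 2) return(NULL)
    cbind(classifier = cl,
          pairwise_fisher(un, ex, groups = cts,
                          alternative = params$fisher_alternative),
          stringsAsFactors = FALSE)
  })
  list(overlap_z = list(z = oz$z, p = oz$p,
                        unexplained_chord = oz$prop_a,
                        unexplained_hrdetect = oz$prop_b,
                        phi = oz$phi, degenerate = oz$degenerate,
                        alternative = params$overlap_alternative),
       pairwise_fisher = do.call(rbind, fisher),
       spearman = spearman_corr(samples$chord_score, samples$hrdetect_score))
}

#' @export
print.hrd_report <- function(x, ...) {
  cat("HRD benchmarking report\n")
  cat(sprintf("  samples: %d; biallelic evidence: %d (%d without methylation)\n",
              x$evidence_summary$n_samples, x$evidence_summary$n_biallelic,
              x$evidence_summary$n_biallelic_no_meth))
  cat(sprintf("  Spearman(CHORD, HRDetect) = %.3f\n", x$stats$spearman))
  cat("  pooled summaries:\n")
  p <- x$pooled
  for (i in seq_len(nrow(p))) {
    cat(sprintf("    %-9s %-8s sensitivity %5.1f%%  unexplained %5.1f%%\n",
                p$classifier[i], p$threshold_kind[i], p$sensitivity_pct[i],
                p$unexplained_pct[i]))
  }
  invisible(x)
}
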