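#!/usr/bin/env Rscript
# Stage 3: ROC / precision-recall evaluation of both classifiers per cancer
# type, with and without methylation evidence, with 2000-replicate
# stratified bootstrap AUC intervals and paired DeLong comparisons.

suppressPackageStartupMessages(library(hrdbench))

seed <- 20260922L
samples <- read_cohort("results/cohort/cohort.tsv")
alterations <- read_alterations("results/cohort/alterations.tsv")
evidence <- label_cohort(samples, alterations)

rows <- list()
for (cl in c("chord", "hrdetect")) {
  sc <- if (cl == "chord") samples$chord_score else samples$hrdetect_score
  for (ct in unique(samples$cancer_type)) {
    i <- samples$cancer_type == ct
    for (mode in c("with_methylation", "no_methylation")) {
      truth <- if (mode == "with_methylation") evidence$hrd_truth[i] else
        evidence$hrd_truth_no_meth[i]
      if (!any(truth) || all(truth)) next
      roc <- compute_roc(sc[i], truth, ci_replicates = 2000, seed = seed)
      pr <- compute_pr(sc[i], truth)
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = cl, cancer_type = ct, evidence_mode = mode,
        n = sum(i), n_pos = roc$n_pos, auc = roc$auc,
        auc_ci_lower = roc$ci[1], auc_ci_upper = roc$ci[2],
        auprc = pr$auprc)
    }
  }
}
metrics <- do.call(rbind, rows)
write.table(metrics, "results/classifier_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("AUC by stratum (95% bootstrap CI):\n")
for (i in seq_len(nrow(metrics))) {
  cat(sprintf("  %-9s %-9s %-17s AUC %.3f [%.3f, %.3f]  AUPRC %.3f\n",
              metrics$classifier[i], metrics$cancer_type[i],
              metrics$evidence_mode[i], metrics$auc[i],
              metrics$auc_ci_lower[i], metrics$auc_ci_upper[i],
              metrics$auprc[i]))
}

cat("\nDeLong paired comparisons (CHORD vs HRDetect, with methylation):\n")
for (ct in unique(samples$cancer_type)) {
  i <- samples$cancer_type == ct
  d <- delong_paired_test(samples$chord_score[i], samples$hrdetect_score[i],
                          evidence$hrd_truth[i])
  cat(sprintf("  %-9s AUC %.3f vs %.3f, z = %+.2f, p = %.3f\n",
              ct, d$auc_a, d$auc_b, d$z, d$p))
}

cat("\nMethylation ablation (drop in AUC when methylation evidence is removed):\n")
for (i in which(metrics$evidence_mode == "with_methylation")) {
  j <- which(metrics$classifier == metrics$classifier[i] &
               metrics$cancer_type == metrics$cancer_type[i] &
               metrics$evidence_mode == "no_methylation")
  if (length(j)) {
    cat(sprintf("  %-9s %-9s %.3f -> %.3f\n", metrics$classifier[i],
                metrics$cancer_type[i], metrics$auc[i], metrics$auc[j]))
  }
}
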