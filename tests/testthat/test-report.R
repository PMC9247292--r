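fixture_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- simulate_cohort(seed = 23)
      cache <<- list(
        cohort = co,
        evidence = label_cohort(co$samples, co$alterations),
        report = suppressMessages(run_full_analysis(
          co$samples, co$alterations,
          hrd_params(bootstrap_replicates = 100, seed = 23))))
    }
    cache
  }
})

test_that("table 1 proportions always equal their own count ratios", {
  fx <- fixture_report()
  t1 <- fx$report$table1
  expect_equal(t1$evidence_pct,
               100 * t1$evidence_count / t1$n_classified)
  expect_equal(t1$no_evidence_pct,
               100 * t1$no_evidence_count / t1$n_classified)
  expect_equal(t1$evidence_count + t1$no_evidence_count, t1$n_classified)
  expect_true(all(t1$evidence_ci_lower <= t1$evidence_pct &
                    t1$evidence_pct <= t1$evidence_ci_upper))

  # an empty stratum yields NA proportions, not a crash
  samples <- make_cohort_df(c("A", "B"), "breast", c(0.1, 0.2), c(0.1, 0.2))
  alts <- make_alts_df(c("A", "A"), "BRCA1", c("germline_pv", "loh"))
  ev <- label_cohort(samples, alts)
  t1_empty <- build_table1(ev, samples)
  expect_true(all(t1_empty$n_classified == 0))
  expect_true(all(is.na(t1_empty$evidence_pct)))
})

test_that("table 2 counts partition each cohort and match accuracies", {
  fx <- fixture_report()
  t2 <- fx$report$table2
  sizes <- table(fx$cohort$samples$cancer_type)
  for (i in seq_len(nrow(t2))) {
    expect_equal(t2$tp[i] + t2$fp[i] + t2$fn[i] + t2$tn[i],
                 unname(sizes[t2$cancer_type[i]]),
                 ignore_attr = TRUE)
  }
  expect_equal(t2$accuracy, (t2$tp + t2$tn) / (t2$tp + t2$fp + t2$fn + t2$tn))
  # optimal rows use the calibrated thresholds
  cal <- fx$report$calibration
  opt <- t2[t2$threshold_kind == "optimal", ]
  key <- paste(opt$classifier, opt$cancer_type)
  expect_equal(opt$threshold,
               cal$optimal_threshold[match(key, paste(cal$classifier,
                                                      cal$cancer_type))])
})

test_that("pooled summaries are sums of per-cancer counts", {
  fx <- fixture_report()
  t2 <- fx$report$table2
  pooled <- fx$report$pooled
  for (i in seq_len(nrow(pooled))) {
    sub <- t2[t2$classifier == pooled$classifier[i] &
                t2$threshold_kind == pooled$threshold_kind[i], ]
    expect_equal(pooled$tp[i], sum(sub$tp))
    expect_equal(pooled$evidence_total[i], sum(sub$tp) + sum(sub$fn))
    expect_equal(pooled$sensitivity_pct[i],
                 100 * sum(sub$tp) / (sum(sub$tp) + sum(sub$fn)))
    expect_equal(pooled$unexplained_pct[i],
                 100 * sum(sub$fp) / (sum(sub$tp) + sum(sub$fp)))
  }
  # no predicted positives: NA marker
  empty <- pooled_summaries(data.frame(
    classifier = "chord", threshold_kind = "default", cancer_type = "x",
    threshold = 2, tp = 0, fp = 0, fn = 5, tn = 95))
  expect_true(is.na(empty$unexplained_pct))
})

test_that("ablating methylation never increases explained counts or AUC", {
  fx <- fixture_report()
  t1 <- fx$report$table1
  t1_nm <- fx$report$table1_no_meth
  expect_true(all(t1_nm$evidence_count <= t1$evidence_count))

  ev <- fx$report$evaluation
  for (cl in unique(ev$classifier)) {
    for (ct in unique(ev$cancer_type)) {
      with_m <- ev$auc[ev$classifier == cl & ev$cancer_type == ct &
                         ev$evidence_mode == "with_methylation"]
      no_m <- ev$auc[ev$classifier == cl & ev$cancer_type == ct &
                       ev$evidence_mode == "no_methylation"]
      if (length(with_m) && length(no_m)) expect_lte(no_m, with_m + 1e-9)
    }
  }
})

test_that("the full analysis is reproducible and writes its artifacts", {
  co <- simulate_cohort(hrd_sim_config(
    n = c(breast = 150L, ovary = 60L),
    evidence_prevalence = c(breast = 0.25, ovary = 0.45),
    methylation_fraction = c(breast = 0.2, ovary = 0.2)), seed = 29)
  params <- hrd_params(bootstrap_replicates = 50, seed = 29)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- suppressMessages(run_full_analysis(co$samples, co$alterations,
                                           params, outdir = d1))
  r2 <- suppressMessages(run_full_analysis(co$samples, co$alterations,
                                           params, outdir = d2))
  expect_identical(r1[setdiff(names(r1), "params")],
                   r2[setdiff(names(r2), "params")])
  for (f in c("table1.tsv", "table2.tsv", "roc_points.tsv", "pr_points.tsv",
              "calibration.tsv", "evidence.tsv", "report.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # validation failures abort with a stage-tagged message
  bad <- co$samples
  bad$sample_id[2] <- bad$sample_id[1]
  expect_error(suppressMessages(
    run_full_analysis(bad, co$alterations, params)),
    "validation failed")
})

test_that("the statistical block carries the configured directions", {
  fx <- fixture_report()
  st <- fx$report$stats
  expect_equal(st$overlap_z$alternative, "less")
  expect_true(all(st$pairwise_fisher$p_adj >= st$pairwise_fisher$p,
                  na.rm = TRUE))
  expect_true(abs(st$spearman) <= 1)
  expect_equal(nrow(st$pairwise_fisher), 6)  # 3 pairs x 2 classifiers
})
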