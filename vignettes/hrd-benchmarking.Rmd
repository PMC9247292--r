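---
title: "Benchmarking HRD classifiers: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking HRD classifiers: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdbench)
```

This vignette is the package's own account of the science it implements:
the labeling model that defines genetic ground truth for homologous
recombination deficiency (HRD), the evaluation and calibration procedures,
the inferential toolkit, the synthetic data generator, and the places where
the design was genuinely open and a choice had to be made.

## 1. Ground truth: biallelic inactivation

HRD is caused by losing both copies of an HR gene (*BRCA1*, *BRCA2*,
*RAD51C*, *PALB2*, *XRCC2*, *RAD51B*, ...). The observable unit is a *hit*:
a germline pathogenic variant (GPV), a somatic mutation, loss of
heterozygosity (LOH), promoter hypermethylation, or a somatic homozygous
("deep") deletion. `classify_gene_hits()` maps the multiset of hits in one
gene of one tumor to a status:

| rule | status |
|---|---|
| deep deletion present | `biallelic_deep_deletion` |
| GPV + (LOH or somatic) | `biallelic_germline` |
| methylation + (somatic or LOH) | `biallelic_methylation` |
| somatic + LOH, or two somatic hits | `biallelic_somatic` |
| any remaining non-LOH mutation | `monoallelic` |
| otherwise (LOH alone, methylation alone, nothing) | `none` |

When several rules match, the highest-precedence status wins (deep deletion
> germline > methylation > somatic). A sample with any biallelic gene is
truly HR-deficient (`hrd_truth`); `hrd_truth_no_meth` repeats the call
after discarding methylation hits, emulating the common situation where
promoter methylation was never assayed.

Three boundary cases are not fully determined by the verbal definitions and
were fixed as package decisions:

* **Methylation alone** (no second hit) is `none`, not monoallelic:
  methylation is an epigenetic state, not a mutation, and the biallelic
  methylation rule explicitly requires a second hit.
* **GPV + methylation** with no LOH/somatic hit is `monoallelic`: neither
  biallelic rule fires, but a non-LOH mutation is present.
* **Two somatic hits** count as biallelic only when ingested as two rows;
  hit multiplicity is the only signal available for a second somatic allele.

"First hit / second hit" ordering cannot be recovered from a hit set, so
germline biallelic status is declared whenever a GPV co-occurs with LOH or
a somatic mutation. The full rule table over all 32 hit subsets is pinned
in the test suite against an independently written oracle.

## 2. Evaluating a continuous score

`compute_roc()` calls a sample positive when `score >= threshold`. The `>=`
convention was chosen so that the published CHORD cutoff of 0.5 calls a
score of exactly 0.5 HRD-positive; every confusion-table function accepts
`strict = TRUE` to switch to `>`. Thresholds sit at the unique observed
score values, and the AUC is computed by the Mann–Whitney mid-rank formula,
so ties contribute exactly ½ — the AUC is identical to exhaustive pair
counting, which the tests verify on every instance up to n = 50, and is
invariant under strictly monotone score transforms.

`compute_pr()` reports *average precision*: the sum over threshold steps of
precision times the recall increment. This step-wise rule was preferred
over nonlinear PR interpolation because it is exactly reproducible and
checkable against a dense threshold sweep (the tests require agreement
within 0.02); it can differ slightly from packages that interpolate.
An all-tied score vector correctly collapses to the positive prevalence,
the average precision of a baseline classifier.

`auc_bootstrap_ci()` resamples *within* each class (stratified bootstrap)
and reports the percentile interval over 2000 replicates by default.
Stratification matters here: the smallest stratum (ovary, n = 66, 30
positives) would otherwise occasionally yield single-class resamples with
an undefined AUC. Coverage is validated in the tests: on cohorts of n = 200
drawn from Beta(5, 2) vs Beta(2, 5) score distributions (analytic AUC
≈ 0.96 by numeric integration), the 95% interval covers the true AUC in
well over 90% of repeats. Percentile intervals are known to narrow
excessively when the AUC point estimate approaches 1 (few discordant
pairs); for near-perfect separation the interval honestly degenerates to
[1, 1].

`delong_paired_test()` implements the structural-components estimator for
two correlated AUCs: per-sample placement values, their empirical
covariance, and a two-sided normal p. When the variance of the AUC
difference is zero (identical scores) the test reports z = 0, p = 1 rather
than failing. The implementation is cross-checked in the tests against
pROC's independent implementation to 8 decimals.

## 3. Nested cross-validation for cancer-type-specific thresholds

The published universal cutoffs (CHORD 0.5, HRDetect 0.7) were not tuned
per cancer type. `nested_cv_calibrate()` re-derives a cutoff per cancer
type and classifier:

1. split the cohort into 10 outer stratified folds;
2. for each outer fold, split the remaining 90% into 10 inner stratified
   folds; fit the accuracy-optimal threshold on each inner-training portion
   by exhaustive sweep; average the 10 inner thresholds;
3. score that averaged threshold on the held-out outer fold;
4. report the mean of the 10 averaged thresholds and the mean held-out
   accuracy.

Open points fixed as package decisions:

* **Inner criterion = accuracy maximization** (Youden's J available via
  `criterion = "youden"`), consistent with how the benchmark's confusion
  tables are summarized. Under accuracy-on-train fitting the
  inner-validation portions are not separately used; the inner folds serve
  to average away the jitter of single-fit thresholds.
* **Candidate set** = midpoints between consecutive distinct scores plus
  one cutoff just below the minimum and one just above the maximum (half
  the smallest gap beyond the range): with k distinct scores, exactly k + 1
  candidates — every achievable confusion table, nothing else. A fixed grid
  would quantize the optimum.
* **Ties broken toward the smallest cutoff**, which maximizes sensitivity;
  in a clinical screening context a false negative (a missed HRD tumor) is
  the costlier error.
* **Folds are stratified by label and shuffled by a caller-supplied seed**;
  each class must contain at least `outer_k` samples, otherwise the
  calibration refuses with an explicit minimum-count message rather than
  silently producing single-class folds.

On synthetic cohorts with Beta(8, 2) vs Beta(2, 8) class scores (n = 400,
balanced), the calibrated threshold lands within ±0.1 of the density
crossing at 0.5 — the accuracy-optimal cutoff of the generative model,
computed independently by dense numeric sweep — and the held-out accuracy
shows no optimism against a fresh cohort of the same size beyond CV noise.

## 4. Inferential toolkit

**Proportion intervals.** The default is the continuity-corrected Wilson
score interval — the interval underlying `stats::prop.test` — which
reproduces the published cohort intervals exactly (5/34 → 5.5–31.8%;
69/76 → 81.4–95.9%); this identification was confirmed on both before
freezing the default. Plain Wilson and Clopper–Pearson are selectable.

**Partially overlapping samples z-test.** The sets of samples called HRD
by CHORD and by HRDetect overlap only partially, so comparing their
unexplained proportions is neither a paired nor an independent two-sample
problem. The statistic (Derrick et al. 2015, dichotomous-variables
variant) uses all samples and down-weights the pooled variance by the phi
correlation of the paired 2×2 block:

$$z = \frac{\hat p_1 - \hat p_2}
{\sqrt{\hat p(1-\hat p)\left(\tfrac1{n_1} + \tfrac1{n_2}
 - \tfrac{2\,\phi\, n_{12}}{n_1 n_2}\right)}}$$

With no paired samples it reduces algebraically to the classical pooled
two-proportion z-test (the tests verify exact equality with the
uncorrected chi-square statistic), and all-identical outcomes degenerate to
z = 0 with a flag. The normal-approximation p is validated against a
permutation reference that swaps conditions within pairs and reshuffles the
unpaired pool: with ~60 binary observations the permutation null is
discrete with steps of order 0.05, so agreement within 0.08 is the
attainable bound asserted; on larger cohorts the two converge.

**Fisher tests and multiplicity.** Pairwise one-sided Fisher exact tests
across cancer types within each classifier, Bonferroni-corrected over the
number of pairs (3 for three cancers). One-sided directions must be given
explicitly; the pipeline defaults encode the benchmark's claims (CHORD has
*fewer* unexplained cases than HRDetect; breast fewer than pancreas). The
implementation equals full hypergeometric enumeration on every table up to
n = 200 in the tests.

## 5. The synthetic cohort generator

The benchmark's per-sample scores and alteration calls exist only in
supplementary files, so `simulate_cohort()` generates cohorts with the
statistical structure the analysis depends on. Defaults
(`hrd_sim_config()`) are the study conditions:

| parameter | default | basis |
|---|---|---|
| cohort sizes | breast 371, ovary 66, pancreas 391 | stated cohort sizes |
| evidence prevalence | 78/371, 30/66, 55/391 | evidence-positive counts; pooled expectation 163 |
| unexplained fraction | 0.12 | pooled unexplained proportions at default cutoffs span 10.9–21.1%; 0.12 sits in that range |
| score model | Beta(8, 2) HRD / Beta(1, 12) HRP | bimodal scores concentrated near 1 and 0 |
| copula correlation | 0.32 | calibrated once so pooled Spearman(CHORD, HRDetect) ≈ 0.67 |
| methylation fraction | 0.21 breast/ovary, 0 pancreas | ≈23 pooled methylation events among ≈108 breast+ovary evidence events |
| mechanism mix | germline 0.78 / somatic 0.17 / deep deletion 0.05 | normalized event counts (106 germline, 23 somatic, 6 deep deletions) |
| methylation genes | BRCA1 0.9 / RAD51C 0.1 | methylation reported for BRCA1 and RAD51C only |
| monoallelic background | 0.03 per HRP sample | monoallelic hits are rare and concentrated in HRP tumors |

Mechanics: each sample draws an HR-deficiency state at the evidence
prevalence inflated by the unexplained fraction (so the *expected
evidence-positive* count matches the configured prevalence); both
classifier scores come from the state's Beta distribution through a shared
Gaussian latent (`copula_rho`), which preserves the Beta marginals while
inducing the rank correlation; HR-deficient samples not selected as
unexplained emit a biallelic pattern (gene by frequency, mechanism by mix,
second hit LOH-weighted); unexplained samples are *genuinely* HR-deficient
— high scores, no recorded evidence — matching the interpretation of
hidden causes rather than classifier false positives. Scores are written
with 6 decimals and re-parsed at generation time so TSV round trips are
bit-exact.

What the generator does **not** emulate: real mutational-signature
features (scores are simulated directly, not derived from genomes), any
dependence of the score on *which* gene is inactivated, classifier-specific
biases (both classifiers share one score model, so systematic
CHORD/HRDetect sensitivity differences seen on real data do not arise), the
seven minor cancer-type cohorts, and within-class score dispersion beyond
the Beta shapes, which are tuning knobs rather than estimates. Passing
tests on simulated cohorts therefore demonstrate the *machinery* —
labeling, evaluation, calibration and inference recover known generative
parameters — not the published per-cohort AUCs or optimal thresholds,
which require the original per-sample data.

## 6. Numerical choices and degenerate inputs

* Positive calls use `>=`; a one-line `strict` flag switches to `>`.
* Single-class label vectors are rejected as degenerate by ROC/PR/DeLong
  and calibration; confusion tables accept them (their metrics return `NA`
  markers for zero denominators instead of erroring).
* Equal-criterion threshold ties resolve to the smallest candidate;
  floating-point comparisons in the sweep use a 1e-12 slack.
* The overlap z-test returns z = 0 with a degenerate flag when the pooled
  variance vanishes; Fisher pairs with a zero-total group return `NA`.
* All randomness (simulation, folds, bootstrap) is driven by explicit
  integer seeds; identical seeds reproduce results byte-for-byte, and the
  report writer emits deterministic TSV/JSON.

## 7. Problem sizes used by the checks

The test suite and the analysis workflow run at the benchmark's own scale
(828 samples; tenfold-by-tenfold nested CV; 2000-replicate bootstraps in
the workflow, smaller replicate counts inside unit tests where only
determinism or coverage behavior is at stake; a 10^5-replicate permutation
reference for the overlap z-test). These sizes keep every oracle exhaustive
or well-resolved while the whole suite completes in well under a minute per
file.

## 8. Known limitations

* Upstream curation is out of scope: the package consumes alteration
  *calls* (pathogenicity, LOH, methylation already decided) and never reads
  VCF/MAF.
* Percentile bootstrap intervals undercover near AUC = 1; for strata with
  very few positives, Clopper–Pearson-style exact alternatives for the AUC
  are not provided.
* The overlap z-test relies on a normal approximation whose resolution is
  limited by the discreteness of small binary samples (see §4).
* Calibrated thresholds are only as transportable as the cohorts they were
  fit on; the nested-CV accuracy estimates generalization to samples from
  the *same* population, not to other sequencing pipelines — a caveat the
  benchmark itself emphasizes.
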