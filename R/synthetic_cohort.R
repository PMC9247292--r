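#' Simulation configuration for a paper-like HRD benchmarking cohort
#'
#' Returns the default study conditions emulated by the simulator: three
#' cancer-type cohorts (breast n = 371, ovary n = 66, pancreas n = 391)
#' with biallelic-evidence prevalences 78/371, 30/66 and 55/391 (so the
#' expected pooled evidence-positive count is 163); bimodal classifier
#' scores, Beta(8, 2) for HR-deficient and Beta(1, 12) for HR-proficient
#' tumors, coupled between the two classifiers through a Gaussian copula
#' with within-class latent correlation 0.32 so that the pooled Spearman
#' correlation of the two scores is about 0.67; methylation-driven biallelic
#' events (BRCA1/RAD51C) in breast and ovary only, at 21% of evidence
#' events (about 23 pooled methylation events); and a 12% fraction of
#' genuinely HR-deficient tumors carrying no recorded evidence
#' ("unexplained" cases).
#'
#' @param n Named integer vector of cohort sizes per cancer type.
#' @param evidence_prevalence Named vector: expected fraction of samples
#'   with biallelic evidence per cancer type.
#' @param methylation_fraction Named vector: fraction of biallelic evidence
#'   events that are methylation-driven, per cancer type.
#' @param unexplained_fraction Fraction of generatively HR-deficient tumors
#'   emitted with no alteration records.
#' @param shape_hrd,shape_hrp Beta shape pairs for the score distribution of
#'   HR-deficient and HR-proficient tumors.
#' @param copula_rho Within-class latent correlation of the Gaussian copula
#'   coupling the two classifier scores.
#' @param gene_freq Named vector of relative gene frequencies for evidence
#'   events (must sum to 1).
#' @param mechanism_mix Named vector (`germline`, `somatic`,
#'   `deep_deletion`): mix of non-methylation biallelic mechanisms.
#' @param methylation_genes Named vector of relative frequencies of
#'   methylation-eligible genes.
#' @param monoallelic_rate Per-sample probability of a background
#'   monoallelic hit in HR-proficient tumors.
#' @return Object of class `hrd_sim_config` (a validated list).
#' @export
hrd_sim_config <- function(
    n = c(breast = 371L, ovary = 66L, pancreas = 391L),
    evidence_prevalence = c(breast = 78 / 371, ovary = 30 / 66,
                            pancreas = 55 / 391),
    methylation_fraction = c(breast = 0.21, ovary = 0.21, pancreas = 0),
    unexplained_fraction = 0.12,
    shape_hrd = c(8, 2),
    shape_hrp = c(1, 12),
    copula_rho = 0.32,
    gene_freq = c(BRCA1 = 0.33, BRCA2 = 0.38, RAD51C = 0.12, PALB2 = 0.08,
                  XRCC2 = 0.05, RAD51B = 0.04),
    mechanism_mix = c(germline = 0.78, somatic = 0.17, deep_deletion = 0.05),
    methylation_genes = c(BRCA1 = 0.9, RAD51C = 0.1),
    monoallelic_rate = 0.03) {
  cfg <- list(n = n, evidence_prevalence = evidence_prevalence,
              methylation_fraction = methylation_fraction,
              unexplained_fraction = unexplained_fraction,
              shape_hrd = shape_hrd, shape_hrp = shape_hrp,
              copula_rho = copula_rho, gene_freq = gene_freq,
              mechanism_mix = mechanism_mix,
              methylation_genes = methylation_genes,
              monoallelic_rate = monoallelic_rate)
  stopifnot(
    length(n) >= 1, all(n >= 1),
    identical(names(evidence_prevalence), names(n)),
    identical(names(methylation_fraction), names(n)),
    all(evidence_prevalence >= 0 & evidence_prevalence <= 1),
    all(methylation_fraction >= 0 & methylation_fraction <= 1),
    unexplained_fraction >= 0, unexplained_fraction < 1,
    all(shape_hrd > 0), all(shape_hrp > 0),
    copula_rho >= 0, copula_rho <= 1,
    abs(sum(gene_freq) - 1) < 1e-8,
    abs(sum(mechanism_mix) - 1) < 1e-8,
    all(names(mechanism_mix) == c("germline", "somatic", "deep_deletion")),
    abs(sum(methylation_genes) - 1) < 1e-8,
    monoallelic_rate >= 0, monoallelic_rate <= 1)
  class(cfg) <- "hrd_sim_config"
  cfg
}

correlated_scores <- function(n, hrd, cfg) {
  z <- stats::rnorm(n)
  draw <- function() {
    u <- stats::pnorm(sqrt(cfg$copula_rho) * z +
                        sqrt(1 - cfg$copula_rho) * stats::rnorm(n))
    ifelse(hrd,
           stats::qbeta(u, cfg$shape_hrd[1], cfg$shape_hrd[2]),
           stats::qbeta(u, cfg$shape_hrp[1], cfg$shape_hrp[2]))
  }
  # 6-decimal scores, re-parsed so TSV writes round-trip bit-exactly
  six <- function(x) as.numeric(sprintf("%.6f", x))
  list(chord = six(draw()), hrdetect = six(draw()))
}

biallelic_pattern <- function(mechanism) {
  switch(mechanism,
    germline = c("germline_pv",
                 sample(c("loh", "somatic_mutation"), 1, prob = c(0.8, 0.2))),
    somatic = if (stats::runif(1) < 0.7) {
      c("somatic_mutation", "loh")
    } else {
      c("somatic_mutation", "somatic_mutation")
    },
    methylation = c("promoter_methylation",
                    sample(c("loh", "somatic_mutation"), 1,
                           prob = c(0.8, 0.2))),
    deep_deletion = "deep_deletion")
}

#' Simulate a benchmarking cohort
#'
#' Draws, for every sample: an HR-deficiency state from the generative
#' prevalence (evidence prevalence inflated by the unexplained fraction);
#' two coupled classifier scores from the state's Beta mixture; and, for
#' HR-deficient samples not selected as unexplained, a biallelic alteration
#' pattern (gene by frequency; germline+second hit, somatic+second hit,
#' methylation+second hit, or deep deletion by the configured mix).
#' HR-proficient samples receive single monoallelic hits at the background
#' rate. Scores are rounded to 6 decimals so that TSV round trips are exact.
#'
#' @param config An [hrd_sim_config()] object.
#' @param seed Integer seed; output is fully reproducible.
#' @return List of class `hrd_cohort` with data frames `samples`
#'   (`sample_id`, `cancer_type`, `chord_score`, `hrdetect_score`),
#'   `alterations` (`sample_id`, `gene`, `hit_class`), and `truth`
#'   (`sample_id`, `cancer_type`, `hrd`, `unexplained`).
#' @export
simulate_cohort <- function(config = hrd_sim_config(), seed = 1L) {
  stopifnot(inherits(config, "hrd_sim_config"))
  set.seed(seed)
  samples <- list(); truth <- list(); alts <- list()
  for (ct in names(config$n)) {
    n <- config$n[[ct]]
    prev_gen <- min(1, config$evidence_prevalence[[ct]] /
                      (1 - config$unexplained_fraction))
    hrd <- stats::runif(n) < prev_gen
    unexplained <- hrd & (stats::runif(n) < config$unexplained_fraction)
    sc <- correlated_scores(n, hrd, config)
    sid <- sprintf("%s_%04d", ct, seq_len(n))
    samples[[ct]] <- data.frame(sample_id = sid, cancer_type = ct,
                                chord_score = sc$chord,
                                hrdetect_score = sc$hrdetect,
                                stringsAsFactors = FALSE)
    truth[[ct]] <- data.frame(sample_id = sid, cancer_type = ct,
                              hrd = hrd, unexplained = unexplained,
                              stringsAsFactors = FALSE)
    mf <- config$methylation_fraction[[ct]]
    for (i in which(hrd & !unexplained)) {
      if (stats::runif(1) < mf) {
        gene <- sample(names(config$methylation_genes), 1,
                       prob = config$methylation_genes)
        pattern <- biallelic_pattern("methylation")
      } else {
        gene <- sample(names(config$gene_freq), 1, prob = config$gene_freq)
        mech <- sample(names(config$mechanism_mix), 1,
                       prob = config$mechanism_mix)
        pattern <- biallelic_pattern(mech)
      }
      alts[[length(alts) + 1L]] <-
        data.frame(sample_id = sid[i], gene = gene, hit_class = pattern,
                   stringsAsFactors = FALSE)
    }
    for (i in which(!hrd)) {
      if (stats::runif(1) < config$monoallelic_rate) {
        gene <- sample(names(config$gene_freq), 1, prob = config$gene_freq)
        alts[[length(alts) + 1L]] <-
          data.frame(sample_id = sid[i], gene = gene,
                     hit_class = "somatic_mutation", stringsAsFactors = FALSE)
      }
    }
  }
  alterations <- if (length(alts)) {
    do.call(rbind, alts)
  } else {
    data.frame(sample_id = character(0), gene = character(0),
               hit_class = character(0), stringsAsFactors = FALSE)
  }
  out <- list(samples = do.call(rbind, samples),
              alterations = alterations,
              truth = do.call(rbind, truth),
              config = config, seed = seed)
  rownames(out$samples) <- rownames(out$alterations) <- rownames(out$truth) <- NULL
  class(out) <- "hrd_cohort"
  out
}

#' @export
print.hrd_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d samples (%s), %d alteration rows, seed %d\n",
              nrow(x$samples),
              paste(sprintf("%s %d", names(x$config$n), x$config$n),
                    collapse = ", "),
              nrow(x$alterations), x$seed))
  invisible(x)
}

#' Write a simulated cohort as TSV fixtures
#'
#' Emits `cohort.tsv`, `alterations.tsv` and `truth.tsv` in the package's
#' TSV dialect; re-running with the same cohort overwrites to identical
#' bytes.
#'
#' @param cohort An `hrd_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixtures <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hrd_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(cohort = file.path(dir, "cohort.tsv"),
             alterations = file.path(dir, "alterations.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_cohort(cohort$samples, paths["cohort"])
  write_alterations(cohort$alterations, paths["alterations"])
  utils::write.table(cohort$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
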