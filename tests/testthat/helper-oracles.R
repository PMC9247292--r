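# Independent oracles used by the tests. These restate the definitions
# from first principles (exhaustive enumeration, numeric integration,
# permutation) and never call the code paths they check.

# AUC as the exhaustive pair-counting probability (ties count 1/2).
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) {
    for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Frozen rule table for gene-hit classification over all 2^5 hit subsets,
# derived by hand from the biallelic/monoallelic definitions. Keys are the
# sorted hit abbreviations pasted with "+": g = germline_pv, s =
# somatic_mutation, l = loh, m = promoter_methylation, d = deep_deletion.
classify_rule_table <- local({
  base <- c(
    "g" = "monoallelic", "s" = "monoallelic", "l" = "none", "m" = "none",
    "g+s" = "biallelic_germline", "g+l" = "biallelic_germline",
    "g+m" = "monoallelic",
    "l+s" = "biallelic_somatic", "m+s" = "biallelic_methylation",
    "l+m" = "biallelic_methylation",
    "g+l+s" = "biallelic_germline", "g+m+s" = "biallelic_germline",
    "g+l+m" = "biallelic_germline", "l+m+s" = "biallelic_methylation",
    "g+l+m+s" = "biallelic_germline")
  base <- c(base, setNames("none", ""))  # the empty hit set
  # every subset containing a deep deletion is biallelic by that deletion
  with_d <- setNames(rep("biallelic_deep_deletion", length(base)),
                     ifelse(names(base) == "", "d",
                            paste(names(base), "d", sep = "+")))
  names(with_d) <- vapply(strsplit(names(with_d), "+", fixed = TRUE),
                          function(x) paste(sort(x), collapse = "+"),
                          character(1))
  c(base, with_d)
})

hit_abbrev <- c(germline_pv = "g", somatic_mutation = "s", loh = "l",
                promoter_methylation = "m", deep_deletion = "d")

all_hit_subsets <- function() {
  out <- list()
  for (mask in 0:31) {
    out[[mask + 1]] <- hrdbench::hit_classes[bitwAnd(mask, 2^(0:4)) > 0]
  }
  out
}

# Average precision recomputed by a dense threshold sweep.
pr_grid_oracle <- function(scores, labels, grid_n = 5000) {
  labels <- as.logical(labels)
  thr <- sort(unique(c(seq(min(scores) - 1e-6, max(scores) + 1e-6,
                           length.out = grid_n), scores)),
              decreasing = TRUE)
  np <- sum(labels)
  rec_prev <- 0
  ap <- 0
  for (t in thr) {
    pred <- scores >= t
    if (!any(pred)) next
    rec <- sum(pred & labels) / np
    prec <- sum(pred & labels) / sum(pred)
    ap <- ap + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  ap
}

# One-sided Fisher p by full hypergeometric enumeration: probability of
# group-1 successes at least as large as observed, given all margins.
fisher_tail_oracle <- function(s1, f1, s2, f2,
                               alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  r1 <- s1 + f1
  r2 <- s2 + f2
  c1 <- s1 + s2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(lchoose(r1, support) + lchoose(r2, c1 - support) -
                 lchoose(r1 + r2, c1))
  if (alternative == "greater") sum(probs[support >= s1]) else
    sum(probs[support <= s1])
}

# Permutation reference for the partially overlapping samples z-test:
# exchanges conditions within each pair and reshuffles the unpaired pool,
# recomputing the statistic each time. Returns the mid-p tail probability.
perm_overlap_p <- function(pa, pb, oa, ob, replicates = 1e4,
                           alternative = "greater", seed = 1) {
  obs <- overlap_z_test(pa, pb, oa, ob, alternative)$z
  u <- c(oa, ob)
  nu <- length(u)
  na <- length(oa)
  n12 <- length(pa)
  set.seed(seed)
  zs <- numeric(replicates)
  for (r in seq_len(replicates)) {
    sw <- stats::runif(n12) < 0.5
    a2 <- ifelse(sw, pb, pa)
    b2 <- ifelse(sw, pa, pb)
    idx <- if (nu > 0) sample.int(nu, na) else integer(0)
    zs[r] <- overlap_z_test(a2, b2, u[idx], u[setdiff(seq_len(nu), idx)],
                            alternative)$z
  }
  side <- switch(alternative,
                 greater = mean(zs > obs + 1e-9),
                 less = mean(zs < obs - 1e-9),
                 two.sided = mean(abs(zs) > abs(obs) + 1e-9))
  side + 0.5 * mean(abs(zs - obs) < 1e-9)
}

# P(X > Y) for X ~ Beta(a1, b1), Y ~ Beta(a2, b2) by numeric integration.
beta_auc_analytic <- function(shape_pos, shape_neg) {
  stats::integrate(function(x) {
    stats::dbeta(x, shape_pos[1], shape_pos[2]) *
      stats::pbeta(x, shape_neg[1], shape_neg[2])
  }, 0, 1, rel.tol = 1e-10)$value
}

# Accuracy-optimal cutoff of two known Beta class densities by dense sweep.
bayes_cutoff_grid <- function(shape_pos, shape_neg, prevalence = 0.5,
                              grid_n = 20001) {
  t <- seq(0, 1, length.out = grid_n)
  err <- prevalence * stats::pbeta(t, shape_pos[1], shape_pos[2]) +
    (1 - prevalence) * (1 - stats::pbeta(t, shape_neg[1], shape_neg[2]))
  t[which.min(err)]
}

# Small deterministic cohort builders used across test files.
make_cohort_df <- function(ids, cancer, chord, hrdetect) {
  data.frame(sample_id = ids, cancer_type = cancer, chord_score = chord,
             hrdetect_score = hrdetect, stringsAsFactors = FALSE)
}

make_alts_df <- function(ids, genes, hits) {
  data.frame(sample_id = ids, gene = genes, hit_class = hits,
             stringsAsFactors = FALSE)
}
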