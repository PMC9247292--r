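#!/usr/bin/env Rscript
# Stage 2: derive HRD-truth labels from gene alterations.
#
# Each altered gene is classified as biallelic (germline+second hit,
# methylation+second hit, somatic+LOH or two somatic hits, deep deletion),
# monoallelic, or none; a sample is truly HR-deficient when any gene is
# biallelic. The no-methylation labels discard promoter-methylation hits
# first, emulating cohorts without methylation assays.

suppressPackageStartupMessages(library(hrdbench))

samples <- read_cohort("results/cohort/cohort.tsv")
alterations <- read_alterations("results/cohort/alterations.tsv")

issues <- validate_cohort(samples, alterations)
stopifnot(nrow(issues) == 0)

evidence <- label_cohort(samples, alterations)
write_evidence(evidence, "results/evidence.tsv")

s <- summarize_evidence(evidence)
cat(sprintf("%d/%d samples with biallelic evidence; %d remain without methylation\n",
            s$n_biallelic, s$n_samples, s$n_biallelic_no_meth))
agg <- aggregate(count ~ status, s$by_gene, sum)
for (i in seq_len(nrow(agg))) {
  cat(sprintf("  %-24s %d genes hit\n", agg$status[i], agg$count[i]))
}
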