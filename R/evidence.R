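#' Gene-level inactivation statuses, in decreasing precedence
#'
#' @export
gene_statuses <- c("biallelic_deep_deletion", "biallelic_germline",
                   "biallelic_methylation", "biallelic_somatic",
                   "monoallelic", "none")

biallelic_statuses <- gene_statuses[1:4]

#' Classify the hit set of one gene in one sample
#'
#' Applies the biallelic/monoallelic inactivation rules to the multiset of
#' hits observed in a single gene of a single tumor:
#'
#' * a deep (homozygous) deletion is biallelic by itself;
#' * a germline pathogenic variant with a second hit (LOH or somatic
#'   mutation) is germline biallelic inactivation;
#' * promoter methylation with a second hit (somatic mutation or LOH) is
#'   methylation-driven biallelic inactivation;
#' * a somatic mutation with LOH, or two somatic mutations, is somatic
#'   biallelic inactivation;
#' * any remaining mutation other than LOH (a lone germline variant or lone
#'   somatic mutation) is monoallelic;
#' * LOH alone, promoter methylation alone, or no hits at all give `none`.
#'
#' When several rules match, the status of highest precedence wins
#' (deep deletion > germline > methylation > somatic > monoallelic).
#' Multiplicity matters only for somatic mutations: two somatic rows for the
#' same gene count as two hits.
#'
#' @param hits Character vector of hit classes (see [hit_classes]); may
#'   contain repeats.
#' @return A single status string from [gene_statuses].
#' @export
classify_gene_hits <- function(hits) {
  stopifnot(all(hits %in% hit_classes))
  has <- function(x) x %in% hits
  if (has("deep_deletion")) return("biallelic_deep_deletion")
  second <- has("loh") || has("somatic_mutation")
  if (has("germline_pv") && second) return("biallelic_germline")
  if (has("promoter_methylation") && second) return("biallelic_methylation")
  if (has("somatic_mutation") &&
      (has("loh") || sum(hits == "somatic_mutation") >= 2)) {
    return("biallelic_somatic")
  }
  if (has("germline_pv") || has("somatic_mutation")) return("monoallelic")
  "none"
}

label_one_sample <- function(alts) {
  if (nrow(alts) == 0) {
    return(list(genes = data.frame(gene = character(0), status = character(0),
                                   status_no_meth = character(0),
                                   stringsAsFactors = FALSE),
                hrd_truth = FALSE, hrd_truth_no_meth = FALSE))
  }
  genes <- unique(alts$gene)
  status <- character(length(genes))
  status_nm <- character(length(genes))
  for (i in seq_along(genes)) {
    h <- alts$hit_class[alts$gene == genes[i]]
    status[i] <- classify_gene_hits(h)
    status_nm[i] <- classify_gene_hits(h[h != "promoter_methylation"])
  }
  list(genes = data.frame(gene = genes, status = status,
                          status_no_meth = status_nm, stringsAsFactors = FALSE),
       hrd_truth = any(status %in% biallelic_statuses),
       hrd_truth_no_meth = any(status_nm %in% biallelic_statuses))
}

#' Derive HRD-truth labels for one sample
#'
#' Classifies every altered gene independently and aggregates to per-sample
#' labels. `hrd_truth` is `TRUE` if any gene carries biallelic inactivation;
#' `hrd_truth_no_meth` repeats the call after discarding promoter-methylation
#' hits (so it can never be `TRUE` when `hrd_truth` is `FALSE`).
#'
#' @param alterations Alteration rows for a single sample (all sharing one
#'   `sample_id`).
#' @return A list with `sample_id`, `gene_evidence` (data frame gene/status/
#'   status_no_meth), `hrd_truth`, `hrd_truth_no_meth`.
#' @export
label_sample <- function(alterations) {
  sid <- unique(alterations$sample_id)
  if (length(sid) > 1) {
    stop("label_sample expects alterations for a single sample; got: ",
         paste(sid, collapse = ", "), call. = FALSE)
  }
  res <- label_one_sample(alterations)
  list(sample_id = if (length(sid)) sid else NA_character_,
       gene_evidence = res$genes,
       hrd_truth = res$hrd_truth,
       hrd_truth_no_meth = res$hrd_truth_no_meth)
}

#' Label a whole cohort with HRD-truth evidence
#'
#' @param samples Cohort data frame ([read_cohort()] columns).
#' @param alterations Alteration data frame ([read_alterations()] columns).
#' @return A data frame with one row per sample (input order): `sample_id`,
#'   `cancer_type`, `hrd_truth`, `hrd_truth_no_meth`, plus a `gene_evidence`
#'   attribute holding the per-gene status table (columns `sample_id`,
#'   `gene`, `status`, `status_no_meth`).
#' @export
label_cohort <- function(samples, alterations) {
  alt_split <- split(alterations, factor(alterations$sample_id,
                                         levels = unique(samples$sample_id)))
  hrd <- logical(nrow(samples))
  hrd_nm <- logical(nrow(samples))
  gene_tabs <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    alts <- alt_split[[sid]]
    if (is.null(alts)) alts <- alterations[0, , drop = FALSE]
    res <- label_one_sample(alts)
    hrd[i] <- res$hrd_truth
    hrd_nm[i] <- res$hrd_truth_no_meth
    if (nrow(res$genes) > 0) {
      gene_tabs[[i]] <- cbind(sample_id = sid, res$genes,
                              stringsAsFactors = FALSE)
    }
  }
  out <- data.frame(sample_id = samples$sample_id,
                    cancer_type = samples$cancer_type,
                    hrd_truth = hrd, hrd_truth_no_meth = hrd_nm,
                    stringsAsFactors = FALSE)
  ge <- do.call(rbind, gene_tabs[!vapply(gene_tabs, is.null, logical(1))])
  if (is.null(ge)) {
    ge <- data.frame(sample_id = character(0), gene = character(0),
                     status = character(0), status_no_meth = character(0),
                     stringsAsFactors = FALSE)
  }
  rownames(ge) <- NULL
  attr(out, "gene_evidence") <- ge
  out
}

#' Tabulate gene-level evidence by cancer type
#'
#' Cross-tabulates per-gene inactivation statuses by gene and cancer type and
#' reports per-sample biallelic totals.
#'
#' @param evidence Labeled cohort from [label_cohort()].
#' @return A list with `by_gene` (data frame cancer_type/gene/status/count),
#'   `n_samples`, `n_biallelic` (samples with any biallelic gene, i.e.
#'   `hrd_truth`), and `n_biallelic_no_meth`.
#' @export
summarize_evidence <- function(evidence) {
  ge <- attr(evidence, "gene_evidence")
  if (is.null(ge)) stop("evidence must come from label_cohort()", call. = FALSE)
  ct <- evidence$cancer_type[match(ge$sample_id, evidence$sample_id)]
  if (nrow(ge) > 0) {
    tab <- as.data.frame(table(cancer_type = ct, gene = ge$gene,
                               status = ge$status), stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, , drop = FALSE]
    names(tab)[names(tab) == "Freq"] <- "count"
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(cancer_type = character(0), gene = character(0),
                      status = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  }
  list(by_gene = tab,
       n_samples = nrow(evidence),
       n_biallelic = sum(evidence$hrd_truth),
       n_biallelic_no_meth = sum(evidence$hrd_truth_no_meth))
}

#' Write the per-sample evidence table
#'
#' Emits `sample_id`, `gene`, `status`, `hrd_truth`, `hrd_truth_no_meth`;
#' samples with no altered genes appear with gene `.` and status `none`.
#'
#' @param evidence Labeled cohort from [label_cohort()].
#' @param path Output TSV path.
#' @export
write_evidence <- function(evidence, path) {
  ge <- attr(evidence, "gene_evidence")
  idx <- match(evidence$sample_id, ge$sample_id)
  blank <- evidence$sample_id[!(evidence$sample_id %in% ge$sample_id)]
  out <- rbind(
    data.frame(sample_id = ge$sample_id, gene = ge$gene, status = ge$status,
               stringsAsFactors = FALSE),
    data.frame(sample_id = blank, gene = ".", status = "none",
               stringsAsFactors = FALSE))
  out$hrd_truth <- evidence$hrd_truth[match(out$sample_id, evidence$sample_id)]
  out$hrd_truth_no_meth <-
    evidence$hrd_truth_no_meth[match(out$sample_id, evidence$sample_id)]
  out <- out[order(match(out$sample_id, evidence$sample_id)), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
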