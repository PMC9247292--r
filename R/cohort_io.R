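#' Recognised gene-hit classes
#'
#' The five event types from which biallelic/monoallelic inactivation calls
#' are derived: germline pathogenic variant, somatic mutation, loss of
#' heterozygosity, promoter hypermethylation, and somatic homozygous (deep)
#' deletion.
#'
#' @export
hit_classes <- c("germline_pv", "somatic_mutation", "loh",
                 "promoter_methylation", "deep_deletion")

cohort_columns <- c("sample_id", "cancer_type", "chord_score", "hrdetect_score")
alteration_columns <- c("sample_id", "gene", "hit_class")

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s file %s is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[, required, drop = FALSE]
}

parse_score <- function(x, column, n_offset = 1L) {
  val <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(val) | val < 0 | val > 1)
  if (length(bad) > 0) {
    stop(sprintf("column %s: score out of [0,1] or unparseable at data row(s) %s",
                 column, paste(bad, collapse = ", ")), call. = FALSE)
  }
  val
}

#' Read a cohort table of classifier scores
#'
#' Reads a tab-separated file with columns `sample_id`, `cancer_type`,
#' `chord_score` and `hrdetect_score`. Scores must be finite probabilities in
#' \[0,1\]; cancer-type labels are lower-cased, arbitrary labels are accepted.
#'
#' @param path Path to a TSV file with a header row.
#' @return A data frame with one row per sample, in input order.
#' @export
read_cohort <- function(path) {
  df <- read_tsv_checked(path, cohort_columns, "cohort")
  df$cancer_type <- tolower(trimws(df$cancer_type))
  df$sample_id <- trimws(df$sample_id)
  df$chord_score <- parse_score(df$chord_score, "chord_score")
  df$hrdetect_score <- parse_score(df$hrdetect_score, "hrdetect_score")
  rownames(df) <- NULL
  df
}

#' Read a gene-alteration table
#'
#' Reads a tab-separated file with columns `sample_id`, `gene`, `hit_class`.
#' Hit classes are matched case-insensitively against [hit_classes].
#' Multiple rows for the same sample/gene/class are kept (multiplicity is
#' meaningful: two somatic hits in one gene constitute biallelic
#' inactivation).
#'
#' @param path Path to a TSV file with a header row.
#' @return A data frame with one row per alteration, in input order.
#' @export
read_alterations <- function(path) {
  df <- read_tsv_checked(path, alteration_columns, "alterations")
  df$sample_id <- trimws(df$sample_id)
  df$gene <- trimws(df$gene)
  hc <- tolower(trimws(df$hit_class))
  bad <- which(!(hc %in% hit_classes))
  if (length(bad) > 0) {
    stop(sprintf("unknown hit_class token(s) %s at data row(s) %s; allowed: %s",
                 paste(unique(df$hit_class[bad]), collapse = ", "),
                 paste(bad, collapse = ", "),
                 paste(hit_classes, collapse = ", ")), call. = FALSE)
  }
  df$hit_class <- hc
  rownames(df) <- NULL
  df
}

#' Write a cohort table
#'
#' @param samples Data frame as returned by [read_cohort()].
#' @param path Output TSV path.
#' @export
write_cohort <- function(samples, path) {
  utils::write.table(samples[, cohort_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene-alteration table
#'
#' @param alterations Data frame as returned by [read_alterations()].
#' @param path Output TSV path.
#' @export
write_alterations <- function(alterations, path) {
  utils::write.table(alterations[, alteration_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a paired cohort/alterations dataset
#'
#' Report-based validation: never throws. Flags duplicated sample ids,
#' alteration rows referring to unknown samples, and score-range violations.
#'
#' @param samples Cohort data frame (columns as [read_cohort()]).
#' @param alterations Alteration data frame (columns as [read_alterations()]).
#' @return A data frame with columns `issue`, `detail`; zero rows iff clean.
#' @export
validate_cohort <- function(samples, alterations) {
  issues <- list()
  dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
  for (d in dup) {
    issues[[length(issues) + 1L]] <-
      c("duplicate_sample_id", sprintf("sample_id '%s' appears %d times",
                                       d, sum(samples$sample_id == d)))
  }
  for (col in c("chord_score", "hrdetect_score")) {
    v <- samples[[col]]
    bad <- which(!is.finite(v) | v < 0 | v > 1)
    for (i in bad) {
      issues[[length(issues) + 1L]] <-
        c("score_out_of_range", sprintf("%s=%s for sample '%s' (row %d)",
                                        col, format(v[i]), samples$sample_id[i], i))
    }
  }
  orphan <- which(!(alterations$sample_id %in% samples$sample_id))
  for (i in orphan) {
    issues[[length(issues) + 1L]] <-
      c("orphan_alteration", sprintf("alteration row %d refers to unknown sample '%s'",
                                     i, alterations$sample_id[i]))
  }
  if (length(issues) == 0) {
    return(data.frame(issue = character(0), detail = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, issues)
  data.frame(issue = m[, 1], detail = m[, 2], stringsAsFactors = FALSE)
}
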