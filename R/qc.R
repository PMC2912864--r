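#' Per-SNP genotype call rate
#'
#' Fraction of enrolled subjects with a non-missing call at one SNP.  The
#' denominator is all subjects currently in the cohort (call rates are a
#' property of the genotyping run, so they are computed before any subject
#' filtering).
#'
#' @param x A `cohort`.
#' @param rsid SNP in the panel.
#' @return Fraction in \[0, 1\].
#' @export
snp_call_rate <- function(x, rsid) {
  stopifnot(inherits(x, "cohort"))
  j <- match(rsid, x$panel$rsid)
  if (is.na(j)) stop("unknown rsid: ", rsid, call. = FALSE)
  mean(!is.na(x$genotypes[, j]))
}

#' Remove subjects with too many missing genotypes
#'
#' Drops subjects whose missing-call count across the panel is at least
#' `min_missing_to_drop` (default 4, the threshold the calibration study
#' applied to its seven-SNP panel).  Remaining subjects keep their order and
#' data.
#'
#' @param x A `cohort`.
#' @param min_missing_to_drop Inclusive threshold, >= 1.
#' @return List with elements `cohort` (filtered) and `removed` (ids).
#' @export
drop_high_missingness_subjects <- function(x, min_missing_to_drop = 4L) {
  stopifnot(inherits(x, "cohort"), min_missing_to_drop >= 1)
  n_missing <- rowSums(is.na(x$genotypes))
  drop <- n_missing >= min_missing_to_drop
  list(cohort = .subset_cohort(x, !drop), removed = x$subjects$id[drop])
}

#' Ancestry-based inclusion filter
#'
#' Retains subjects whose West African ancestry fraction is at least
#' `min_ancestry` (inclusive, default 0.25 as in the calibration study's
#' inclusion criterion).
#'
#' @param x A `cohort`; every subject must have a non-missing ancestry.
#' @param min_ancestry Inclusive lower bound.
#' @return List with elements `cohort` and `removed`.
#' @export
ancestry_inclusion_filter <- function(x, min_ancestry = 0.25) {
  stopifnot(inherits(x, "cohort"))
  a <- x$subjects$ancestry
  if (anyNA(a))
    stop("missing ancestry for subject ",
         x$subjects$id[which(is.na(a))[1L]], call. = FALSE)
  drop <- a < min_ancestry
  list(cohort = .subset_cohort(x, !drop), removed = x$subjects$id[drop])
}

.subset_cohort <- function(x, keep) {
  cohort(x$panel, x$subjects[keep, , drop = FALSE],
         x$genotypes[keep, , drop = FALSE])
}

#' Concordance between duplicate genotyping runs
#'
#' Fraction of subject x SNP cells, non-missing in both runs, whose genotype
#' codes agree.  Used for duplicate-sample quality control.
#'
#' @param a,b Two `cohort` objects over the same subjects and panel.
#' @return Fraction in \[0, 1\].
#' @export
duplicate_concordance <- function(a, b) {
  stopifnot(inherits(a, "cohort"), inherits(b, "cohort"))
  if (!identical(a$panel$rsid, b$panel$rsid) ||
      !identical(a$subjects$id, b$subjects$id))
    stop("cohorts must share subjects and panel", call. = FALSE)
  both <- !is.na(a$genotypes) & !is.na(b$genotypes)
  if (!any(both)) stop("no cells are non-missing in both cohorts",
                       call. = FALSE)
  sum(a$genotypes[both] == b$genotypes[both]) / sum(both)
}

#' Quality-control report for a cohort
#'
#' Computes per-SNP call rates on the incoming cohort, then applies the
#' high-missingness subject filter, and reports both together.
#'
#' @param x A `cohort`.
#' @param min_missing_to_drop Passed to [drop_high_missingness_subjects()].
#' @return A `qc_report`: list with `call_rates` (named per rsid),
#'   `median_call_rate`, `removed_subject_ids`, and `cohort` (the filtered
#'   cohort).
#' @export
qc_report <- function(x, min_missing_to_drop = 4L) {
  stopifnot(inherits(x, "cohort"))
  cr <- vapply(x$panel$rsid, function(rs) snp_call_rate(x, rs), numeric(1))
  dropped <- drop_high_missingness_subjects(x, min_missing_to_drop)
  structure(list(call_rates = cr, median_call_rate = stats::median(cr),
                 removed_subject_ids = dropped$removed,
                 cohort = dropped$cohort),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n  call rates:\n")
  for (rs in names(x$call_rates))
    cat(sprintf("    %-12s %.3f\n", rs, x$call_rates[[rs]]))
  cat(sprintf("  median call rate: %.3f\n", x$median_call_rate))
  cat(sprintf("  subjects removed for missingness: %d\n",
              length(x$removed_subject_ids)))
  invisible(x)
}
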