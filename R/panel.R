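#' Define a SNP
#'
#' A SNP definition carries the rsID and its major/minor alleles.  Genotypes
#' are coded throughout the package as the number of minor alleles
#' (0 = homozygous major, 1 = heterozygous, 2 = homozygous minor, `NA` =
#' missing), so the allele assignment fixes the coding.
#'
#' @param rsid Non-empty rsID string.
#' @param major,minor Single-character nucleotides (A/C/G/T); must differ.
#' @return A one-row `data.frame` with columns `rsid`, `major`, `minor`.
#' @export
snp_def <- function(rsid, major, minor) {
  stopifnot(is.character(rsid), length(rsid) == 1L, nzchar(rsid))
  ok <- function(a) is.character(a) && length(a) == 1L && a %in% c("A", "C", "G", "T")
  if (!ok(major) || !ok(minor))
    stop("alleles must be single nucleotides A/C/G/T", call. = FALSE)
  if (major == minor) stop("major and minor allele must differ", call. = FALSE)
  data.frame(rsid = rsid, major = major, minor = minor,
             stringsAsFactors = FALSE)
}

#' Assemble a SNP panel
#'
#' @param ... One-row data frames from [snp_def()].
#' @return A `data.frame` of class `snp_panel`, one row per SNP.
#' @export
snp_panel <- function(...) {
  panel <- do.call(rbind, list(...))
  if (anyDuplicated(panel$rsid)) stop("duplicate rsid in panel", call. = FALSE)
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' The default seven-SNP 8q24 panel
#'
#' The seven 8q24 variants of the calibration study, with the major > minor
#' allele orientation used by its reference-genotype convention (e.g.
#' rs16901979 G > T, so G/G is genotype code 0).
#'
#' @return A `snp_panel` with seven rows.
#' @export
panel_8q24 <- function() {
  snp_panel(
    snp_def("rs6983561",  "A", "C"),
    snp_def("rs1447295",  "G", "T"),
    snp_def("rs4242384",  "A", "C"),
    snp_def("rs4242382",  "G", "A"),
    snp_def("rs11934905", "G", "A"),
    snp_def("rs16901979", "G", "T"),
    snp_def("rs10090154", "G", "A")
  )
}

#' Published genotype counts for the 8q24 calibration study
#'
#' Per-SNP genotype counts by case status from the published case-control
#' association table of the calibration study (195 prostate-cancer cases,
#' 531 controls of African descent).  These counts drive the default
#' synthetic-cohort configuration and the exact contingency-table checks.
#'
#' For rs11934905 the source table pools heterozygotes and rare-allele
#' homozygotes; the pooled carrier count is stored in the heterozygote cell
#' and the homozygote cell is zero (the analysis plan collapses this SNP, so
#' the split never enters a statistic).
#'
#' @return A named list (one entry per rsid) of 2x3 integer matrices with
#'   rows `case`, `control` and columns `g0`, `g1`, `g2` (minor-allele
#'   count coding).
#' @export
ref_counts_8q24 <- function() {
  m <- function(c0, c1, c2, k0, k1, k2)
    matrix(as.integer(c(c0, c1, c2, k0, k1, k2)), nrow = 2L, byrow = TRUE,
           dimnames = list(c("case", "control"), c("g0", "g1", "g2")))
  list(
    rs6983561  = m(48, 88, 50,   171, 232, 105),
    rs1447295  = m(86, 77, 26,   237, 221, 65),
    rs4242384  = m(122, 65, 6,   383, 120, 21),
    rs4242382  = m(85, 80, 28,   244, 191, 72),
    rs11934905 = m(173, 10, 0,   500, 21, 0),
    rs16901979 = m(45, 97, 50,   188, 237, 87),
    rs10090154 = m(124, 59, 6,   357, 131, 17)
  )
}
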