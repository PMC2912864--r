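#' Construct a cohort
#'
#' The central container of the pipeline: a SNP panel, a subject table
#' (id, case/control status, age, PSA, West African ancestry fraction) and a
#' subjects x SNPs genotype matrix in minor-allele-count coding (0/1/2,
#' `NA` = missing call).
#'
#' @param panel A `snp_panel` (see [snp_panel()]).
#' @param subjects A data.frame with columns `id`, `status` (values
#'   `"case"`/`"control"`), `age` (years), `psa` (ng/ml, may be `NA`) and
#'   `ancestry` (fraction in \[0,1\]).
#' @param genotypes Integer matrix, `nrow(subjects)` x `nrow(panel)`, values
#'   in `{0, 1, 2, NA}`.
#' @return An object of class `cohort`.
#' @export
cohort <- function(panel, subjects, genotypes) {
  stopifnot(inherits(panel, "snp_panel"), is.data.frame(subjects))
  req <- c("id", "status", "age", "psa", "ancestry")
  miss <- setdiff(req, names(subjects))
  if (length(miss)) stop("subjects lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  subjects$id <- as.character(subjects$id)
  if (anyDuplicated(subjects$id))
    stop("duplicate subject id: ",
         subjects$id[anyDuplicated(subjects$id)], call. = FALSE)
  if (!all(subjects$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'", call. = FALSE)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(subjects) || ncol(genotypes) != nrow(panel))
    stop("genotype matrix dimensions do not match subjects x panel",
         call. = FALSE)
  if (!all(genotypes %in% c(0L, 1L, 2L, NA)))
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  bad <- !is.na(subjects$ancestry) &
    (subjects$ancestry < 0 | subjects$ancestry > 1)
  if (any(bad)) stop("ancestry outside [0, 1] for subject ",
                     subjects$id[which(bad)[1L]], call. = FALSE)
  dimnames(genotypes) <- list(subjects$id, panel$rsid)
  structure(list(panel = panel, subjects = subjects, genotypes = genotypes),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- table(factor(x$subjects$status, c("case", "control")))
  cat(sprintf("<cohort> %d subjects (%d cases / %d controls), %d SNPs\n",
              nrow(x$subjects), n[["case"]], n[["control"]], nrow(x$panel)))
  cat("  panel:", paste(x$panel$rsid, collapse = " "), "\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotype fraction: %.3f\n", miss))
  invisible(x)
}

#' Number of subjects per status
#' @param x A `cohort`.
#' @return Named integer vector `c(case = ..., control = ...)`.
#' @export
status_counts <- function(x) {
  stopifnot(inherits(x, "cohort"))
  tab <- table(factor(x$subjects$status, c("case", "control")))
  c(case = unname(tab[["case"]]), control = unname(tab[["control"]]))
}

# map one genotype cell (code or allele pair) to an integer code
.parse_geno_cell <- function(cell, major, minor, missing_token, where) {
  if (is.na(cell) || cell == missing_token || cell == "") return(NA_integer_)
  if (cell %in% c("0", "1", "2")) return(as.integer(cell))
  chars <- strsplit(cell, "")[[1L]]
  chars <- chars[!chars %in% c("/", "|")]
  if (length(chars) != 2L || !all(chars %in% c(major, minor)))
    stop(sprintf("unparseable genotype '%s' at %s (alleles %s/%s)",
                 cell, where, major, minor), call. = FALSE)
  sum(chars == minor)
}

#' Read a cohort from a delimited table
#'
#' Expects a header row `subject_id status age psa ancestry <rsid>...`.
#' Genotype cells may be allele pairs (`"GT"`, `"T/G"`; order-insensitive),
#' integer codes 0/1/2, or the missing token.
#'
#' @param path File path.
#' @param panel Panel used to map allele pairs to codes and to fix column
#'   order; defaults to the rsID columns found in the header, in which case
#'   allele-pair cells are rejected (codes only).
#' @param sep Field delimiter (default tab).
#' @param missing Token denoting a missing genotype (default `"NA"`).
#' @return A [cohort()].
#' @export
read_cohort_table <- function(path, panel = NULL, sep = "\t", missing = "NA") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  req <- c("subject_id", "status", "age", "psa", "ancestry")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  rsids <- setdiff(names(df), req)
  if (is.null(panel)) {
    panel <- do.call(snp_panel, lapply(rsids, snp_def, major = "A", minor = "C"))
    codes_only <- TRUE
  } else {
    absent <- setdiff(panel$rsid, rsids)
    if (length(absent)) stop("panel SNPs absent from file: ",
                             paste(absent, collapse = ", "), call. = FALSE)
    rsids <- panel$rsid
    codes_only <- FALSE
  }
  bad_status <- !df$status %in% c("case", "control")
  if (any(bad_status))
    stop(sprintf("row %d: status '%s' not in {case, control}",
                 which(bad_status)[1L], df$status[which(bad_status)[1L]]),
         call. = FALSE)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject id: ", df$subject_id[anyDuplicated(df$subject_id)],
         call. = FALSE)
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == missing, NA, x)))
  subjects <- data.frame(
    id = df$subject_id, status = df$status,
    age = num(df$age), psa = num(df$psa), ancestry = num(df$ancestry),
    stringsAsFactors = FALSE)
  geno <- matrix(NA_integer_, nrow(df), length(rsids))
  for (j in seq_along(rsids)) {
    rs <- rsids[j]
    maj <- panel$major[panel$rsid == rs]
    mnr <- panel$minor[panel$rsid == rs]
    cells <- df[[rs]]
    for (i in seq_along(cells)) {
      if (codes_only && !(cells[i] %in% c("0", "1", "2", missing, "")))
        stop(sprintf("allele-pair genotype '%s' at row %d column %s requires a panel",
                     cells[i], i, rs), call. = FALSE)
      geno[i, j] <- .parse_geno_cell(cells[i], maj, mnr, missing,
                                     sprintf("row %d column %s", i, rs))
    }
  }
  cohort(panel, subjects, geno)
}

#' Write a cohort to a delimited table
#'
#' Inverse of [read_cohort_table()]; round-trips exactly.
#'
#' @param x A `cohort`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @param geno_format `"code"` writes 0/1/2; `"alleles"` writes allele pairs
#'   such as `"GT"`.
#' @param missing Token written for missing values.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(x, path, sep = "\t",
                               geno_format = c("code", "alleles"),
                               missing = "NA") {
  stopifnot(inherits(x, "cohort"))
  geno_format <- match.arg(geno_format)
  g <- x$genotypes
  out <- data.frame(subject_id = x$subjects$id, status = x$subjects$status,
                    age = x$subjects$age, psa = x$subjects$psa,
                    ancestry = x$subjects$ancestry, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(x$panel))) {
    rs <- x$panel$rsid[j]
    if (geno_format == "code") {
      col <- as.character(g[, j])
    } else {
      maj <- x$panel$major[j]; mnr <- x$panel$minor[j]
      col <- c(paste0(maj, maj), paste0(maj, mnr), paste0(mnr, mnr))[g[, j] + 1L]
    }
    col[is.na(col)] <- missing
    out[[rs]] <- col
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = missing)
  invisible(path)
}

#' Read a cohort from a VCF
#'
#' Reads diploid GT fields for the panel's sites (matched by the VCF `ID`
#' column) and codes genotypes by counting minor alleles; `./.` becomes
#' missing.  Multi-allelic records and records whose REF/ALT pair does not
#' match the panel's alleles are rejected.  Requires the
#' \pkg{VariantAnnotation} package.
#'
#' @param vcf_path Path to a VCF 4.x file.
#' @param status_map Named character vector mapping every VCF sample name to
#'   `"case"` or `"control"`.
#' @param panel A `snp_panel`; sites absent from the VCF yield an all-missing
#'   column with a warning.
#' @param covariates Optional data.frame with columns `id`, `age`, `psa`,
#'   `ancestry`; subjects without a row get `NA` covariates.
#' @return A [cohort()].
#' @export
read_vcf_cohort <- function(vcf_path, status_map, panel = panel_8q24(),
                            covariates = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf_cohort requires the VariantAnnotation package",
         call. = FALSE)
  vcf <- VariantAnnotation::readVcf(vcf_path)
  samples <- colnames(vcf)
  absent <- setdiff(samples, names(status_map))
  if (length(absent))
    stop("VCF samples absent from status_map: ",
         paste(absent, collapse = ", "), call. = FALSE)
  gt <- VariantAnnotation::geno(vcf)$GT
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_l <- VariantAnnotation::alt(vcf)
  rsid_row <- rownames(vcf)
  geno <- matrix(NA_integer_, length(samples), nrow(panel))
  for (j in seq_len(nrow(panel))) {
    rs <- panel$rsid[j]
    k <- which(rsid_row == rs)
    if (!length(k)) {
      warning("site ", rs, " absent from VCF; column set to missing")
      next
    }
    k <- k[1L]
    alts <- as.character(alt_l[[k]])
    if (length(alts) != 1L)
      stop("multi-allelic record at ", rs, " not supported", call. = FALSE)
    maj <- panel$major[j]; mnr <- panel$minor[j]
    if (ref[k] == maj && alts == mnr) {
      minor_is_alt <- TRUE
    } else if (ref[k] == mnr && alts == maj) {
      minor_is_alt <- FALSE
    } else {
      stop(sprintf("REF/ALT %s/%s at %s do not match panel alleles %s/%s",
                   ref[k], alts, rs, maj, mnr), call. = FALSE)
    }
    for (i in seq_along(samples)) {
      al <- strsplit(gt[k, i], "[/|]")[[1L]]
      if (length(al) != 2L || any(al == ".")) next
      n_alt <- sum(al == "1")
      geno[i, j] <- if (minor_is_alt) n_alt else 2L - n_alt
    }
  }
  subjects <- data.frame(id = samples,
                         status = unname(status_map[samples]),
                         age = NA_real_, psa = NA_real_, ancestry = NA_real_,
                         stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    m <- match(samples, covariates$id)
    for (v in intersect(c("age", "psa", "ancestry"), names(covariates)))
      subjects[[v]] <- covariates[[v]][m]
  }
  cohort(panel, subjects, geno)
}

#' Tabulate genotype counts for one SNP
#'
#' Builds the 2 (status) x 3 (genotype code) count table feeding every
#' association statistic.  Missing genotypes are excluded.
#'
#' @param x A `cohort`.
#' @param rsid SNP to tabulate; must be in the panel.
#' @param subset Optional status filter, `"case"` or `"control"` (the other
#'   row is then all zero).
#' @return A `geno_counts` object: list with elements `snp` (one panel row)
#'   and `counts` (2x3 integer matrix, rows `case`/`control`).
#' @export
count_genotypes <- function(x, rsid, subset = NULL) {
  stopifnot(inherits(x, "cohort"))
  j <- match(rsid, x$panel$rsid)
  if (is.na(j)) stop("unknown rsid: ", rsid, call. = FALSE)
  keep <- rep(TRUE, nrow(x$subjects))
  if (!is.null(subset)) {
    subset <- match.arg(subset, c("case", "control"))
    keep <- x$subjects$status == subset
  }
  counts <- matrix(0L, 2L, 3L,
                   dimnames = list(c("case", "control"), c("g0", "g1", "g2")))
  for (st in c("case", "control")) {
    g <- x$genotypes[keep & x$subjects$status == st, j]
    counts[st, ] <- tabulate(g[!is.na(g)] + 1L, 3L)
  }
  structure(list(snp = x$panel[j, , drop = FALSE], counts = counts),
            class = "geno_counts")
}

#' Wrap a hand-specified count matrix as a `geno_counts`
#'
#' Convenience for analyses that start from published count tables rather
#' than subject-level data.
#'
#' @param counts 2x3 matrix, rows case/control, columns genotype codes 0..2.
#' @param snp A one-row panel entry from [snp_def()].
#' @return A `geno_counts` object.
#' @export
geno_counts <- function(counts, snp) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 3L)), all(counts >= 0))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(c("case", "control"), c("g0", "g1", "g2"))
  structure(list(snp = snp, counts = counts), class = "geno_counts")
}

#' @export
print.geno_counts <- function(x, ...) {
  cat("<geno_counts>", x$snp$rsid, sprintf("(%s > %s)\n", x$snp$major, x$snp$minor))
  print(x$counts)
  invisible(x)
}
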