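# Builders for small deterministic cohorts used across the suite.

# cohort with hand-assigned genotypes; geno: n x p matrix (0/1/2/NA)
make_cohort <- function(status, geno, panel = NULL, ancestry = NULL,
                        age = NULL, psa = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  if (is.null(panel))
    panel <- do.call(snp_panel, lapply(seq_len(ncol(geno)), function(j)
      snp_def(sprintf("rs%04d", j), "A", "C")))
  subjects <- data.frame(
    id = sprintf("T%03d", seq_len(n)), status = status,
    age = if (is.null(age)) rep(60, n) else age,
    psa = if (is.null(psa)) ifelse(status == "case", 8, 1) else psa,
    ancestry = if (is.null(ancestry)) rep(0.8, n) else ancestry,
    stringsAsFactors = FALSE)
  cohort(panel, subjects, geno)
}

# cohort whose per-SNP genotype count tables exactly equal the given 2x3
# count matrices (one per panel SNP); per status, leftover subjects beyond a
# SNP's genotyped total are set missing at that SNP
cohort_from_counts <- function(counts_list, n_case, n_control,
                               panel = panel_8q24()) {
  stopifnot(length(counts_list) == nrow(panel))
  fill <- function(cnt_row, n) {
    g <- rep(0:2, cnt_row)
    c(g, rep(NA_integer_, n - length(g)))
  }
  geno <- sapply(seq_len(nrow(panel)), function(j) {
    m <- counts_list[[j]]
    c(fill(m["case", ], n_case), fill(m["control", ], n_control))
  })
  make_cohort(rep(c("case", "control"), c(n_case, n_control)), geno,
              panel = panel)
}

# cohort reproducing the published 8q24 genotype count tables exactly
ref_cohort_8q24 <- function() {
  cohort_from_counts(ref_counts_8q24(), 195, 531)
}

# joint-cell two-locus sampler for interaction tests: probs is a per-status
# list of 3x3 matrices over (gA, gB); extra null SNPs drawn from maf 0.3 HWE
sample_pair_cohort <- function(n_case, n_control, probs, n_null_snps = 2) {
  status <- rep(c("case", "control"), c(n_case, n_control))
  draw <- function(st, n) {
    cell <- sample(0:8, n, replace = TRUE, prob = as.vector(probs[[st]]))
    cbind(cell %% 3, cell %/% 3)
  }
  gAB <- rbind(draw("case", n_case), draw("control", n_control))
  maf <- 0.3
  hwe <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  gnull <- sapply(seq_len(n_null_snps), function(j)
    sample(0:2, n_case + n_control, replace = TRUE, prob = hwe))
  panel <- do.call(snp_panel, lapply(seq_len(2 + n_null_snps), function(j)
    snp_def(sprintf("rs%04d", j), "A", "C")))
  make_cohort(status, cbind(gAB, gnull), panel = panel)
}

# direct balanced accuracy from a 2x3 count matrix (independent of the MDR
# engine): label cells by case:control ratio vs the table's own ratio
ba_from_table <- function(m) {
  T0 <- sum(m["case", ]) / sum(m["control", ])
  ratio <- ifelse(m["control", ] > 0, m["case", ] / m["control", ], Inf)
  high <- ifelse(m["control", ] > 0, ratio >= T0, m["case", ] > 0)
  sens <- sum(m["case", high]) / sum(m["case", ])
  spec <- sum(m["control", !high]) / sum(m["control", ])
  (sens + spec) / 2
}
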