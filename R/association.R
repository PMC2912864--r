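#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio of a 2x2 exposure-by-status table with the Woolf
#' (log-OR +/- z * sqrt(sum of reciprocal cells)) interval.  When any cell
#' is zero the Haldane--Anscombe correction adds 0.5 to all four cells
#' before computing; a table with two zero cells in the same row or column
#' has an undefined OR and raises an error.
#'
#' @param a Exposed cases.
#' @param b Unexposed cases.
#' @param c Exposed controls.
#' @param d Unexposed controls.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric `c(or, lo, hi)`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d, conf = 0.95) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0))
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0))
    stop("odds ratio undefined: empty row or column", call. = FALSE)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(or = or, lo = exp(log(or) - z * se), hi = exp(log(or) + z * se))
}

#' Pearson chi-square test of homogeneity
#'
#' Tests whether the genotype distribution differs between cases and
#' controls, without continuity correction; columns that are empty in both
#' rows are dropped before computing degrees of freedom (a collapsed SNP's
#' 2x3 table with an all-zero homozygote column is tested as 2x2).
#'
#' @param tab A `geno_counts` object or a 2-row count matrix.
#' @return Named list `statistic`, `df`, `p`.
#' @export
chi_square_homogeneity <- function(tab) {
  m <- if (inherits(tab, "geno_counts")) tab$counts else as.matrix(tab)
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (any(rowSums(m) == 0) || ncol(m) < 2L)
    stop("degenerate table: empty row or fewer than two informative columns",
         call. = FALSE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Cochran--Armitage trend test
#'
#' Score test for a monotone dose effect of the minor-allele count on
#' case status, with ordinal genotype scores (default 0, 1, 2) and no
#' continuity correction.  `z^2` equals the 1-df score chi-square of the
#' ordinal logistic coding (the statistic of `stats::prop.trend.test`).
#'
#' @param tab A `geno_counts` object or 2x3 count matrix (rows case,
#'   control).
#' @param scores Ordinal genotype scores.
#' @return Named list `z`, `p` (two-sided, normal reference).
#' @export
cochran_armitage_trend <- function(tab, scores = c(0, 1, 2)) {
  m <- if (inherits(tab, "geno_counts")) tab$counts else as.matrix(tab)
  stopifnot(nrow(m) == 2L, ncol(m) == length(scores))
  cases <- m[1L, ]; totals <- colSums(m)
  N <- sum(totals); R <- sum(cases)
  if (N == 0 || R == 0 || R == N)
    stop("degenerate margins: need both cases and controls", call. = FALSE)
  pbar <- R / N
  u <- sum(scores * (cases - totals * pbar))
  v <- pbar * (1 - pbar) * (sum(totals * scores^2) - sum(totals * scores)^2 / N)
  if (v <= 0) stop("degenerate margins: no score variance", call. = FALSE)
  z <- u / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Define a genotype contrast
#'
#' A contrast pools one or both non-reference genotype codes against the
#' reference homozygote for a 2x2 odds-ratio comparison.
#'
#' @param name One of `"het_vs_ref"`, `"hom_vs_ref"`, `"dominant"`,
#'   `"collapsed"` (the rare-allele plan: carriers vs reference as the only
#'   contrast).
#' @return A `contrast` object with fields `name` and `exposed_codes`.
#' @export
contrast <- function(name = c("het_vs_ref", "hom_vs_ref", "dominant",
                              "collapsed")) {
  name <- match.arg(name)
  exposed <- switch(name, het_vs_ref = 1L, hom_vs_ref = 2L, c(1L, 2L))
  structure(list(name = name, exposed_codes = exposed), class = "contrast")
}

#' Crude association statistics for one SNP
#'
#' For each contrast, pools the exposed genotype codes against the
#' reference homozygote and computes the crude odds ratio with its Woolf
#' interval; adds the chi-square homogeneity p-value of the full table and,
#' unless the plan is collapsed-only, the Cochran--Armitage trend p-value.
#'
#' @param tab A `geno_counts` object.
#' @param contrasts List of [contrast()] objects; default the codominant +
#'   dominant plan.
#' @param conf Confidence level for the Woolf intervals.
#' @return An `assoc_result`: list with `rsid`, `table` (a data.frame of
#'   per-contrast estimates), `p_homogeneity`, `p_trend` (`NA` for a
#'   collapsed-only plan).
#' @export
genotype_association <- function(tab,
                                 contrasts = list(contrast("het_vs_ref"),
                                                  contrast("hom_vs_ref"),
                                                  contrast("dominant")),
                                 conf = 0.95) {
  stopifnot(inherits(tab, "geno_counts"))
  m <- tab$counts
  if (sum(m["case", ]) == 0 || sum(m["control", ]) == 0)
    stop("need at least one case and one control", call. = FALSE)
  rows <- lapply(contrasts, function(ct) {
    exp_idx <- ct$exposed_codes + 1L
    a <- sum(m["case", exp_idx]);    b <- m["case", 1L]
    cc <- sum(m["control", exp_idx]); d <- m["control", 1L]
    est <- odds_ratio_2x2(a, b, cc, d, conf)
    p2x2 <- chi_square_homogeneity(rbind(c(b, a), c(d, cc)))$p
    data.frame(contrast = ct$name, n_case = a, n_control = cc,
               or = est[["or"]], lo = est[["lo"]], hi = est[["hi"]],
               p = p2x2, stringsAsFactors = FALSE)
  })
  collapsed_only <- length(contrasts) == 1L &&
    contrasts[[1L]]$name == "collapsed"
  p_trend <- if (collapsed_only) NA_real_ else cochran_armitage_trend(m)$p
  structure(list(rsid = tab$snp$rsid, table = do.call(rbind, rows),
                 p_homogeneity = chi_square_homogeneity(m)$p,
                 p_trend = p_trend),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("<assoc_result>", x$rsid, "\n")
  tb <- x$table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  %-10s OR %.2f (%.2f - %.2f)\n",
                tb$contrast[i], tb$or[i], tb$lo[i], tb$hi[i]))
  cat(sprintf("  p(homogeneity) = %.4f", x$p_homogeneity))
  if (!is.na(x$p_trend)) cat(sprintf("  p(trend) = %.4f", x$p_trend))
  cat("\n")
  invisible(x)
}

#' Covariate-adjusted logistic regression for one SNP
#'
#' Unconditional maximum-likelihood logistic regression of case status on a
#' genotype coding plus covariates, fitted by iteratively reweighted least
#' squares (epsilon 1e-10, at most 100 iterations).  Adjusted odds ratios
#' are `exp(coefficient)` with Wald intervals from the observed information.
#' Complete-case rows only.
#'
#' @param x A `cohort`.
#' @param rsid SNP in the panel.
#' @param coding `"dominant"` (carrier indicator), `"codominant"` (separate
#'   indicators for codes 1 and 2) or `"ordinal"` (minor-allele count).
#' @param covariates Character subset of `c("age", "ancestry", "psa")`.
#'   Default age + ancestry, the adjustment set the calibration study used
#'   in its reported models.
#' @param conf Confidence level for Wald intervals.
#' @return A data.frame, one row per genotype term: `term`, `or`, `lo`,
#'   `hi`, `p`.
#' @export
logistic_fit <- function(x, rsid,
                         coding = c("dominant", "codominant", "ordinal"),
                         covariates = c("age", "ancestry"), conf = 0.95) {
  stopifnot(inherits(x, "cohort"))
  coding <- match.arg(coding)
  if (length(covariates))
    covariates <- match.arg(covariates, c("age", "ancestry", "psa"),
                            several.ok = TRUE)
  j <- match(rsid, x$panel$rsid)
  if (is.na(j)) stop("unknown rsid: ", rsid, call. = FALSE)
  g <- x$genotypes[, j]
  df <- data.frame(y = as.integer(x$subjects$status == "case"))
  terms <- switch(coding,
    dominant  = {df$g_dom <- as.integer(g >= 1L); "g_dom"},
    ordinal   = {df$g_ord <- as.numeric(g); "g_ord"},
    codominant = {
      df$g_het <- as.integer(g == 1L); df$g_hom <- as.integer(g == 2L)
      c("g_het", "g_hom")
    })
  for (v in covariates) df[[v]] <- x$subjects[[v]]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < ncol(df) + 1L)
    stop("too few complete-case rows for the requested model", call. = FALSE)
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  if (!fit$converged)
    stop("logistic fit did not converge for ", rsid, call. = FALSE)
  if (any(abs(stats::coef(fit)[terms]) > 15))
    stop("separation suspected for ", rsid,
         " (genotype coefficient diverges)", call. = FALSE)
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- lapply(terms, function(tm) {
    est <- sm[tm, "Estimate"]; se <- sm[tm, "Std. Error"]
    data.frame(term = tm, or = exp(est), lo = exp(est - z * se),
               hi = exp(est + z * se), p = sm[tm, "Pr(>|z|)"],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# contrast plan per SNP: collapse to carriers-vs-reference when the
# rare-homozygote cell is nearly empty (the published plan for rs11934905)
.contrast_plan <- function(counts, collapse_min_hom = 5L) {
  if (sum(counts[, 3L]) < collapse_min_hom) list(contrast("collapsed"))
  else list(contrast("het_vs_ref"), contrast("hom_vs_ref"),
            contrast("dominant"))
}

#' Association analysis of every SNP in the panel
#'
#' Applies the study's contrast plan SNP by SNP: codominant plus dominant
#' contrasts in general, carriers-vs-reference only when the rare-allele
#' homozygote count is below `collapse_min_hom` (then the trend test is
#' omitted).  Crude estimates come from the contingency table; adjusted
#' estimates from [logistic_fit()] with the given covariates.
#'
#' @param x A `cohort` that already passed QC.
#' @param covariates Adjustment set for the logistic models (default
#'   age + ancestry); `character(0)` skips adjusted models.
#' @param collapse_min_hom Collapse threshold on the total rare-homozygote
#'   count.
#' @param conf Confidence level.
#' @return A data.frame with one row per SNP x contrast: counts, crude OR
#'   and CI, adjusted OR and CI (NA when not fitted), homogeneity and trend
#'   p-values (repeated within SNP).
#' @export
analyze_all_snps <- function(x, covariates = c("age", "ancestry"),
                             collapse_min_hom = 5L, conf = 0.95) {
  stopifnot(inherits(x, "cohort"))
  out <- list()
  for (rs in x$panel$rsid) {
    tab <- count_genotypes(x, rs)
    plan <- .contrast_plan(tab$counts, collapse_min_hom)
    res <- genotype_association(tab, plan, conf)
    adj <- NULL
    fit_one <- function(coding) tryCatch(
      logistic_fit(x, rs, coding, covariates, conf),
      error = function(e) NULL)
    collapsed <- length(plan) == 1L
    adj_dom <- fit_one("dominant")
    adj_cod <- if (!collapsed) fit_one("codominant") else NULL
    pick_adj <- function(ct_name) {
      src <- switch(ct_name,
        het_vs_ref = if (!is.null(adj_cod)) adj_cod[adj_cod$term == "g_het", ],
        hom_vs_ref = if (!is.null(adj_cod)) adj_cod[adj_cod$term == "g_hom", ],
        adj_dom)  # dominant and collapsed share the carrier indicator
      if (is.null(src) || !nrow(src))
        data.frame(or = NA_real_, lo = NA_real_, hi = NA_real_, p = NA_real_)
      else src[, c("or", "lo", "hi", "p")]
    }
    for (i in seq_len(nrow(res$table))) {
      ct <- res$table$contrast[i]
      aj <- pick_adj(ct)
      out[[length(out) + 1L]] <- data.frame(
        rsid = rs, contrast = ct,
        n_case = res$table$n_case[i], n_control = res$table$n_control[i],
        or_crude = res$table$or[i], lo_crude = res$table$lo[i],
        hi_crude = res$table$hi[i], p_crude = res$table$p[i],
        or_adj = aj$or, lo_adj = aj$lo, hi_adj = aj$hi, p_adj = aj$p,
        p_homogeneity = res$p_homogeneity, p_trend = res$p_trend,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
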