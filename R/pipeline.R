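#' Summarize a cohort (demographics table)
#'
#' Per-status medians and ranges for age, PSA and ancestry, PSA strata
#' counts (< 2.0, 2.0--4.0 inclusive, > 4.0 ng/ml) and two-sample
#' Wilcoxon rank-sum p-values for the case/control location difference.
#'
#' @param x A nonempty `cohort`.
#' @return A `cohort_summary`: list with `n` (per status), `age`, `psa`,
#'   `ancestry` (each a per-status list of `median`, `min`, `max` and a
#'   joint `p`), and `psa_strata` (2x3 count matrix).
#' @export
summarize_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"), nrow(x$subjects) >= 1)
  st <- x$subjects$status
  one_var <- function(v) {
    by_st <- lapply(c(case = "case", control = "control"), function(s) {
      vv <- v[st == s & !is.na(v)]
      if (!length(vv)) return(list(median = NA_real_, min = NA_real_,
                                   max = NA_real_))
      list(median = stats::median(vv), min = min(vv), max = max(vv))
    })
    p <- if (all(c("case", "control") %in% st) &&
             sum(!is.na(v[st == "case"])) > 0 &&
             sum(!is.na(v[st == "control"])) > 0)
      suppressWarnings(stats::wilcox.test(v[st == "case"],
                                          v[st == "control"])$p.value)
    else NA_real_
    c(by_st, list(p = p))
  }
  psa <- x$subjects$psa
  strata <- function(s) {
    v <- psa[st == s & !is.na(psa)]
    c(`<2.0` = sum(v < 2), `2.0-4.0` = sum(v >= 2 & v <= 4),
      `>4.0` = sum(v > 4))
  }
  structure(list(
    n = c(case = sum(st == "case"), control = sum(st == "control")),
    age = one_var(x$subjects$age),
    psa = one_var(psa),
    ancestry = one_var(x$subjects$ancestry),
    psa_strata = rbind(case = strata("case"), control = strata("control"))),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d cases / %d controls\n",
              x$n[["case"]], x$n[["control"]]))
  row <- function(nm, v)
    cat(sprintf("  %-9s case %.3f (%.3f-%.3f)  control %.3f (%.3f-%.3f)  p=%.4g\n",
                nm, v$case$median, v$case$min, v$case$max,
                v$control$median, v$control$min, v$control$max, v$p))
  row("age", x$age); row("psa", x$psa); row("ancestry", x$ancestry)
  invisible(x)
}

#' Configure a full pipeline run
#'
#' @param input Either a file path to a cohort table or a [sim_config()].
#' @param out_dir Output directory for report files.
#' @param panel Panel used when reading a file input.
#' @param min_missing_to_drop,min_ancestry QC thresholds.
#' @param covariates Adjustment set for logistic models.
#' @param mdr_max_order,mdr_k,mdr_B MDR parameters.
#' @param seed Master seed propagated to every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir, panel = panel_8q24(),
                            min_missing_to_drop = 4L, min_ancestry = 0.25,
                            covariates = c("age", "ancestry"),
                            mdr_max_order = 1L, mdr_k = 10L, mdr_B = 1000L,
                            seed = 1L) {
  if (!(is.character(input) || inherits(input, "sim_config")))
    stop("input must be a file path or a sim_config", call. = FALSE)
  structure(list(input = input, out_dir = out_dir, panel = panel,
                 min_missing_to_drop = min_missing_to_drop,
                 min_ancestry = min_ancestry, covariates = covariates,
                 mdr_max_order = mdr_max_order, mdr_k = mdr_k,
                 mdr_B = mdr_B, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline: load/simulate, QC, association, MDR
#'
#' Stages run in order; per-stage subject counts are logged via `message()`.
#' Writes `cohort.tsv`, `qc.tsv`, `association.tsv` and `mdr.tsv` under the
#' output directory and returns everything as a report object.
#'
#' @param config A [pipeline_config()].
#' @return A `study_report`: list with `summary`, `qc`, `association`
#'   (data.frame), `mdr` (`mdr_result`), `counts_log` and `provenance`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  coh <- if (inherits(config$input, "sim_config"))
    simulate_cohort(config$input, seed = config$seed)
  else read_cohort_table(config$input, panel = config$panel)
  log <- c(loaded = nrow(coh$subjects))
  message("[load] ", nrow(coh$subjects), " subjects")

  qc <- qc_report(coh, config$min_missing_to_drop)
  coh <- qc$cohort
  anc <- ancestry_inclusion_filter(coh, config$min_ancestry)
  coh <- anc$cohort
  log <- c(log, after_missingness = nrow(qc$cohort$subjects),
           after_ancestry = nrow(coh$subjects))
  message("[qc] removed ", length(qc$removed_subject_ids),
          " high-missingness and ", length(anc$removed),
          " low-ancestry subjects; ", nrow(coh$subjects), " remain")

  assoc <- analyze_all_snps(coh, covariates = config$covariates)
  message("[assoc] ", length(unique(assoc$rsid)), " SNPs analyzed")
  mdr <- run_mdr(coh, max_order = config$mdr_max_order, k = config$mdr_k,
                 B = config$mdr_B, seed = config$seed)
  message("[mdr] best model ", paste(mdr$best$loci, collapse = "+"),
          sprintf(" (CVC %d/%d, ATA %.3f)", mdr$best$cvc, mdr$k,
                  mdr$best$ata))

  write_cohort_table(coh, file.path(config$out_dir, "cohort.tsv"))
  utils::write.table(
    data.frame(rsid = names(qc$call_rates), call_rate = qc$call_rates),
    file.path(config$out_dir, "qc.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(assoc, file.path(config$out_dir, "association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mdr_tab <- data.frame(
    model = vapply(mdr$candidates, function(cd)
      paste(cd$loci, collapse = "+"), character(1)),
    cvc = sprintf("%d/%d",
                  as.integer(vapply(mdr$candidates, `[[`, numeric(1), "cvc")),
                  as.integer(mdr$k)),
    ata = vapply(mdr$candidates, `[[`, numeric(1), "ata"),
    stringsAsFactors = FALSE)
  utils::write.table(mdr_tab, file.path(config$out_dir, "mdr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  structure(list(summary = summarize_cohort(coh), qc = qc,
                 association = assoc, mdr = mdr, counts_log = log,
                 provenance = list(seed = config$seed,
                                   version = as.character(
                                     utils::packageVersion("snpmdr")))),
            class = "study_report")
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort TSV), `qc`, `assoc`,
#' `mdr` (each read a cohort TSV and write a report TSV), and `run` (full
#' pipeline).  Invoke as `snpmdr_main(c("simulate", "--seed", "7",
#' "--out", "cohort.tsv"))` or from `Rscript` via the installed
#' `exec/snpmdr` script.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the subcommand's result object.
#' @export
snpmdr_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: snpmdr <simulate|qc|assoc|mdr|run> [--in FILE] [--out PATH] [--seed N] [--max-order N] [--folds N] [--permutations N]"
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[[1L]]
  opt <- list(`in` = NULL, out = "snpmdr_out", seed = 1L,
              `max-order` = 1L, folds = 10L, permutations = 1000L)
  rest <- args[-1L]
  while (length(rest)) {
    key <- sub("^--", "", rest[[1L]])
    if (!key %in% names(opt) || length(rest) < 2L)
      stop(usage, call. = FALSE)
    opt[[key]] <- rest[[2L]]
    rest <- rest[-(1:2)]
  }
  seed <- as.integer(opt$seed)
  need_in <- function() {
    if (is.null(opt$`in`)) stop("subcommand requires --in FILE", call. = FALSE)
    read_cohort_table(opt$`in`, panel = panel_8q24())
  }
  res <- switch(cmd,
    simulate = {
      coh <- simulate_cohort(default_sim_config(seed))
      write_cohort_table(coh, opt$out)
      message("wrote ", opt$out)
      coh
    },
    qc = {
      rep <- qc_report(need_in())
      print(rep)
      rep
    },
    assoc = {
      tab <- analyze_all_snps(need_in())
      utils::write.table(tab, opt$out, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      message("wrote ", opt$out)
      tab
    },
    mdr = {
      res <- run_mdr(need_in(), max_order = as.integer(opt$`max-order`),
                     k = as.integer(opt$folds),
                     B = as.integer(opt$permutations), seed = seed)
      print(res)
      res
    },
    run = {
      input <- if (is.null(opt$`in`)) default_sim_config(seed) else opt$`in`
      run_full_pipeline(pipeline_config(input, opt$out, seed = seed))
    },
    stop(usage, call. = FALSE))
  invisible(res)
}
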