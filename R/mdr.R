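# ---- multifactor dimensionality reduction (MDR) ----------------------------
#
# MDR collapses a multilocus genotype table into a one-dimensional classifier:
# each genotype cell is labeled high risk when its case:control ratio reaches
# a threshold T (the training-set case:control ratio), and a subject is
# predicted "case" iff its cell is high risk.  Candidate locus sets compete
# over stratified k-fold cross-validation; the fold winner is the candidate
# with the highest training balanced accuracy, cross-validation consistency
# (CVC) counts fold wins, and average testing accuracy (ATA) is the mean
# held-out balanced accuracy.  Significance comes from label-permutation
# with the full fitting procedure re-run on every shuffled dataset.
#
# All accounting is done on per-(cell, status, fold) count arrays, so a full
# cross-validation costs one pass over the genotype matrix regardless of the
# number of folds, and permutation testing at B = 10,000 stays cheap.

#' Label multilocus genotype cells high or low risk
#'
#' A cell is high risk iff its case:control count ratio is at least the
#' threshold `T` (inclusive).  A cell with cases but no controls is high
#' risk; a cell with no cases (including an empty cell) is low risk.
#'
#' @param case_counts,control_counts Nonnegative count vectors over the same
#'   cells.
#' @param threshold Positive ratio `T`, conventionally the case:control
#'   ratio of the data the labeling is built on.
#' @return Logical vector, `TRUE` = high risk.
#' @export
assign_risk_labels <- function(case_counts, control_counts, threshold) {
  stopifnot(length(case_counts) == length(control_counts), threshold > 0,
            all(case_counts >= 0), all(control_counts >= 0))
  (control_counts > 0 & case_counts / control_counts >= threshold) |
    (control_counts == 0 & case_counts > 0)
}

# balanced accuracy from a cells x {case, control} count matrix and labels;
# an empty class contributes chance level (0.5) rather than an error so that
# cross-validation folds degrade gracefully
.ba_from_counts <- function(case_counts, control_counts, high) {
  n_case <- sum(case_counts); n_control <- sum(control_counts)
  sens <- if (n_case > 0) sum(case_counts[high]) / n_case else 0.5
  spec <- if (n_control > 0) sum(control_counts[!high]) / n_control else 0.5
  (sens + spec) / 2
}

#' Build a risk labeling for a locus set from a cohort
#'
#' Tabulates the multilocus genotype cells (complete cases at the involved
#' loci) and labels them with [assign_risk_labels()].
#'
#' @param x A `cohort` (typically a training split).
#' @param loci Character vector of rsids, length >= 1.
#' @param threshold Ratio `T`; default the evaluable case:control ratio of
#'   `x` at these loci.
#' @return A `risk_labeling`: list with `loci`, `threshold`, `high` (logical
#'   over the `3^length(loci)` cells in mixed-radix order, first locus
#'   fastest).
#' @export
build_risk_labeling <- function(x, loci, threshold = NULL) {
  stopifnot(inherits(x, "cohort"), length(loci) >= 1)
  cells <- .cell_index(x, loci)
  m <- 3L ^ length(loci)
  is_case <- x$subjects$status == "case"
  cc <- tabulate(cells[is_case], m)
  kk <- tabulate(cells[!is_case], m)
  if (is.null(threshold)) {
    if (sum(kk) == 0) stop("no evaluable controls to set the threshold",
                           call. = FALSE)
    threshold <- sum(cc) / sum(kk)
  }
  structure(list(loci = loci, threshold = threshold,
                 high = assign_risk_labels(cc, kk, threshold)),
            class = "risk_labeling")
}

#' Balanced accuracy of a risk labeling on a cohort
#'
#' Predicts "case" for subjects in high-risk cells and computes
#' (sensitivity + specificity) / 2.  Subjects missing a genotype at any
#' involved locus are excluded; the evaluated data must retain at least one
#' case and one control.
#'
#' @param labeling A `risk_labeling` from [build_risk_labeling()].
#' @param x A `cohort`.
#' @return Fraction in \[0, 1\].
#' @export
balanced_accuracy <- function(labeling, x) {
  stopifnot(inherits(labeling, "risk_labeling"), inherits(x, "cohort"))
  cells <- .cell_index(x, labeling$loci)
  m <- 3L ^ length(labeling$loci)
  is_case <- x$subjects$status == "case"
  cc <- tabulate(cells[is_case], m)
  kk <- tabulate(cells[!is_case], m)
  if (sum(cc) == 0 || sum(kk) == 0)
    stop("no evaluable cases or controls at these loci", call. = FALSE)
  .ba_from_counts(cc, kk, labeling$high)
}

# mixed-radix cell index (1-based) for a locus set; NA if any locus missing
.cell_index <- function(x, loci) {
  j <- match(loci, x$panel$rsid)
  if (anyNA(j)) stop("unknown rsid: ", loci[which(is.na(j))[1L]],
                     call. = FALSE)
  idx <- rep(1L, nrow(x$genotypes))
  mult <- 1L
  for (jj in j) {
    idx <- idx + x$genotypes[, jj] * mult
    mult <- mult * 3L
  }
  idx
}

# stratified fold assignment: seeded shuffle within each status, then
# round-robin, giving folds as even as possible; uses the current RNG state
.stratified_folds <- function(is_case, k) {
  fold <- integer(length(is_case))
  for (grp in list(which(is_case), which(!is_case))) {
    if (length(grp) < k)
      stop("stratification error: fewer than k subjects in one status",
           call. = FALSE)
    fold[grp[sample.int(length(grp))]] <- rep_len(seq_len(k), length(grp))
  }
  fold
}

# Core CV engine on precomputed cell indices.  cells_list: per candidate,
# the subjects' 1-based cell index (NA = incomplete); ms: cells per
# candidate.  Returns per-candidate train/test balanced-accuracy matrices,
# fold winners, CVC and ATA.
.cv_engine <- function(cells_list, ms, is_case, fold, k) {
  C <- length(cells_list)
  s01 <- ifelse(is_case, 0L, 1L)          # 0 = case, 1 = control
  train_acc <- matrix(NA_real_, C, k)
  test_acc <- matrix(NA_real_, C, k)
  for (ci in seq_len(C)) {
    m <- ms[ci]
    idx <- cells_list[[ci]] + m * (s01 + 2L * (fold - 1L))
    cnt <- array(tabulate(idx, m * 2L * k), dim = c(m, 2L, k))
    tot_case <- rowSums(cnt[, 1L, , drop = FALSE], dims = 1L)
    tot_ctrl <- rowSums(cnt[, 2L, , drop = FALSE], dims = 1L)
    for (f in seq_len(k)) {
      te_case <- cnt[, 1L, f]; te_ctrl <- cnt[, 2L, f]
      tr_case <- tot_case - te_case; tr_ctrl <- tot_ctrl - te_ctrl
      n_tr_ctrl <- sum(tr_ctrl)
      threshold <- if (n_tr_ctrl > 0) sum(tr_case) / n_tr_ctrl else 1
      high <- assign_risk_labels(tr_case, tr_ctrl, threshold)
      train_acc[ci, f] <- .ba_from_counts(tr_case, tr_ctrl, high)
      test_acc[ci, f] <- .ba_from_counts(te_case, te_ctrl, high)
    }
  }
  winner <- apply(train_acc, 2L, which.max)   # candidates pre-sorted for ties
  cvc <- tabulate(winner, C)
  list(train_acc = train_acc, test_acc = test_acc, winner = winner,
       cvc = cvc, ata = rowMeans(test_acc))
}

# canonical candidate order: fewest loci first, then lexicographic rsid
.sort_candidates <- function(candidates) {
  key <- vapply(candidates, function(l) paste(sort(l), collapse = ","),
                character(1))
  candidates[order(lengths(candidates), key)]
}

#' Cross-validate MDR candidate locus sets
#'
#' Stratified k-fold cross-validation of a list of candidate locus sets.
#' Per fold, each candidate's risk labeling is built on the training
#' fraction with threshold equal to the training (evaluable) case:control
#' ratio and evaluated on the held-out fold; the fold winner is the
#' candidate with the highest training balanced accuracy (ties: fewest
#' loci, then lexicographic rsid order).  CVC is the number of folds won
#' and ATA the mean held-out balanced accuracy.
#'
#' @param x A `cohort`.
#' @param candidates List of character vectors of rsids.
#' @param k Folds (default 10); both statuses must have at least `k`
#'   subjects.
#' @param seed Integer seed fixing the fold assignment.
#' @return A list of `mdr_candidate` objects (fields `loci`, `train_acc`,
#'   `test_acc`, `winner`, `cvc`, `ata`), in canonical candidate order.
#' @export
mdr_cross_validate <- function(x, candidates, k = 10L, seed = 1L) {
  stopifnot(inherits(x, "cohort"), length(candidates) >= 1, k >= 2)
  candidates <- .sort_candidates(candidates)
  set.seed(seed)
  is_case <- x$subjects$status == "case"
  fold <- .stratified_folds(is_case, k)
  cells_list <- lapply(candidates, function(l) .cell_index(x, l))
  ms <- 3L ^ lengths(candidates)
  res <- .cv_engine(cells_list, ms, is_case, fold, k)
  lapply(seq_along(candidates), function(ci) {
    structure(list(loci = candidates[[ci]],
                   train_acc = res$train_acc[ci, ],
                   test_acc = res$test_acc[ci, ],
                   winner = res$winner == ci,
                   cvc = res$cvc[ci], ata = res$ata[ci], k = k),
              class = "mdr_candidate")
  })
}

#' @export
print.mdr_candidate <- function(x, ...) {
  cat(sprintf("<mdr_candidate> %s  CVC %d/%d  ATA %.3f\n",
              paste(x$loci, collapse = "+"), as.integer(x$cvc),
              as.integer(x$k), x$ata))
  invisible(x)
}

#' Select the best MDR model
#'
#' Maximal CVC; ties broken by maximal ATA, then fewest loci, then
#' lexicographic rsid order.
#'
#' @param candidates Nonempty list of `mdr_candidate` objects.
#' @return The winning `mdr_candidate`.
#' @export
select_best_model <- function(candidates) {
  stopifnot(length(candidates) >= 1)
  key <- vapply(candidates, function(cd) paste(sort(cd$loci), collapse = ","),
                character(1))
  ord <- order(-vapply(candidates, `[[`, numeric(1), "cvc"),
               -vapply(candidates, `[[`, numeric(1), "ata"),
               lengths(lapply(candidates, `[[`, "loci")),
               key)
  candidates[[ord[1L]]]
}

#' Permutation test for the best MDR model
#'
#' Shuffles case/control labels (preserving the totals), re-runs the entire
#' cross-validation and model selection on every shuffled dataset, and
#' compares the observed best model's ATA to the null distribution of
#' best-model ATAs: `p = (#\{null ATA >= observed ATA\} + 1) / (B + 1)`.
#' The null distribution of the best model's CVC is recorded alongside.
#'
#' @param x A `cohort`.
#' @param candidates List of character vectors of rsids.
#' @param k Folds.
#' @param B Number of permutations (the calibration study used 10,000).
#' @param seed Integer seed (drives folds and permutations).
#' @return An `mdr_result`: list with `best` (`mdr_candidate`),
#'   `candidates`, `permutation_p`, `null_ata`, `null_cvc`, `B`, `k`,
#'   `seed`.
#' @export
mdr_permutation_test <- function(x, candidates, k = 10L, B = 10000L,
                                 seed = 1L) {
  stopifnot(inherits(x, "cohort"), B >= 1)
  candidates <- .sort_candidates(candidates)
  set.seed(seed)
  is_case <- x$subjects$status == "case"
  cells_list <- lapply(candidates, function(l) .cell_index(x, l))
  ms <- 3L ^ lengths(candidates)
  run_once <- function(case_flags) {
    fold <- .stratified_folds(case_flags, k)
    res <- .cv_engine(cells_list, ms, case_flags, fold, k)
    best <- order(-res$cvc, -res$ata)[1L]   # candidate order breaks ties
    list(res = res, best = best)
  }
  obs <- run_once(is_case)
  null_ata <- numeric(B)
  null_cvc <- integer(B)
  for (b in seq_len(B)) {
    perm <- is_case[sample.int(length(is_case))]
    nb <- run_once(perm)
    null_ata[b] <- nb$res$ata[nb$best]
    null_cvc[b] <- nb$res$cvc[nb$best]
  }
  obs_ata <- obs$res$ata[obs$best]
  p <- (sum(null_ata >= obs_ata) + 1) / (B + 1)
  best <- structure(list(loci = candidates[[obs$best]],
                         train_acc = obs$res$train_acc[obs$best, ],
                         test_acc = obs$res$test_acc[obs$best, ],
                         winner = obs$res$winner == obs$best,
                         cvc = obs$res$cvc[obs$best],
                         ata = obs_ata, k = k),
                    class = "mdr_candidate")
  all_cands <- lapply(seq_along(candidates), function(ci) {
    structure(list(loci = candidates[[ci]],
                   train_acc = obs$res$train_acc[ci, ],
                   test_acc = obs$res$test_acc[ci, ],
                   winner = obs$res$winner == ci,
                   cvc = obs$res$cvc[ci], ata = obs$res$ata[ci], k = k),
              class = "mdr_candidate")
  })
  structure(list(best = best, candidates = all_cands, permutation_p = p,
                 null_ata = null_ata, null_cvc = null_cvc,
                 B = B, k = k, seed = seed),
            class = "mdr_result")
}

#' @export
print.mdr_result <- function(x, ...) {
  cat(sprintf("<mdr_result> best model %s\n",
              paste(x$best$loci, collapse = "+")))
  cat(sprintf("  CVC %d/%d  ATA %.3f  permutation p %.4g (B = %d)\n",
              as.integer(x$best$cvc), as.integer(x$k), x$best$ata,
              x$permutation_p, as.integer(x$B)))
  invisible(x)
}

#' Run exhaustive MDR up to a given interaction order
#'
#' Evaluates every locus subset of size 1..`max_order` of the panel with
#' stratified cross-validation and permutation testing.  `max_order = 1`
#' reproduces the single-factor screen of the calibration study.
#'
#' @param x A `cohort`.
#' @param max_order Largest subset size (default 1).
#' @param k Folds.
#' @param B Permutations; `B = 0` skips the permutation test and returns
#'   the cross-validated result with `permutation_p = NA`.
#' @param seed Integer seed.
#' @return An `mdr_result`.
#' @export
run_mdr <- function(x, max_order = 1L, k = 10L, B = 10000L, seed = 1L) {
  stopifnot(inherits(x, "cohort"), max_order >= 1,
            max_order <= nrow(x$panel))
  candidates <- list()
  for (ord in seq_len(max_order)) {
    sets <- utils::combn(x$panel$rsid, ord, simplify = FALSE)
    candidates <- c(candidates, sets)
  }
  if (B >= 1) return(mdr_permutation_test(x, candidates, k, B, seed))
  cands <- mdr_cross_validate(x, candidates, k, seed)
  best <- select_best_model(cands)
  structure(list(best = best, candidates = cands, permutation_p = NA_real_,
                 null_ata = numeric(0), null_cvc = integer(0),
                 B = 0L, k = k, seed = seed),
            class = "mdr_result")
}
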