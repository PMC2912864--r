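test_that("risk labels follow the case:control ratio rule", {
  cnt <- ref_counts_8q24()$rs16901979
  T0 <- 192 / 512
  high <- assign_risk_labels(cnt["case", ], cnt["control", ], T0)
  expect_identical(unname(high), c(FALSE, TRUE, TRUE))  # GG low, GT/TT high
  # inclusive bound: all cells exactly at T are high
  expect_true(all(assign_risk_labels(c(10, 20), c(20, 40), 0.5)))
  # empty cell and zero-case cell are low; cases-without-controls is high
  expect_identical(unname(assign_risk_labels(c(0, 0, 3), c(0, 5, 0), 0.4)),
                   c(FALSE, FALSE, TRUE))
})

test_that("balanced accuracy matches direct computation and brute force", {
  coh <- ref_cohort_8q24()
  lab <- build_risk_labeling(coh, "rs16901979")
  # (147/192 + 188/512) / 2 from the published counts
  expect_equal(balanced_accuracy(lab, coh), 0.56640625, tolerance = 1e-12)
  # engine vs direct contingency-table computation for every panel SNP
  for (rs in coh$panel$rsid) {
    m <- count_genotypes(coh, rs)$counts
    expect_equal(balanced_accuracy(build_risk_labeling(coh, rs), coh),
                 ba_from_table(m), tolerance = 1e-12, label = rs)
  }
  # degenerate classifier: everything high-risk scores 0.5
  all_high <- structure(list(loci = "rs16901979", threshold = 1e-9,
                             high = rep(TRUE, 3)), class = "risk_labeling")
  expect_equal(balanced_accuracy(all_high, coh), 0.5)

  # 8-subject brute-force confusion-matrix oracle
  g <- matrix(c(0, 0, 1, 2, 0, 1, 1, 2), ncol = 1)
  st <- c("case", "case", "case", "case", "control", "control", "control",
          "control")
  tiny <- make_cohort(st, g)
  lab8 <- build_risk_labeling(tiny, "rs0001")  # T = 1
  pred_case <- lab8$high[g[, 1] + 1]
  sens <- sum(pred_case & st == "case") / sum(st == "case")
  spec <- sum(!pred_case & st == "control") / sum(st == "control")
  expect_equal(balanced_accuracy(lab8, tiny), (sens + spec) / 2)
})

test_that("cross-validation is deterministic, stratified, and exact for a
           single candidate", {
  coh <- simulate_cohort(default_sim_config(), seed = 5)
  res <- mdr_cross_validate(coh, list("rs16901979"), k = 10, seed = 9)
  expect_identical(as.integer(res[[1]]$cvc), 10L)  # uncontested candidate
  expect_true(all(res[[1]]$test_acc >= 0 & res[[1]]$test_acc <= 1))
  again <- mdr_cross_validate(coh, list("rs16901979"), k = 10, seed = 9)
  expect_identical(res[[1]]$test_acc, again[[1]]$test_acc)
  # too few cases for k folds is a stratification error
  few <- make_cohort(rep(c("case", "control"), c(3, 20)),
                     matrix(0L, 23, 1))
  expect_error(mdr_cross_validate(few, list("rs0001"), k = 10),
               "stratification")
})

test_that("select_best_model implements the stated ordering", {
  mk <- function(loci, cvc, ata)
    structure(list(loci = loci, cvc = cvc, ata = ata, k = 10),
              class = "mdr_candidate")
  a <- mk("rs2", 10, 0.52); b <- mk("rs1", 4, 0.60); c <- mk("rs3", 3, 0.70)
  expect_identical(select_best_model(list(b, a, c))$loci, "rs2")
  # CVC tie broken by ATA
  d <- mk("rs4", 5, 0.60); e <- mk("rs5", 5, 0.55)
  expect_identical(select_best_model(list(e, d))$loci, "rs4")
  # full ordering vs brute-force argmax over all permutations of 4 candidates
  cands <- list(mk("rs1", 7, 0.52), mk("rs2", 7, 0.52),
                mk(c("rs1", "rs2"), 7, 0.52), mk("rs0", 6, 0.99))
  pick <- function(l) {
    key <- sapply(l, function(x) paste(sort(x$loci), collapse = ","))
    score <- order(-sapply(l, `[[`, "cvc"), -sapply(l, `[[`, "ata"),
                   lengths(lapply(l, `[[`, "loci")), key)
    l[[score[1]]]
  }
  for (perm in list(1:4, 4:1, c(2, 4, 1, 3), c(3, 1, 4, 2))) {
    got <- select_best_model(cands[perm])
    expect_identical(got$loci, pick(cands[perm])$loci)
    expect_identical(got$loci, "rs1")   # lexicographic tie-break
  }
})

test_that("run_mdr enumerates candidate subsets and permutation p behaves", {
  coh <- simulate_cohort(default_sim_config(), seed = 6)
  r1 <- run_mdr(coh, max_order = 1, B = 0, seed = 2)
  expect_length(r1$candidates, 7)
  r2 <- run_mdr(coh, max_order = 2, B = 0, seed = 2)
  expect_length(r2$candidates, 28)
  # add-one estimator floor: observed beats every null -> p = 1/(B+1)
  cfg <- plant_single_locus_effect(default_sim_config(), "rs16901979",
                                   c(6, 12))
  strong <- simulate_cohort(cfg, seed = 8)
  res <- mdr_permutation_test(strong, list("rs16901979", "rs1447295"),
                              k = 10, B = 99, seed = 3)
  expect_equal(res$permutation_p, 0.01)
  expect_true(all(res$null_ata < res$best$ata))
  # reproducibility of the whole run
  res2 <- mdr_permutation_test(strong, list("rs16901979", "rs1447295"),
                               k = 10, B = 99, seed = 3)
  expect_identical(res$null_ata, res2$null_ata)
  expect_identical(res$permutation_p, res2$permutation_p)
})

test_that("null candidates score near 0.5 and planted effects strengthen ATA", {
  cfg <- default_sim_config()
  for (rs in cfg$panel$rsid)
    cfg$geno_probs[[rs]]["case", ] <- cfg$geno_probs[[rs]]["control", ]
  cfg$n_cases <- 5000L; cfg$n_controls <- 5000L
  nul <- simulate_cohort(cfg, seed = 17)
  res <- mdr_cross_validate(nul, as.list(cfg$panel$rsid), k = 10, seed = 17)
  for (cd in res) expect_lt(abs(cd$ata - 0.5), 0.03)

  # monotonicity: a stronger planted effect does not lower the median
  # selected-model ATA (5 paired seeds, paper-scale cohorts)
  med_ata <- function(or_pair) {
    cfg <- plant_single_locus_effect(default_sim_config(), "rs16901979",
                                     or_pair)
    stats::median(sapply(1:5, function(s) {
      run_mdr(simulate_cohort(cfg, seed = 300 + s), B = 0,
              seed = 300 + s)$best$ata
    }))
  }
  expect_gte(med_ata(c(3, 9)), med_ata(c(1.2, 1.44)))
})

test_that("MDR recovers a planted two-locus pure interaction", {
  # XOR-style risk: carriers of exactly one minor allele class are high
  # risk; marginal effects vanish by construction
  maf <- 0.5
  hwe <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  base <- outer(hwe, hwe)
  risk <- matrix(1, 3, 3)
  odd <- outer(0:2, 0:2, function(a, b) (a + b) %% 2 == 1)
  risk[odd] <- 4
  probs <- list(control = base / sum(base),
                case = base * risk / sum(base * risk))
  hits <- 0
  set.seed(42)
  for (s in 1:10) {
    coh <- sample_pair_cohort(600, 1400, probs, n_null_snps = 2)
    res <- run_mdr(coh, max_order = 2, B = 0, seed = 500 + s)
    ok <- setequal(res$best$loci, c("rs0001", "rs0002")) && res$best$cvc >= 8
    hits <- hits + ok
  }
  expect_gte(hits, 9)
})
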