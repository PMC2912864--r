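test_that("crude odds ratios and Woolf intervals reproduce the published table", {
  # (exposed cases, unexposed cases, exposed controls, unexposed controls)
  cases <- list(
    list(cells = c(97, 45, 237, 188), or = 1.71, ci = c(1.14, 2.56)),  # rs16901979 het
    list(cells = c(50, 45, 87, 188),  or = 2.40, ci = c(1.49, 3.87)),  # rs16901979 hom
    list(cells = c(147, 45, 324, 188), or = 1.90, ci = c(1.30, 2.77)), # rs16901979 carriers
    list(cells = c(88, 48, 232, 171), or = 1.35, ci = c(0.90, 2.02)),  # rs6983561 het
    list(cells = c(50, 48, 105, 171), or = 1.70, ci = c(1.07, 2.70)),  # rs6983561 hom
    list(cells = c(138, 48, 337, 171), or = 1.46, ci = c(1.00, 2.13)), # rs6983561 carriers
    list(cells = c(65, 122, 120, 383), or = 1.70, ci = c(1.18, 2.45)), # rs4242384 het
    list(cells = c(59, 124, 131, 357), or = 1.30, ci = c(0.90, 1.88)), # rs10090154 het
    list(cells = c(10, 173, 21, 500), or = 1.38, ci = c(0.64, 2.98))   # rs11934905 collapsed
  )
  for (cs in cases) {
    est <- odds_ratio_2x2(cs$cells[1], cs$cells[2], cs$cells[3], cs$cells[4])
    expect_equal(round(est[["or"]], 2), cs$or)
    expect_equal(round(c(est[["lo"]], est[["hi"]]), 2), cs$ci)
  }
  # proportional table
  expect_equal(odds_ratio_2x2(10, 10, 10, 10)[["or"]], 1.0)
  # undefined OR: empty column
  expect_error(odds_ratio_2x2(0, 5, 0, 5), "undefined")
})

test_that("odds-ratio symmetry and Woolf-interval properties hold", {
  set.seed(21)
  for (i in 1:25) {
    cells <- stats::rpois(4, 40) + 1
    est <- odds_ratio_2x2(cells[1], cells[2], cells[3], cells[4])
    # swap rows AND columns: unchanged; swap only columns: inverted
    both <- odds_ratio_2x2(cells[4], cells[3], cells[2], cells[1])
    one <- odds_ratio_2x2(cells[2], cells[1], cells[4], cells[3])
    expect_equal(est[["or"]], both[["or"]], tolerance = 1e-12)
    expect_equal(est[["or"]], 1 / one[["or"]], tolerance = 1e-12)
    # CI contains the point estimate
    expect_true(est[["lo"]] <= est[["or"]] && est[["or"]] <= est[["hi"]])
    # scaling all cells up narrows (or keeps) the CI around the same OR
    big <- odds_ratio_2x2(10 * cells[1], 10 * cells[2], 10 * cells[3],
                          10 * cells[4])
    expect_equal(big[["or"]], est[["or"]], tolerance = 1e-12)
    expect_lte(big[["hi"]] / big[["lo"]], est[["hi"]] / est[["lo"]])
  }
})

test_that("chi-square homogeneity matches the published p and the stats oracle", {
  tab <- geno_counts(ref_counts_8q24()$rs16901979, panel_8q24()[6, ])
  res <- chi_square_homogeneity(tab)
  expect_equal(res$df, 2)
  expect_equal(round(res$statistic, 1), 13.8)
  expect_equal(round(res$p, 3), 0.001)
  # proportional table: statistic 0, p 1
  prop <- chi_square_homogeneity(rbind(c(10, 20, 30), c(20, 40, 60)))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p, 1)
  # oracle: stats::chisq.test without correction, random tables
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(stats::rpois(6, 30) + 1, 2, 3)
    res <- chi_square_homogeneity(m)
    orc <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(res$statistic, unname(orc$statistic), tolerance = 1e-12)
    expect_equal(res$p, orc$p.value, tolerance = 1e-12)
  }
  expect_error(chi_square_homogeneity(rbind(c(0, 0, 0), c(1, 2, 3))),
               "degenerate")
})

test_that("Cochran-Armitage trend equals the 1-df score chi-square", {
  # published trend p for rs6983561 is 0.0246; CA with scores (0,1,2)
  res <- cochran_armitage_trend(ref_counts_8q24()$rs6983561)
  expect_lt(abs(res$p - 0.0246), 0.003)
  # identical distributions: z = 0, p = 1
  nul <- cochran_armitage_trend(rbind(c(10, 20, 30), c(20, 40, 60)))
  expect_equal(nul$z, 0)
  expect_equal(nul$p, 1)
  # z^2 equals prop.trend.test's score chi-square to 1e-9
  set.seed(14)
  for (i in 1:20) {
    m <- matrix(stats::rpois(6, 25) + 1, 2, 3, byrow = TRUE)
    res <- cochran_armitage_trend(m)
    orc <- stats::prop.trend.test(m[1, ], colSums(m))
    expect_equal(res$z^2, unname(orc$statistic), tolerance = 1e-9)
  }
  expect_error(cochran_armitage_trend(rbind(c(0, 0, 0), c(0, 0, 0))),
               "degenerate")
})

test_that("genotype_association pools contrasts as in the published plan", {
  panel <- panel_8q24()
  counts <- ref_counts_8q24()
  res <- genotype_association(geno_counts(counts$rs6983561, panel[1, ]))
  tb <- res$table
  expect_equal(round(tb$or[tb$contrast == "hom_vs_ref"], 2), 1.70)
  expect_equal(round(tb$or[tb$contrast == "dominant"], 2), 1.46)
  # null table: all ORs 1
  nul <- geno_counts(rbind(c(30, 20, 10), c(30, 20, 10)), panel[1, ])
  expect_true(all(abs(genotype_association(nul)$table$or - 1) < 1e-12))
  # dominant OR for rs4242382 from per-genotype counts (the published
  # carrier total 326 is internally inconsistent; per-genotype counts rule)
  res4 <- genotype_association(geno_counts(counts$rs4242382, panel[4, ]))
  expect_equal(round(res4$table$or[res4$table$contrast == "dominant"], 2), 1.18)
})

test_that("logistic_fit matches the contingency OR and recovers planted effects", {
  coh <- simulate_cohort(default_sim_config(), seed = 12)
  # saturated-model equivalence: crude dominant fit == 2x2 cross-product
  fit <- logistic_fit(coh, "rs16901979", coding = "dominant",
                      covariates = character(0))
  m <- count_genotypes(coh, "rs16901979")$counts
  est <- odds_ratio_2x2(m[1, 2] + m[1, 3], m[1, 1], m[2, 2] + m[2, 3], m[2, 1])
  expect_equal(fit$or, est[["or"]], tolerance = 1e-6)

  # null recovery: genotype independent of status in a large cohort
  cfg <- default_sim_config()
  for (rs in cfg$panel$rsid)
    cfg$geno_probs[[rs]]["case", ] <- cfg$geno_probs[[rs]]["control", ]
  cfg$n_cases <- 3000L; cfg$n_controls <- 3000L
  nul <- simulate_cohort(cfg, seed = 99)
  nfit <- logistic_fit(nul, "rs16901979", coding = "dominant",
                       covariates = character(0))
  se <- (log(nfit$hi) - log(nfit$or)) / stats::qnorm(0.975)
  expect_lt(abs(log(nfit$or)), 3 * se)

  # degenerate input: too few rows
  tiny <- make_cohort(c("case", "control"), matrix(c(1L, 0L), ncol = 1))
  expect_error(logistic_fit(tiny, "rs0001"), "too few")
})

test_that("analyze_all_snps applies the per-SNP contrast plan", {
  coh <- ref_cohort_8q24()
  res <- analyze_all_snps(coh, covariates = character(0))
  expect_identical(unique(res$rsid), coh$panel$rsid)  # panel order
  # rs11934905 collapses to carriers-vs-reference, no trend test
  sub <- res[res$rsid == "rs11934905", ]
  expect_identical(sub$contrast, "collapsed")
  expect_equal(round(sub$or_crude, 2), 1.38)
  expect_true(is.na(sub$p_trend))
  # the six other SNPs carry the codominant + dominant plan
  expect_true(all(table(res$rsid[res$rsid != "rs11934905"]) == 3))
  # dominant crude OR for rs10090154
  d <- res[res$rsid == "rs10090154" & res$contrast == "dominant", ]
  expect_equal(round(d$or_crude, 2), 1.26)
})
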