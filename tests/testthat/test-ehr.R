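mkPt <- function(events, samples = unique(events$sample)) {
  subjectsDf <- data.frame(sample = samples,
                           birth_date = as.Date("2000-01-01"),
                           sex = "F", affection = "unknown")
  PhenotypeTable(subjectsDf, events)
}

test_that("the two-encounter case definition follows the stated rule", {
  ev <- function(sample, code, dates, source = "encounter",
                 system = "ICD10")
    data.frame(sample = sample, system = system, code = code,
               date = as.Date(dates), source = source)
  # two encounters on different days -> case
  pt <- mkPt(ev("a", "K50.0", c("2010-01-01", "2010-02-01")))
  expect_true(defineCases(pt)[["a"]])
  # two encounters on the same day -> not a case
  pt <- mkPt(ev("b", "K50.1", c("2010-01-01", "2010-01-01")))
  expect_false(defineCases(pt)[["b"]])
  # one problem-list entry suffices
  pt <- mkPt(ev("c", "555.9", "2011-05-05", source = "problem_list",
                system = "ICD9"))
  expect_true(defineCases(pt)[["c"]])
  # a single encounter does not
  pt <- mkPt(ev("d", "K51.0", "2011-05-05"))
  expect_false(defineCases(pt)[["d"]])
  # non-IBD codes never qualify
  pt <- mkPt(ev("e", "I10", c("2010-01-01", "2010-02-01")))
  expect_false(defineCases(pt)[["e"]])
  # ICD-9 prefixes only match ICD-9 events
  pt <- mkPt(ev("f", "555.9", c("2010-01-01", "2010-02-01"),
                system = "ICD10"))
  expect_false(defineCases(pt)[["f"]])
})

test_that("case definitions are monotone under added events", {
  set.seed(61)
  codes <- c("K50.1", "K51.9", "I10", "E11.9")
  for (rep in 1:10) {
    n1 <- sample(1:4, 1)
    e1 <- data.frame(sample = "s", system = "ICD10",
                     code = sample(codes, n1, replace = TRUE),
                     date = as.Date("2010-01-01") + sample(0:400, n1),
                     source = "encounter")
    extra <- data.frame(sample = "s", system = "ICD10",
                        code = sample(codes, 2, replace = TRUE),
                        date = as.Date("2012-01-01") + sample(0:400, 2),
                        source = "encounter")
    before <- defineCases(mkPt(e1))[["s"]]
    after <- defineCases(mkPt(rbind(e1, extra)))[["s"]]
    expect_true(after >= before)
  }
})

test_that("first-diagnosis age does date arithmetic with onset flags", {
  e <- data.frame(sample = "a", system = "ICD10", code = "K50.9",
                  date = as.Date(c("2015-06-01", "2018-01-01")),
                  source = "encounter")
  pt <- mkPt(e)  # born 2000-01-01
  res <- firstDiagnosisAge(pt)
  expect_equal(res$onset_age, 15.41, tolerance = 0.01)
  expect_true(res$pediatric)
  expect_true(res$early_onset)
  # the age never exceeds the age at any matching event
  allAges <- as.numeric(e$date - as.Date("2000-01-01")) / 365.25
  expect_true(all(res$onset_age <= allAges))

  # no matching codes -> undefined with a reason
  pt2 <- mkPt(data.frame(sample = "b", system = "ICD10", code = "I10",
                         date = as.Date("2019-01-01"), source = "encounter"))
  res2 <- firstDiagnosisAge(pt2)
  expect_true(is.na(res2$onset_age))
  expect_equal(res2$reason, "no_matching_code")

  # event before birth is an error
  pt3 <- mkPt(data.frame(sample = "c", system = "ICD10", code = "K50.1",
                         date = as.Date("1999-01-01"), source = "encounter"))
  expect_error(firstDiagnosisAge(pt3), "predates birth")
})

test_that("conflicting CD/UC code carriers are flagged, not resolved", {
  e <- data.frame(
    sample = c("both", "both", "cdonly", "uc9"),
    system = c("ICD10", "ICD10", "ICD10", "ICD9"),
    code = c("K50.1", "K51.9", "K50.0", "556.2"),
    date = as.Date("2012-03-04"), source = "encounter")
  pt <- mkPt(e)
  expect_equal(flagConflictingDiagnoses(pt), "both")
  # an ICD-9 556 with an ICD-10 K50 also conflicts
  e2 <- rbind(e, data.frame(sample = "uc9", system = "ICD10", code = "K50.8",
                            date = as.Date("2013-01-01"),
                            source = "encounter"))
  expect_setequal(flagConflictingDiagnoses(mkPt(e2)), c("both", "uc9"))
  expect_equal(flagConflictingDiagnoses(mkPt(e[0, ], samples = "x")),
               character(0))
})

test_that("diagnosis lead time is signed and summarised over prior cases", {
  e <- data.frame(
    sample = c("a", "a", "b", "b"),
    system = "ICD10",
    code = c("D50.9", "K50.9", "K50.9", "D50.9"),
    date = as.Date(c("2010-01-01", "2012-04-01",   # anemia 2.25 y prior
                     "2010-01-01", "2011-01-01")), # anemia 1 y after
    source = "encounter")
  res <- diagnosisLeadTime(mkPt(e))
  lead <- setNames(res$perSample$lead_years, res$perSample$sample)
  expect_equal(lead[["a"]], 2.247, tolerance = 0.01)
  expect_lt(lead[["b"]], 0)
  expect_equal(res$summary$prop_prior, 0.5)
  expect_equal(res$summary$mean_prior_lead, lead[["a"]])
})

test_that("a planted anemia lead of 2.26 years is recovered at n = 1000", {
  cfg <- simCohortConfig(nTrios = 0L, nSingletons = 9000L,
                         kappa0 = 0.12, psiHet = 1, psiRec = 1, seed = 515L)
  cohort <- simulateCohort(cfg)
  phen <- simulatePhenotypes(cohort)
  expect_gt(sum(phen$truth$affected), 1000)
  res <- diagnosisLeadTime(phen$phenotypes)
  expect_equal(res$summary$mean_prior_lead, 2.26, tolerance = 0.1)
  expect_equal(res$summary$prop_prior, 0.58, tolerance = 0.06)
})

test_that("the PheWAS recovers a planted recessive-only signal", {
  cfg <- simCohortConfig(nTrios = 0L, nSingletons = 6000L,
                         kappa0 = 0.02, psiHet = 1, psiRec = 40,
                         qcHetHomProb = 0, qcLowDepthProb = 0, seed = 616L)
  cohort <- simulateCohort(cfg)
  phen <- simulatePhenotypes(cohort)
  mask <- buildClassMask(cohort$genotypes)
  q <- selectBurdenVariants(mask)
  dip <- callDiplotypes(cohort$genotypes, q, usePopulation = FALSE)
  ind <- setNames(dip$calls$burden == 2L, dip$calls$sample)
  expect_gt(sum(ind), 10)
  pw <- runPhewas(ind, phen$phenotypes)
  # the top-ranked group is the planted Crohn's code family and it
  # survives Bonferroni
  expect_true(pw$code[1] %in% c("K50", "555"))
  expect_true(pw$significant[1])
  # a background code is not significant
  expect_false(any(pw$significant[pw$code %in% c("I10", "E11", "Z00")]))
})

test_that("PheWAS p-values under a permuted indicator behave like a null", {
  cfg <- simCohortConfig(nTrios = 0L, nSingletons = 1500L,
                         kappa0 = 0.05, psiHet = 1, psiRec = 1, seed = 717L)
  cohort <- simulateCohort(cfg)
  phen <- simulatePhenotypes(cohort)
  set.seed(718)
  hits <- 0L; tests <- 0L
  for (rep in 1:20) {
    ind <- setNames(sample(c(rep(TRUE, 40), rep(FALSE, 1460))),
                    phen$truth$sample)
    pw <- runPhewas(ind, phen$phenotypes, correction = "bonferroni")
    hits <- hits + sum(pw$p < 0.05)
    tests <- tests + nrow(pw)
  }
  # Fisher exactness makes the per-code p super-uniform
  expect_lt(hits / tests, 0.05 + 0.02)
})

test_that("a single-code phenome makes the correction the identity", {
  e <- data.frame(sample = c("a", "a", "b", "b"), system = "ICD10",
                  code = "K50.9",
                  date = as.Date(c("2010-01-01", "2010-06-01",
                                   "2011-01-01", "2011-06-01")),
                  source = "encounter")
  pt <- mkPt(e, samples = c("a", "b", "c", "d"))
  ind <- c(a = TRUE, b = FALSE, c = TRUE, d = FALSE)
  pw <- runPhewas(ind, pt)
  expect_equal(nrow(pw), 1L)
  expect_equal(pw$p_adj, pw$p)
})
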