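test_that("odds ratios and Woolf intervals equal textbook arithmetic", {
  set.seed(314)
  for (rep in 1:10) {
    cnt <- rpois(6, 30) + 1
    gc <- genotypeCounts(cnt[1:3], cnt[4:6], "rand")
    add <- orAdditive(gc)
    altCa <- cnt[2] + 2 * cnt[3]; altCo <- cnt[5] + 2 * cnt[6]
    want <- woolfOracle(altCa, 2 * sum(cnt[1:3]) - altCa,
                        altCo, 2 * sum(cnt[4:6]) - altCo)
    expect_equal(add$or, want[["or"]], tolerance = 1e-12)
    expect_equal(add$ciLow, want[["lo"]], tolerance = 1e-12)
    expect_equal(add$ciHigh, want[["hi"]], tolerance = 1e-12)

    rec <- orRecessive(gc)
    want <- woolfOracle(cnt[3], cnt[1] + cnt[2], cnt[6], cnt[4] + cnt[5])
    expect_equal(rec$or, want[["or"]], tolerance = 1e-12)
    expect_equal(c(rec$ciLow, rec$ciHigh),
                 unname(want[c("lo", "hi")]), tolerance = 1e-12)
  }
})

test_that("a perfectly balanced table gives OR 1 and p 1", {
  gc <- genotypeCounts(c(50, 30, 20), c(50, 30, 20), "balanced")
  add <- orAdditive(gc)
  expect_equal(add$or, 1)
  expect_equal(add$pFisher, 1)
  expect_equal(orGenotypic(gc)$or, c(1, 1))
})

test_that("Fisher exact p equals full hypergeometric enumeration", {
  expect_equal(fisherExactP(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-10)
  m <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(fisherExactP(m), 1)
  set.seed(21)
  for (rep in 1:10) {
    m <- matrix(rpois(4, 6), 2)
    expect_equal(fisherExactP(m), fisherEnumOracle(m), tolerance = 1e-7)
  }
})

test_that("Fisher p is invariant to transposition and row/column swaps", {
  set.seed(22)
  for (rep in 1:8) {
    m <- matrix(rpois(4, 10) + 1, 2)
    p <- fisherExactP(m)
    expect_equal(fisherExactP(t(m)), p, tolerance = 1e-12)
    expect_equal(fisherExactP(m[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisherExactP(m[, 2:1]), p, tolerance = 1e-12)
  }
})

test_that("score p equals the Pearson chi-square formula", {
  set.seed(23)
  for (rep in 1:6) {
    m <- matrix(rpois(4, 15) + 1, 2)
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    want <- pchisq(sum((m - E)^2 / E), df = 1, lower.tail = FALSE)
    expect_equal(scoreChisqP(m), want, tolerance = 1e-12)
  }
})

test_that("recessive model equals the genotypic hom model when no hets", {
  gc <- genotypeCounts(c(100, 0, 7), c(900, 0, 12), "nohet")
  rec <- orRecessive(gc)
  hom <- orGenotypic(gc)[2, ]
  expect_equal(rec$or, hom$or)
  expect_equal(rec$pFisher, hom$pFisher)
})

test_that("zero cells flag the estimate undefined, reporting Haldane", {
  # no affected homozygotes: the printed-NA convention
  gc <- genotypeCounts(c(932, 52, 0), c(48606, 1683, 16), "p.G908R")
  res <- orGenotypic(gc)
  expect_true(res$undefined[2])
  expect_true(is.na(res$or[2]))
  expect_true(is.finite(res$orHaldane[2]))
  rec <- orRecessive(gc)
  expect_true(rec$undefined && is.na(rec$or))
  # all-zero exposure likewise flagged
  gc0 <- genotypeCounts(c(10, 5, 0), c(100, 50, 0), "none")
  expect_true(orRecessive(gc0)$undefined)
})

test_that("fixture cohorts round-trip exact genotype counts", {
  gcIn <- table3Counts()[["p.R702W"]]
  fx <- makeFixtureCohort(list(p.R702W = gcIn))
  gcOut <- buildGenotypeCounts(fx$caseFlags, ge = fx$genotypes,
                               variant = "p.R702W", mode = "variant")
  expect_equal(gcOut@cases, gcIn@cases)
  expect_equal(gcOut@controls, gcIn@controls)
  # the standard case definition recognises the fixture cases
  expect_equal(unname(defineCases(fx$phenotypes)), unname(fx$caseFlags))
})

test_that("pipeline-coded counts equal truth-coded counts without noise", {
  cfg <- simCohortConfig(nTrios = 100L, nSingletons = 200L,
                         qcHetHomProb = 0, qcLowDepthProb = 0, seed = 404L)
  cohort <- simulateCohort(cfg)
  phen <- simulatePhenotypes(cohort)
  mask <- buildClassMask(cohort$genotypes, pedigree = cohort$pedigree)
  q <- selectBurdenVariants(mask)
  dip <- callDiplotypes(cohort$genotypes, q, pedigree = cohort$pedigree)
  # samples without parents whose two hets happen to share a haplotype are
  # genuinely unresolvable: they are called putative, so the exact identity
  # holds on the decided calls
  decided <- dip$calls$category != "CHET_PUTATIVE"
  flags <- setNames(phen$truth$affected, phen$truth$sample)
  got <- buildGenotypeCounts(flags[dip$calls$sample[decided]],
                             calls = dip$calls[decided, ], mode = "burden")
  truthCode <- ifelse(phen$truth$is_rec, 2L,
                      ifelse(phen$truth$n_alt >= 1L, 1L, 0L))
  count3 <- function(keep) c(ref = sum(truthCode[decided & keep] == 0L),
                             het = sum(truthCode[decided & keep] == 1L),
                             rec = sum(truthCode[decided & keep] == 2L))
  expect_equal(got@cases, count3(phen$truth$affected))
  expect_equal(got@controls, count3(!phen$truth$affected))
  # and every putative call is a genuine unphased double het
  putative <- dip$calls$category == "CHET_PUTATIVE"
  expect_true(all(phen$truth$n_alt[putative] >= 2L))
})

test_that("burden test runs Firth on exactly the supplied genotype codes", {
  t4 <- table4Counts()[["plof_only"]]
  res <- burdenTest(t4, model = "recessive", classSet = "plof_only")
  expect_equal(c(res$cases_ref, res$cases_het, res$cases_rec),
               c(529, 73, 11))
  expect_equal(c(res$controls_ref, res$controls_het, res$controls_rec),
               c(51501, 3254, 47))
  expect_equal(res$or, exp(res$beta))
  # additive and recessive codings answer different questions
  add <- burdenTest(t4, model = "additive", classSet = "plof_only")
  expect_gt(res$or, add$or)
  # a class set selecting zero variants leaves no covariate variation
  empty <- genotypeCounts(c(100, 0, 0), c(900, 0, 0), "empty")
  expect_error(burdenTest(empty, model = "recessive"), "degenerate")
})

test_that("onset-age comparison matches the pooled-t formula", {
  expect_equal(compareOnsetAge(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(compareOnsetAge(c(5, 5), c(5, 5))$p, 1)
  set.seed(31)
  a <- rnorm(12, 43, 10); b <- rnorm(40, 51, 12)
  got <- compareOnsetAge(a, b)
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  tWant <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  expect_equal(got$t, tWant, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(tWant), length(a) + length(b) - 2),
               tolerance = 1e-12)
})
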