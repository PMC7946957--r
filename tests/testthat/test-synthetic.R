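test_that("the generator is byte-deterministic given the seed", {
  cfg <- simCohortConfig(nTrios = 20L, nSingletons = 30L, seed = 9L)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(dosages(c1$genotypes), dosages(c2$genotypes))
  expect_identical(c1$truth, c2$truth)
  p1 <- simulatePhenotypes(c1)
  p2 <- simulatePhenotypes(c2)
  expect_identical(diagnosisEvents(p1$phenotypes),
                   diagnosisEvents(p2$phenotypes))
  expect_identical(p1$truth$affected, p2$truth$affected)
})

test_that("zero-frequency variants give all-reference haplotypes", {
  panel <- nod2VariantPanel()
  panel$freq <- 0
  cfg <- simCohortConfig(nTrios = 5L, nSingletons = 5L, panel = panel,
                         seed = 2L)
  H <- simulateFounderHaplotypes(cfg, 100L)
  expect_equal(dim(H), c(200L, nrow(panel)))
  expect_true(all(H == 0L))
})

test_that("founder haplotypes hit their frequencies in HWE proportions", {
  cfg <- simCohortConfig(seed = 1001L)
  n <- 20000L
  H <- simulateFounderHaplotypes(cfg, n)
  f <- cfg$panel$freq[match("p.R702W", cfg$panel$label)]
  expect_equal(f, 0.05)
  pHat <- mean(H[, "p.R702W"])
  se <- sqrt(f * (1 - f) / (2 * n))
  expect_lt(abs(pHat - f), 3 * se)
  # genotypes from consecutive haplotype pairs follow Hardy-Weinberg
  g <- H[seq(1, 2 * n, by = 2), "p.R702W"] + H[seq(2, 2 * n, by = 2),
                                               "p.R702W"]
  obs <- tabulate(g + 1L, 3L)
  expected <- n * c((1 - pHat)^2, 2 * pHat * (1 - pHat), pHat^2)
  chi <- sum((obs - expected)^2 / expected)
  expect_gt(pchisq(chi, df = 1, lower.tail = FALSE), 0.001)
})

test_that("transmission is Mendelian-exact before noise", {
  cfg <- simCohortConfig(nTrios = 500L, nSingletons = 0L,
                         qcHetHomProb = 0, qcLowDepthProb = 0, seed = 1100L)
  cohort <- simulateCohort(cfg)
  ped <- as.data.frame(cohort$pedigree)
  d <- cohort$trueDosage
  hapA <- cohort$haplotypes$A; hapB <- cohort$haplotypes$B
  kids <- ped$id[!is.na(ped$father)]
  mendelErrors <- 0L
  for (k in kids) {
    fa <- ped$father[match(k, ped$id)]; mo <- ped$mother[match(k, ped$id)]
    # each transmitted haplotype must equal one of the parent's two
    okA <- all(hapA[k, ] == hapA[fa, ]) || all(hapA[k, ] == hapB[fa, ])
    okB <- all(hapB[k, ] == hapA[mo, ]) || all(hapB[k, ] == hapB[mo, ])
    if (!okA || !okB) mendelErrors <- mendelErrors + 1L
    # conservation: offspring alt count cannot exceed parental dosage sum
    if (any(d[, k] > d[, fa] + d[, mo])) mendelErrors <- mendelErrors + 1L
  }
  expect_equal(mendelErrors, 0L)
  # observed matrix equals the truth projection when noise is off
  expect_identical(dosages(cohort$genotypes), cohort$trueDosage)
})

test_that("cis-group variants co-segregate on one haplotype", {
  cfg <- simCohortConfig(nTrios = 300L, nSingletons = 400L, seed = 1200L)
  cohort <- simulateCohort(cfg)
  hapA <- cohort$haplotypes$A; hapB <- cohort$haplotypes$B
  # with cis linkage 1, the rarer member of a cis group never occurs
  # without its partner on the same haplotype, so no individual is
  # true-trans for a blacklisted pair
  for (pair in defaultCisBlacklist()) {
    rare <- pair[which.min(cfg$panel$freq[match(pair, cfg$panel$label)])]
    main <- setdiff(pair, rare)
    expect_true(all(hapA[, rare] <= hapA[, main]))
    expect_true(all(hapB[, rare] <= hapB[, main]))
  }
  # a parent carrying a cis pair transmits both variants or neither
  ped <- as.data.frame(cohort$pedigree)
  kids <- ped$id[!is.na(ped$father)]
  pair <- defaultCisBlacklist()[[1]]
  carrierKids <- kids[cohort$trueDosage[pair[2], kids] > 0]
  for (k in carrierKids)
    expect_true(all(cohort$trueDosage[pair[1], k] >=
                      cohort$trueDosage[pair[2], k]))
})

test_that("a null penetrance model makes disease independent of genotype", {
  cfg <- simCohortConfig(nTrios = 0L, nSingletons = 20000L,
                         kappa0 = 0.05, psiHet = 1, psiRec = 1, seed = 1300L)
  cohort <- simulateCohort(cfg)
  phen <- simulatePhenotypes(cohort)
  tab <- table(rec = phen$truth$is_rec, aff = phen$truth$affected)
  expect_gt(fisherExactP(unclass(tab)), 0.001)
})

test_that("penetrance multipliers are respected on the odds scale", {
  cfg <- simCohortConfig(nTrios = 0L, nSingletons = 50000L,
                         kappa0 = 0.02, psiHet = 1, psiRec = 10,
                         qcHetHomProb = 0, qcLowDepthProb = 0, seed = 1400L)
  cohort <- simulateCohort(cfg)
  phen <- simulatePhenotypes(cohort)
  rec <- phen$truth$is_rec
  pRec <- mean(phen$truth$affected[rec])
  pNon <- mean(phen$truth$affected[!rec & phen$truth$n_alt == 0])
  orHat <- (pRec / (1 - pRec)) / (pNon / (1 - pNon))
  expect_gt(sum(rec), 100)
  expect_equal(orHat, 10, tolerance = 0.35)
})
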