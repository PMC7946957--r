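test_that("pedigree phasing resolves the canonical trio configurations", {
  # father het at A only, mother het at B only -> alt alleles from different
  # parents: TRANS
  fx <- trioFixture(father = c(1L, 0L), mother = c(0L, 1L),
                    child = c(1L, 1L))
  pc <- phaseByPedigree(fx$ge, fx$ped, "kid", "p.VarA", "p.VarB")
  expect_equal(pc$verdict, "TRANS")
  expect_equal(pc$evidence, "pedigree")

  # mother carries both, father neither -> inherited together: CIS
  fx <- trioFixture(father = c(0L, 0L), mother = c(1L, 1L),
                    child = c(1L, 1L))
  expect_equal(phaseByPedigree(fx$ge, fx$ped, "kid", "p.VarA",
                               "p.VarB")$verdict, "CIS")

  # both parents carry both -> ambiguous
  fx <- trioFixture(father = c(1L, 1L), mother = c(1L, 1L),
                    child = c(1L, 1L))
  expect_equal(phaseByPedigree(fx$ge, fx$ped, "kid", "p.VarA",
                               "p.VarB")$verdict, "UNRESOLVED")

  # missing parental genotype -> ambiguous
  fx <- trioFixture(father = c(NA_integer_, 0L), mother = c(0L, 1L),
                    child = c(1L, 1L))
  expect_equal(phaseByPedigree(fx$ge, fx$ped, "kid", "p.VarA",
                               "p.VarB")$verdict, "UNRESOLVED")

  # neither parent carries variant A -> Mendelian inconsistency, flagged
  fx <- trioFixture(father = c(0L, 1L), mother = c(0L, 0L),
                    child = c(1L, 1L))
  pc <- phaseByPedigree(fx$ge, fx$ped, "kid", "p.VarA", "p.VarB")
  expect_equal(pc$verdict, "UNRESOLVED")
  expect_true(pc$mendel_inconsistent)

  # a singleton founder has no parents -> UNRESOLVED
  ge <- tinyGe(matrix(c(1L, 1L), 2, 1, dimnames = list(NULL, "solo")),
               labels = c("p.VarA", "p.VarB"))
  ped <- Pedigree(fam = "S1", id = "solo", father = NA, mother = NA, sex = 1)
  expect_equal(phaseByPedigree(ge, ped, "solo", "p.VarA",
                               "p.VarB")$verdict, "UNRESOLVED")
  expect_error(phaseByPedigree(ge, ped, "ghost", "p.VarA", "p.VarB"),
               "ghost")
})

test_that("pedigree verdicts are invariant to swapping the variant pair", {
  set.seed(42)
  for (rep in 1:25) {
    father <- sample(0:2, 2, replace = TRUE)
    mother <- sample(0:2, 2, replace = TRUE)
    fx <- trioFixture(father, mother, child = c(1L, 1L))
    ab <- phaseByPedigree(fx$ge, fx$ped, "kid", "p.VarA", "p.VarB")
    ba <- phaseByPedigree(fx$ge, fx$ped, "kid", "p.VarB", "p.VarA")
    expect_identical(ab$verdict, ba$verdict)
  }
})

test_that("population phasing thresholds the trans posterior", {
  # no cis haplotype exists -> posterior 1 -> TRANS
  pc <- phaseByPopulation("s", "a", "b",
                          c(AB = 0, Ab = 0.1, aB = 0.05, ab = 0.85))
  expect_equal(pc$posterior_trans, 1)
  expect_equal(pc$verdict, "TRANS")
  expect_equal(pc$evidence, "population")

  # symmetric products -> posterior exactly 0.5 -> UNRESOLVED
  pc <- phaseByPopulation("s", "a", "b",
                          c(AB = 0.1, Ab = 0.1, aB = 0.4, ab = 0.4))
  expect_equal(pc$posterior_trans, 0.5)
  expect_equal(pc$verdict, "UNRESOLVED")

  # dominant cis haplotype -> CIS at the default threshold
  pc <- phaseByPopulation("s", "a", "b",
                          c(AB = 0.2, Ab = 0.001, aB = 0.001, ab = 0.798))
  expect_equal(pc$verdict, "CIS")

  # degenerate frequencies -> UNRESOLVED without a posterior
  pc <- phaseByPopulation("s", "a", "b",
                          c(AB = 0, Ab = 0, aB = 0, ab = 1))
  expect_equal(pc$verdict, "UNRESOLVED")
  expect_true(is.na(pc$posterior_trans))
})

test_that("suspect homozygous calls are demoted by depth and balance", {
  v <- tinyVariants("p.V1")
  d <- matrix(c(2L, 2L, 2L, 1L), 1, 4,
              dimnames = list(NULL, c("ok", "lowdp", "lowab", "het")))
  depth <- matrix(c(40, 6, 50, 5), 1, 4)
  ab <- matrix(c(0.98, 0.95, 0.60, 0.50), 1, 4)
  ge <- GenotypeExperiment(v, d, depth = depth, alleleBalance = ab)

  res <- qcGenotypes(ge)
  expect_equal(unname(dosages(res$genotypes)[1, ]),
               c(2L, NA, NA, 1L))  # het calls untouched even at low depth
  expect_setequal(res$log$sample, c("lowdp", "lowab"))

  res2 <- qcGenotypes(ge, policy = "demote_to_het")
  expect_equal(unname(dosages(res2$genotypes)[1, ]), c(2L, 1L, 1L, 1L))
})

test_that("QC strictly reduces false homozygous diplotypes on a noisy cohort", {
  cfg <- simCohortConfig(nTrios = 150L, nSingletons = 300L,
                         qcHetHomProb = 0.08, qcLowDepthProb = 0,
                         seed = 202L)
  cohort <- simulateCohort(cfg)
  mask <- buildClassMask(cohort$genotypes, pedigree = cohort$pedigree)
  q <- selectBurdenVariants(mask)
  falseHom <- function(ge) {
    dip <- callDiplotypes(ge, q, pedigree = cohort$pedigree,
                          usePopulation = FALSE)
    sum(dip$calls$category == "HOM" & cohort$truth$category != "HOM")
  }
  before <- falseHom(cohort$genotypes)
  after <- falseHom(qcGenotypes(cohort$genotypes)$genotypes)
  expect_gt(before, 0)
  expect_lt(after, before)
})

test_that("the cis blacklist removes pairs in either order and logs them", {
  pairs <- data.frame(var_a = c("p.L1007fs", "p.M863V", "p.R702W"),
                      var_b = c("p.M863V", "p.L1007fs", "p.G908R"),
                      stringsAsFactors = FALSE)
  res <- applyCisBlacklist(pairs)
  expect_equal(nrow(res$excluded), 2L)
  expect_equal(res$retained$var_a, "p.R702W")
  # empty blacklist is the identity
  res2 <- applyCisBlacklist(pairs, list())
  expect_identical(res2$retained, pairs)
  expect_equal(nrow(res2$excluded), 0L)
})

test_that("diplotype calling assigns the documented categories and codes", {
  labels <- c("p.VarA", "p.VarB")
  ped <- Pedigree(fam = c("F1", "F1", "F1", "S1", "S2", "S3", "S4"),
                  id = c("dad", "mum", "kid", "hom", "car", "ref", "put"),
                  father = c(NA, NA, "dad", NA, NA, NA, NA),
                  mother = c(NA, NA, "mum", NA, NA, NA, NA),
                  sex = c(1, 2, 1, 1, 2, 1, 2))
  d <- cbind(dad = c(1L, 0L), mum = c(0L, 1L), kid = c(1L, 1L),
             hom = c(2L, 0L), car = c(0L, 1L), ref = c(0L, 0L),
             put = c(1L, 1L))
  ge <- tinyGe(d, labels = labels)
  dip <- callDiplotypes(ge, labels, pedigree = ped, usePopulation = FALSE)
  got <- setNames(dip$calls$category, dip$calls$sample)
  expect_equal(got[["kid"]], "CHET_CONFIRMED")
  expect_equal(got[["hom"]], "HOM")
  expect_equal(got[["car"]], "CARRIER")
  expect_equal(got[["ref"]], "REF")
  expect_equal(got[["put"]], "CHET_PUTATIVE")
  code <- setNames(dip$calls$burden, dip$calls$sample)
  expect_equal(unname(code[c("kid", "hom", "car", "ref", "put")]),
               c(2L, 2L, 1L, 0L, 2L))
  # putative compound hets drop to code 1 when not counted as biallelic
  dip1 <- callDiplotypes(ge, labels, pedigree = ped, usePopulation = FALSE,
                         includePutative = FALSE)
  expect_equal(dip1$calls$burden[dip1$calls$sample == "put"], 1L)
  # exactly one call per sample
  expect_equal(sort(dip$calls$sample), sort(colnames(d)))

  # a blacklisted pair alone is CIS_EXCLUDED but still a carrier haplotype
  geBl <- tinyGe(cbind(s1 = c(1L, 1L)),
                 labels = c("p.L1007fs", "p.M863V"))
  dipBl <- callDiplotypes(geBl, c("p.L1007fs", "p.M863V"),
                          usePopulation = FALSE)
  expect_equal(dipBl$calls$category, "CIS_EXCLUDED")
  expect_equal(dipBl$calls$burden, 1L)
})

test_that("pedigree phasing never contradicts the simulated truth", {
  cfg <- simCohortConfig(nTrios = 120L, nSingletons = 0L,
                         qcHetHomProb = 0, qcLowDepthProb = 0, seed = 303L)
  cohort <- simulateCohort(cfg)
  mask <- buildClassMask(cohort$genotypes, pedigree = cohort$pedigree)
  q <- selectBurdenVariants(mask)
  d <- dosages(cohort$genotypes)[match(q, variantInfo(cohort$genotypes)$label), ]
  hapA <- cohort$haplotypes$A[, q]; hapB <- cohort$haplotypes$B[, q]
  ped <- as.data.frame(cohort$pedigree)
  offspring <- ped$id[!is.na(ped$father)]
  checked <- 0L
  for (s in offspring) {
    hets <- which(d[, s] == 1L)
    if (length(hets) < 2L) next
    for (pair in utils::combn(hets, 2L, simplify = FALSE)) {
      pc <- phaseByPedigree(cohort$genotypes, cohort$pedigree, s,
                            q[pair[1]], q[pair[2]])
      trueTrans <- (hapA[s, pair[1]] == 1L && hapB[s, pair[2]] == 1L) ||
        (hapB[s, pair[1]] == 1L && hapA[s, pair[2]] == 1L)
      if (pc$verdict == "TRANS") expect_true(trueTrans)
      if (pc$verdict == "CIS") expect_false(trueTrans)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})
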