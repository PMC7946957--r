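# Small fixtures built in code; no files are shipped.

suppressPackageStartupMessages(library(SummarizedExperiment))

# minimal variant table for hand-built GenotypeExperiments
tinyVariants <- function(labels = c("p.A1T", "p.B2C"),
                         consequence = "missense",
                         votes = "DDDDD", pos = NULL) {
  n <- length(labels)
  data.frame(chrom = "16",
             pos = if (is.null(pos)) seq_len(n) * 100L else pos,
             ref = "A", alt = "G", label = labels, gene = "NOD2",
             consequence = rep_len(consequence, n),
             votes = rep_len(votes, n),
             stringsAsFactors = FALSE)
}

tinyGe <- function(dosage, labels = NULL, ...) {
  dosage <- as.matrix(dosage)
  if (is.null(labels)) labels <- sprintf("p.V%d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("s%02d", seq_len(ncol(dosage)))
  GenotypeExperiment(tinyVariants(labels, ...), dosage)
}

# a trio with configurable dosages at two variants;
# order: father, mother, child
trioFixture <- function(father, mother, child,
                        labels = c("p.VarA", "p.VarB")) {
  d <- cbind(dad = father, mum = mother, kid = child)
  ge <- tinyGe(d, labels = labels)
  ped <- Pedigree(fam = "F1", id = c("dad", "mum", "kid"),
                  father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"),
                  sex = c(1, 2, 1))
  list(ge = ge, ped = ped)
}

# genotype vectors drawn under linkage equilibrium HWE at given frequencies
leGenotypes <- function(n, pA, pB) {
  list(a = stats::rbinom(n, 2, pA), b = stats::rbinom(n, 2, pB))
}

# independent 1-D grid-search oracle for two-locus haplotype frequencies:
# margins fixed at observed allele frequencies, profile over pAB
emGridOracle <- function(dosA, dosB, resolution = 1e-3) {
  keep <- !is.na(dosA) & !is.na(dosB)
  dosA <- dosA[keep]; dosB <- dosB[keep]
  pA <- mean(dosA) / 2; pB <- mean(dosB) / 2
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, by = resolution)
  counts <- table(factor(dosA, 0:2), factor(dosB, 0:2))
  ll <- vapply(grid, function(pAB) {
    p <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
    if (any(p < 0)) return(-Inf)
    BiallelicBurden:::.emLogLik(p, counts)
  }, 0)
  grid[which.max(ll)]
}

# textbook Woolf computation, independent of the package's implementation
woolfOracle <- function(a, b, c, d, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(or = or, lo = or * exp(-z * se), hi = or * exp(z * se))
}

# exact two-sided Fisher p by full enumeration with choose(), independent of
# stats::fisher.test
fisherEnumOracle <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- vapply(ks, function(k)
    choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1), 0)
  pObs <- prob[ks == m[1, 1]]
  sum(prob[prob <= pObs * (1 + 1e-7)])
}

# printed reference contingency tables used across acceptance tests
table3Counts <- function() {
  list(
    "p.R702W" = genotypeCounts(c(857, 116, 11), c(45433, 4727, 145),
                               "p.R702W"),
    "p.G908R" = genotypeCounts(c(932, 52, 0), c(48606, 1683, 16),
                               "p.G908R"),
    "p.L1007fs" = genotypeCounts(c(890, 86, 8), c(47455, 2808, 42),
                                 "p.L1007fs"),
    composite = genotypeCounts(c(711, 232, 41), c(40900, 8955, 450),
                               "composite"),
    compound_het = genotypeCounts(c(962, 0, 22), c(50042, 0, 263),
                                  "compound_het"))
}

table4Counts <- function() {
  list(plof_only = genotypeCounts(c(529, 73, 11), c(51501, 3254, 47),
                                  "plof_only"),
       plof_plus_pdns = genotypeCounts(c(474, 115, 24),
                                       c(48253, 6388, 161),
                                       "plof_plus_pdns"))
}
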