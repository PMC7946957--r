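#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood estimation of the four haplotype frequencies
#' (pAB, pAb, paB, pab) for a pair of biallelic loci from unphased unrelated
#' genotypes, by expectation-maximization over the double-heterozygote
#' ambiguity. Uppercase letters denote the alt allele, so `pAB` is the
#' frequency of the haplotype carrying both alt alleles (the cis haplotype of
#' a candidate compound-het pair). All other genotype configurations resolve
#' to haplotypes deterministically; when one locus is homozygous alt the
#' phase is forced and no EM ambiguity arises.
#'
#' The observed-data log-likelihood is checked to be non-decreasing at every
#' iteration (a defining property of EM) and the trace is returned.
#'
#' @param dosA,dosB integer dosage vectors (`{0,1,2,NA}`) at the two loci for
#'   a set of unrelated samples; pairs with a missing value are dropped.
#' @param tol convergence threshold on the largest frequency change
#'   (default 1e-10).
#' @param maxIter iteration cap (default 1000); non-convergence is an error
#'   reporting the last delta.
#' @return list with `freqs` (named numeric, sums to 1), `loglik` (trace),
#'   `iterations`, `n` (samples used).
#' @examples
#' # complete repulsion: every double het is trans by construction
#' a <- c(1, 1, 1, 0, 0); b <- c(1, 1, 1, 0, 0)
#' emHaplotypeFreqs(a, b)$freqs
#' @export
emHaplotypeFreqs <- function(dosA, dosB, tol = 1e-10, maxIter = 1000L) {
  keep <- !is.na(dosA) & !is.na(dosB)
  dosA <- dosA[keep]; dosB <- dosB[keep]
  if (length(dosA) < 2L)
    stop("need at least 2 unrelated samples with genotypes at both loci",
         call. = FALSE)
  # 3x3 genotype count table, [gA+1, gB+1]
  counts <- matrix(0, 3, 3)
  for (i in seq_along(dosA))
    counts[dosA[i] + 1L, dosB[i] + 1L] <- counts[dosA[i] + 1L, dosB[i] + 1L] + 1
  n2 <- 2 * sum(counts)

  # unambiguous haplotype contributions (per copy) for each genotype cell;
  # columns: AB, Ab, aB, ab
  hapIndex <- function(a, b) {  # 1 AB, 2 Ab, 3 aB, 4 ab
    if (a && b) 1L else if (a) 2L else if (b) 3L else 4L
  }
  fixedHap <- function(cnt) {
    h <- numeric(4)
    for (gA in 0:2) for (gB in 0:2) {
      if (gA == 1 && gB == 1) next  # the only ambiguous configuration
      cell <- cnt[gA + 1L, gB + 1L]
      if (!cell) next
      # with at most one het locus the two haplotypes are determined:
      # one copy takes an alt allele wherever dosage >= 1, the other
      # wherever dosage == 2
      i1 <- hapIndex(gA >= 1, gB >= 1)
      i2 <- hapIndex(gA == 2, gB == 2)
      h[i1] <- h[i1] + cell
      h[i2] <- h[i2] + cell
    }
    h
  }
  fixed <- fixedHap(counts)
  nDH <- counts[2, 2]  # double heterozygotes: AB/ab or Ab/aB

  p <- rep(0.25, 4)  # AB, Ab, aB, ab
  ll <- .emLogLik(p, counts)
  trace <- ll
  for (iter in seq_len(maxIter)) {
    # E step: split double hets between cis (AB/ab) and trans (Ab/aB)
    cis <- p[1] * p[4]; trans <- p[2] * p[3]
    wCis <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    expected <- fixed + nDH * c(wCis, 1 - wCis, 1 - wCis, wCis)
    pNew <- expected / n2
    delta <- max(abs(pNew - p))
    p <- pNew
    llNew <- .emLogLik(p, counts)
    if (llNew < ll - 1e-9)
      stop("EM log-likelihood decreased; this should be impossible",
           call. = FALSE)
    ll <- llNew
    trace <- c(trace, ll)
    if (delta < tol) {
      names(p) <- c("AB", "Ab", "aB", "ab")
      return(list(freqs = p, loglik = trace, iterations = iter,
                  n = length(dosA)))
    }
  }
  stop(sprintf(
    "haplotype EM did not converge in %d iterations (last delta %.3e)",
    maxIter, delta), call. = FALSE)
}

# observed-data log-likelihood of the 3x3 genotype counts under HWE on
# haplotypes; p = (AB, Ab, aB, ab)
.emLogLik <- function(p, counts) {
  pr <- matrix(0, 3, 3)
  hap <- list(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  for (i in 1:4) for (j in 1:4) {
    gA <- hap[[i]][1] + hap[[j]][1]
    gB <- hap[[i]][2] + hap[[j]][2]
    pr[gA + 1L, gB + 1L] <- pr[gA + 1L, gB + 1L] + p[i] * p[j]
  }
  keep <- counts > 0
  if (any(pr[keep] <= 0)) return(-Inf)
  sum(counts[keep] * log(pr[keep]))
}
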