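#' Genotype QC for suspect homozygous calls
#'
#' Heterozygous variants can be miscalled homozygous when a region is poorly
#' covered or the allelic balance is skewed. Homozygous-alt calls with read
#' depth below `minDepth` or alt-allele balance below `homAbMin` are demoted:
#' either set missing (default) or demoted to heterozygous. Calls without QC
#' values are kept.
#'
#' @param ge a [GenotypeExperiment-class] (QC assays `depth` / `alleleBalance`
#'   used when present).
#' @param minDepth minimum read depth for a trusted hom call (default 10).
#' @param homAbMin minimum alt-allele balance for a trusted hom call
#'   (default 0.85).
#' @param policy `"set_missing"` (default) or `"demote_to_het"`.
#' @return list with `genotypes` (modified [GenotypeExperiment-class]) and
#'   `log` (data.frame of demoted calls: sample, variant, depth, ab, action).
#' @export
qcGenotypes <- function(ge, minDepth = 10, homAbMin = 0.85,
                        policy = c("set_missing", "demote_to_het")) {
  policy <- match.arg(policy)
  d <- dosages(ge)
  dp <- depths(ge)
  ab <- alleleBalances(ge)
  bad <- matrix(FALSE, nrow(d), ncol(d))
  if (!is.null(dp)) bad <- bad | (!is.na(dp) & dp < minDepth)
  if (!is.null(ab)) bad <- bad | (!is.na(ab) & ab < homAbMin)
  bad <- bad & !is.na(d) & d == 2L

  log <- data.frame(sample = character(), variant = character(),
                    depth = numeric(), ab = numeric(), action = character(),
                    stringsAsFactors = FALSE)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    log <- data.frame(
      sample = colnames(d)[idx[, "col"]],
      variant = variantInfo(ge)$label[idx[, "row"]],
      depth = if (is.null(dp)) NA_real_ else dp[bad],
      ab = if (is.null(ab)) NA_real_ else ab[bad],
      action = policy, stringsAsFactors = FALSE)
    d[bad] <- if (policy == "set_missing") NA_integer_ else 1L
    assay(ge, "dosage") <- d
  }
  list(genotypes = ge, log = log)
}

#' Phase a candidate compound-het pair by pedigree
#'
#' For a sample heterozygous at two variants of the same gene, parental
#' genotypes can resolve whether the two alt alleles sit on opposite
#' haplotypes (trans — true biallelic loss) or the same haplotype (cis).
#' TRANS when each variant is carried by exactly one parent and the parents
#' differ; CIS when one parent carries both variants and the other carries
#' neither; UNRESOLVED when parents are absent, genotypes are missing, both
#' parents carry both variants, or the transmission is Mendelian-inconsistent
#' (the inconsistency is additionally flagged).
#'
#' @param ge a [GenotypeExperiment-class]
#' @param pedigree a [Pedigree-class]; `sample` must be present.
#' @param sample sample id (must be het at both variants).
#' @param varA,varB variant labels.
#' @return one-row data.frame: `sample`, `var_a`, `var_b`, `verdict`
#'   (`TRANS` / `CIS` / `UNRESOLVED`), `evidence` (`pedigree` / `none`),
#'   `posterior_trans` (`NA`; population phasing fills this),
#'   `mendel_inconsistent`.
#' @export
phaseByPedigree <- function(ge, pedigree, sample, varA, varB) {
  d <- dosages(ge)
  labels <- variantInfo(ge)$label
  iA <- match(varA, labels); iB <- match(varB, labels)
  if (is.na(iA) || is.na(iB))
    stop("unknown variant label(s)", call. = FALSE)
  if (!sample %in% colnames(d))
    stop("sample not genotyped: ", sample, call. = FALSE)
  par <- parentsOf(pedigree, sample)  # errors if sample not in pedigree

  unresolved <- function(mendel = FALSE)
    data.frame(sample = sample, var_a = varA, var_b = varB,
               verdict = "UNRESOLVED", evidence = "none",
               posterior_trans = NA_real_, mendel_inconsistent = mendel,
               stringsAsFactors = FALSE)
  if (anyNA(par) || !all(par %in% colnames(d))) return(unresolved())

  gF <- d[c(iA, iB), par[["father"]]]
  gM <- d[c(iA, iB), par[["mother"]]]
  if (anyNA(gF) || anyNA(gM)) return(unresolved())

  carF <- gF >= 1L; carM <- gM >= 1L
  # child is het at both; each alt allele must be carried by some parent
  if ((!carF[1] && !carM[1]) || (!carF[2] && !carM[2]))
    return(unresolved(mendel = TRUE))

  verdict <- "UNRESOLVED"
  if (xor(carF[1], carM[1]) && xor(carF[2], carM[2])) {
    # each variant carried by exactly one parent
    verdict <- if (carF[1] != carF[2]) "TRANS" else "CIS"
  } else if ((all(carF) && !any(carM)) || (all(carM) && !any(carF))) {
    verdict <- "CIS"
  }
  data.frame(sample = sample, var_a = varA, var_b = varB,
             verdict = verdict,
             evidence = if (verdict == "UNRESOLVED") "none" else "pedigree",
             posterior_trans = NA_real_, mendel_inconsistent = FALSE,
             stringsAsFactors = FALSE)
}

#' Phase a candidate compound-het pair by population haplotype frequencies
#'
#' For a double heterozygote, the posterior probability that the two alt
#' alleles are in trans follows from two-locus haplotype frequencies:
#' `P(trans) = pAb*paB / (pAb*paB + pAB*pab)`. The verdict is TRANS at or
#' above `transThreshold`, CIS at or below `1 - transThreshold`, else
#' UNRESOLVED. Degenerate frequencies (zero denominator) give UNRESOLVED.
#'
#' @param sample sample id (annotation only).
#' @param varA,varB variant labels (annotation only).
#' @param hapFreqs named frequencies `c(AB=, Ab=, aB=, ab=)` as returned by
#'   [emHaplotypeFreqs()].
#' @param transThreshold posterior cutoff (default 0.95).
#' @return one-row data.frame in the same shape as [phaseByPedigree()].
#' @export
phaseByPopulation <- function(sample, varA, varB, hapFreqs,
                              transThreshold = 0.95) {
  stopifnot(all(c("AB", "Ab", "aB", "ab") %in% names(hapFreqs)))
  trans <- hapFreqs[["Ab"]] * hapFreqs[["aB"]]
  cis <- hapFreqs[["AB"]] * hapFreqs[["ab"]]
  if (trans + cis <= 0)
    return(data.frame(sample = sample, var_a = varA, var_b = varB,
                      verdict = "UNRESOLVED", evidence = "none",
                      posterior_trans = NA_real_,
                      mendel_inconsistent = FALSE, stringsAsFactors = FALSE))
  post <- trans / (trans + cis)
  verdict <- if (post >= transThreshold) "TRANS"
             else if (post <= 1 - transThreshold) "CIS"
             else "UNRESOLVED"
  data.frame(sample = sample, var_a = varA, var_b = varB, verdict = verdict,
             evidence = "population", posterior_trans = post,
             mendel_inconsistent = FALSE, stringsAsFactors = FALSE)
}

#' Default cis-haplotype blacklist
#'
#' Variant pairs known to segregate together on one haplotype; a double het
#' for such a pair is a single risk haplotype, not a compound het.
#'
#' @return list of unordered label pairs.
#' @export
defaultCisBlacklist <- function() {
  list(c("p.L1007fs", "p.M863V"), c("p.S431L", "p.V793M"))
}

#' Remove blacklisted cis pairs from compound-het candidacy
#'
#' Candidate pairs matching the blacklist (in either order) are removed and
#' logged; the sample remains a carrier of that haplotype.
#'
#' @param pairs data.frame with columns `var_a`, `var_b` (one row per
#'   candidate pair; extra columns pass through).
#' @param blacklist list of unordered label pairs; see
#'   [defaultCisBlacklist()]. An empty blacklist is the identity.
#' @return list with `retained` and `excluded` data.frames.
#' @export
applyCisBlacklist <- function(pairs, blacklist = defaultCisBlacklist()) {
  if (!nrow(pairs) || !length(blacklist))
    return(list(retained = pairs, excluded = pairs[0, , drop = FALSE]))
  keyOf <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  blackKeys <- vapply(blacklist, function(p) keyOf(p[1], p[2]), character(1))
  hit <- keyOf(pairs$var_a, pairs$var_b) %in% blackKeys
  list(retained = pairs[!hit, , drop = FALSE],
       excluded = pairs[hit, , drop = FALSE])
}

#' Call per-sample diplotype categories for a gene
#'
#' Combines dosages at the qualifying variants, the cis blacklist, and
#' pedigree- plus population-phasing evidence into one diplotype call per
#' sample:
#'
#' * `HOM` — homozygous alt at any qualifying variant;
#' * `CHET_CONFIRMED` — two hets phased trans (pedigree evidence overrides
#'   population evidence);
#' * `CHET_PUTATIVE` — two or more hets, no pair decided (e.g. singletons);
#' * `CIS_EXCLUDED` — every het pair resolved cis or blacklisted;
#' * `CARRIER` — exactly one het;
#' * `REF` — no qualifying alt allele.
#'
#' Burden codes follow the 0/1/2 genotype coding: 0 for REF; 1 for CARRIER
#' and CIS_EXCLUDED (one effective haplotype); 2 for HOM, CHET_CONFIRMED and
#' — when `includePutative` — CHET_PUTATIVE. With three or more hets the
#' reported pair is the best-evidence one (pedigree-TRANS, then
#' population-TRANS, then unresolved), ties broken by ascending position.
#'
#' @param ge a [GenotypeExperiment-class] (after any QC).
#' @param qualifying character vector of qualifying variant labels
#'   (from [selectBurdenVariants()]).
#' @param pedigree optional [Pedigree-class] for familial phasing.
#' @param blacklist cis blacklist; see [defaultCisBlacklist()].
#' @param includePutative count putative compound hets as biallelic
#'   (default TRUE).
#' @param usePopulation attempt population phasing of pairs unresolved by
#'   pedigree, using haplotype frequencies estimated by EM from founders (or
#'   all samples when no pedigree) (default TRUE).
#' @param transThreshold posterior cutoff for population phasing.
#' @param gene gene symbol stamped on the calls (default: from annotations).
#' @return list with `calls` (data.frame: sample, gene, category, variants,
#'   burden, evidence), `phase` (all per-pair phase calls), `cisExcluded`
#'   (blacklist log).
#' @export
callDiplotypes <- function(ge, qualifying, pedigree = NULL,
                           blacklist = defaultCisBlacklist(),
                           includePutative = TRUE, usePopulation = TRUE,
                           transThreshold = 0.95, gene = NULL) {
  v <- variantInfo(ge)
  keep <- match(qualifying, v$label)
  if (anyNA(keep))
    stop("qualifying variant(s) not in the genotype matrix: ",
         paste(qualifying[is.na(keep)], collapse = ", "), call. = FALSE)
  if (is.null(gene))
    gene <- if (nrow(v)) v$gene[1] else NA_character_
  d <- dosages(ge)[keep, , drop = FALSE]
  pos <- v$pos[keep]
  labels <- v$label[keep]
  samples <- colnames(d)

  nHet <- colSums(d == 1L, na.rm = TRUE)
  isHom <- colSums(d == 2L, na.rm = TRUE) > 0L

  hasParents <- rep(FALSE, length(samples))
  if (!is.null(pedigree)) {
    pd <- as.data.frame(pedigree)
    i <- match(samples, pd$id)
    hasParents <- !is.na(i) & !(is.na(pd$father[i]) & is.na(pd$mother[i]))
  }

  # population haplotype frequencies are estimated once per needed pair,
  # from founders (unrelated set) when a pedigree is available
  popScope <- if (!is.null(pedigree)) {
    intersect(samples, founders(pedigree))
  } else samples
  emCache <- new.env(parent = emptyenv())
  pairFreqs <- function(iA, iB) {
    key <- paste(iA, iB, sep = "_")
    if (!is.null(emCache[[key]])) return(emCache[[key]])
    res <- tryCatch(
      emHaplotypeFreqs(d[iA, popScope], d[iB, popScope]),
      error = function(e) NULL)
    emCache[[key]] <- if (is.null(res)) NA else res$freqs
    emCache[[key]]
  }

  phaseRows <- list()
  evStrength <- c(pedigree_TRANS = 1, population_TRANS = 2,
                  pedigree_CIS = 5, population_CIS = 6, none_UNRESOLVED = 4)

  # vectorized fast path: REF / CARRIER / HOM; only multi-het non-hom
  # samples need pair logic
  category <- rep("REF", length(samples))
  variants <- rep("", length(samples))
  evidence <- rep("none", length(samples))

  homHits <- which(d == 2L, arr.ind = TRUE)
  if (nrow(homHits)) {
    firstHom <- vapply(split(homHits[, "row"], homHits[, "col"]), min, 0L)
    cols <- as.integer(names(firstHom))
    category[cols] <- "HOM"
    variants[cols] <- labels[firstHom]
    evidence[cols] <- "genotype"
  }
  hetHits <- which(d == 1L, arr.ind = TRUE)
  carrier <- !isHom & nHet == 1L
  if (any(carrier)) {
    oneHet <- vapply(split(hetHits[, "row"], hetHits[, "col"]), min, 0L)
    ci <- intersect(which(carrier), as.integer(names(oneHet)))
    category[ci] <- "CARRIER"
    variants[ci] <- labels[oneHet[as.character(ci)]]
  }

  for (si in which(!isHom & nHet >= 2L)) {
    s <- samples[si]
    dos <- d[, si]
    hets <- which(!is.na(dos) & dos == 1L)
    {
      combo <- utils::combn(hets, 2L)
      pairs <- data.frame(var_a = labels[combo[1, ]],
                          var_b = labels[combo[2, ]],
                          ia = combo[1, ], ib = combo[2, ],
                          stringsAsFactors = FALSE)
      bl <- applyCisBlacklist(pairs, blacklist)
      if (nrow(bl$excluded)) {
        ex <- bl$excluded
        ex$sample <- s; ex$verdict <- "CIS"; ex$evidence <- "blacklist"
        ex$posterior_trans <- NA_real_; ex$mendel_inconsistent <- FALSE
        phaseRows[[length(phaseRows) + 1L]] <-
          ex[c("sample", "var_a", "var_b", "verdict", "evidence",
               "posterior_trans", "mendel_inconsistent")]
      }
      pairs <- bl$retained
      if (!nrow(pairs)) {
        category[si] <- "CIS_EXCLUDED"
        variants[si] <- paste(labels[hets], collapse = ",")
        evidence[si] <- "blacklist"
      } else {
        verdicts <- character(nrow(pairs))
        evs <- character(nrow(pairs))
        for (pi in seq_len(nrow(pairs))) {
          pc <- NULL
          if (hasParents[si])
            pc <- phaseByPedigree(ge, pedigree, s,
                                  pairs$var_a[pi], pairs$var_b[pi])
          if ((is.null(pc) || pc$verdict == "UNRESOLVED") && usePopulation) {
            fr <- pairFreqs(pairs$ia[pi], pairs$ib[pi])
            if (!anyNA(fr)) {
              pop <- phaseByPopulation(s, pairs$var_a[pi], pairs$var_b[pi],
                                       fr, transThreshold)
              if (is.null(pc) || pop$verdict != "UNRESOLVED") pc <- pop
            }
          }
          if (is.null(pc))
            pc <- data.frame(sample = s, var_a = pairs$var_a[pi],
                             var_b = pairs$var_b[pi], verdict = "UNRESOLVED",
                             evidence = "none", posterior_trans = NA_real_,
                             mendel_inconsistent = FALSE,
                             stringsAsFactors = FALSE)
          phaseRows[[length(phaseRows) + 1L]] <- pc
          verdicts[pi] <- pc$verdict
          evs[pi] <- pc$evidence
        }
        strength <- evStrength[paste(evs, verdicts, sep = "_")]
        strength[is.na(strength)] <- 4
        best <- order(strength, pmin(pos[pairs$ia], pos[pairs$ib]),
                      pos[pairs$ia] + pos[pairs$ib])[1]
        if (any(verdicts == "TRANS")) {
          category[si] <- "CHET_CONFIRMED"
          variants[si] <- paste(pairs$var_a[best], pairs$var_b[best],
                                sep = ",")
          evidence[si] <- evs[best]
        } else if (any(verdicts == "UNRESOLVED")) {
          category[si] <- "CHET_PUTATIVE"
          variants[si] <- paste(pairs$var_a[best], pairs$var_b[best],
                                sep = ",")
          evidence[si] <- "none"
        } else {
          category[si] <- "CIS_EXCLUDED"
          variants[si] <- paste(labels[hets], collapse = ",")
          evidence[si] <- evs[best]
        }
      }
    }
  }
  calls <- data.frame(sample = samples, gene = gene, category = category,
                      variants = variants, evidence = evidence,
                      stringsAsFactors = FALSE)
  calls$burden <- diplotypeBurdenCode(calls$category, includePutative)
  phase <- if (length(phaseRows)) do.call(rbind, phaseRows) else
    data.frame(sample = character(), var_a = character(),
               var_b = character(), verdict = character(),
               evidence = character(), posterior_trans = numeric(),
               mendel_inconsistent = logical(), stringsAsFactors = FALSE)
  list(calls = calls, phase = phase,
       cisExcluded = phase[phase$evidence == "blacklist", , drop = FALSE])
}

#' Genotype burden code of a diplotype category
#'
#' The 0/1/2 coding used by the burden regression: homozygous reference 0,
#' heterozygous carriers 1, homozygous-alt or compound-heterozygous 2.
#'
#' @param category character vector of diplotype categories.
#' @param includePutative count `CHET_PUTATIVE` as 2 (default TRUE).
#' @return integer vector of codes.
#' @export
diplotypeBurdenCode <- function(category, includePutative = TRUE) {
  stopifnot(all(category %in% .DIPLOTYPE_CATEGORIES))
  code <- integer(length(category))
  code[category %in% c("CARRIER", "CIS_EXCLUDED")] <- 1L
  code[category %in% c("HOM", "CHET_CONFIRMED")] <- 2L
  code[category == "CHET_PUTATIVE"] <- if (includePutative) 2L else 1L
  code
}
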