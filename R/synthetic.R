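#' Default single-gene simulation variant panel
#'
#' A NOD2-like panel: the three "common" low-frequency Crohn's-disease risk
#' alleles at their clinical-cohort allele frequencies (p.R702W 0.050,
#' p.G908R 0.017, p.L1007fs 0.029), rarer deleterious missense and truncating
#' alleles, the two known cis-haplotype pairs (p.L1007fs+p.M863V and
#' p.S431L+p.V793M, tagged `cis1`/`cis2`), and two non-qualifying variants (a
#' synonymous allele and a missense allele with only 4/5 deleterious votes)
#' to exercise the classifier. Positions are approximate and synthetic.
#'
#' @return data.frame with columns `label`, `chrom`, `pos`, `ref`, `alt`,
#'   `consequence`, `votes`, `freq`, `cis_group`.
#' @export
nod2VariantPanel <- function() {
  p <- data.frame(
    label = c("p.P371T", "p.S431L", "p.R587C", "p.R702W", "p.S506Vfs",
              "p.V793M", "p.G908R", "p.N852S", "p.M863V", "p.L1007fs"),
    pos = c(50733456L, 50733810L, 50745656L, 50745926L, 50746086L,
            50750188L, 50756540L, 50756421L, 50756453L, 50763778L),
    ref = c("C", "C", "C", "C", "CA", "G", "G", "A", "A", "C"),
    alt = c("A", "T", "T", "T", "C", "A", "C", "G", "G", "CC"),
    consequence = c("synonymous", "missense", "missense", "missense",
                    "frameshift", "missense", "missense", "missense",
                    "missense", "frameshift"),
    votes = c(".....", "DDDDD", "DDDDT", "DDDDD", ".....",
              "DDDDD", "DDDDD", "DDDDD", "DDDDD", "....."),
    freq = c(0.030, 0.008, 0.040, 0.050, 0.001,
             0.008, 0.017, 0.005, 0.010, 0.029),
    cis_group = c("", "cis2", "", "", "",
                  "cis2", "", "", "cis1", "cis1"),
    stringsAsFactors = FALSE)
  p$chrom <- "16"
  p[order(p$pos), ]
}

#' Simulation configuration
#'
#' Defines the synthetic cohort: family structure (trios, quartets,
#' singletons), the variant panel with population haplotype frequencies and
#' cis groups, the genotype-dependent penetrance (multiplicative on the odds
#' scale, so the simulated multipliers equal the odds ratios the association
#' module estimates asymptotically), the diagnosis-stream model, and the two
#' genotype-noise channels (het-miscalled-as-hom, and low-coverage calls).
#'
#' Defaults mirror a pediatric IBD study cohort (492 complete trios plus 691
#' singleton probands) and a clinical-population disease model: baseline risk
#' `kappa0 = 0.019`, onset mean 51.5 y with recessive carriers 8 y earlier,
#' anemia recorded for 75% of affected subjects, 58% of those concurrent or
#' prior with a mean 2.26-y prior lead.
#'
#' @param nTrios,nQuartets,nSingletons family counts.
#' @param panel variant panel, see [nod2VariantPanel()].
#' @param kappa0 baseline disease risk in (0,1).
#' @param psiHet,psiRec odds multipliers for carriers and recessive
#'   (homozygous or true-trans compound-het) genotypes; `psiRec >= psiHet >= 1`.
#' @param cisLinkage probability that cis-group members co-segregate on one
#'   haplotype (default 1).
#' @param onsetMeanYears,onsetSdYears,recOnsetGapYears onset-age model.
#' @param ibdEventsMean mean extra IBD encounter count beyond the guaranteed
#'   two distinct days.
#' @param backgroundCodeMean mean non-IBD diagnosis codes per subject.
#' @param anemiaProb,anemiaPriorProb,anemiaLeadMeanYears,anemiaLeadSdYears
#'   anemia comorbidity model.
#' @param cdFraction probability a non-recessive affected subject is CD
#'   rather than UC (recessive-driven disease is always CD).
#' @param conflictProb probability an affected subject also receives one
#'   code from the other subtype family.
#' @param icd9Prob probability an IBD event is coded ICD-9.
#' @param problemListProb probability an affected subject also gets a
#'   problem-list entry.
#' @param qcHetHomProb probability a true het call is corrupted to a
#'   low-depth, skewed-balance hom call.
#' @param qcLowDepthProb probability an arbitrary call is flagged low depth.
#' @param refDate reference "today" used to place birth dates.
#' @param seed single integer seed; every stochastic draw flows from it.
#' @return a `SimCohortConfig` list.
#' @export
simCohortConfig <- function(nTrios = 492L, nQuartets = 0L,
                            nSingletons = 691L,
                            panel = nod2VariantPanel(),
                            kappa0 = 0.019, psiHet = 1.5, psiRec = 10,
                            cisLinkage = 1,
                            onsetMeanYears = 51.5, onsetSdYears = 15,
                            recOnsetGapYears = 8,
                            ibdEventsMean = 3, backgroundCodeMean = 3,
                            anemiaProb = 0.75, anemiaPriorProb = 0.58,
                            anemiaLeadMeanYears = 2.26,
                            anemiaLeadSdYears = 1,
                            cdFraction = 0.55, conflictProb = 0.02,
                            icd9Prob = 0.2, problemListProb = 0.3,
                            qcHetHomProb = 0.01, qcLowDepthProb = 0.02,
                            refDate = "2020-01-01", seed = 1L) {
  stopifnot(nTrios >= 0, nQuartets >= 0, nSingletons >= 0,
            nTrios + nQuartets + nSingletons > 0,
            kappa0 > 0, kappa0 < 1, psiHet >= 1, psiRec >= psiHet,
            cisLinkage >= 0, cisLinkage <= 1,
            all(panel$freq >= 0), all(panel$freq <= 0.5))
  stopifnot(all(c(anemiaProb, anemiaPriorProb, cdFraction, conflictProb,
                  icd9Prob, problemListProb, qcHetHomProb,
                  qcLowDepthProb) >= 0),
            all(c(anemiaProb, anemiaPriorProb, cdFraction, conflictProb,
                  icd9Prob, problemListProb, qcHetHomProb,
                  qcLowDepthProb) <= 1))
  structure(as.list(environment()), class = "SimCohortConfig")
}

#' Simulate a founder haplotype pool
#'
#' Draws `2n` haplotypes over the panel under a single-origin model: each
#' rare allele arose once, so a haplotype carries at most one panel allele
#' (distinct alleles are in complete repulsion — the structure that makes a
#' double heterozygote a true trans compound het), except designated
#' cis-group members, which co-occur on one haplotype. A cis group
#' segregates jointly at the smallest member frequency scaled by
#' `cisLinkage`; members with higher marginal frequency additionally occur
#' alone, so every per-variant frequency is preserved exactly. Founder
#' genotypes assembled from consecutive haplotype pairs are in
#' Hardy-Weinberg proportions per variant.
#'
#' @param config a [simCohortConfig()] (its `panel`, `cisLinkage` and `seed`
#'   are used).
#' @param n number of founders.
#' @return integer matrix, `2n` haplotypes x variants (columns labelled).
#' @export
simulateFounderHaplotypes <- function(config, n) {
  set.seed(config$seed)
  .drawHaplotypes(config$panel, 2L * n, config$cisLinkage)
}

.drawHaplotypes <- function(panel, nHap, cisLinkage = 1) {
  H <- matrix(0L, nHap, nrow(panel))
  colnames(H) <- panel$label
  # haplotype "units": a cis group carried jointly, or a single allele
  units <- list()
  addUnit <- function(members, freq) {
    if (freq > 0)
      units[[length(units) + 1L]] <<- list(members = members, freq = freq)
  }
  grouped <- nzchar(panel$cis_group) & !is.na(panel$cis_group)
  for (g in unique(panel$cis_group[grouped])) {
    members <- which(panel$cis_group == g & grouped)
    fJoint <- cisLinkage * min(panel$freq[members])
    addUnit(members, fJoint)
    for (j in members) addUnit(j, panel$freq[j] - fJoint)
  }
  for (j in which(!grouped)) addUnit(j, panel$freq[j])
  if (!length(units)) return(H)
  freqs <- vapply(units, `[[`, 0, "freq")
  if (sum(freqs) > 1)
    stop("panel allele frequencies sum to ", round(sum(freqs), 3),
         " > 1; the single-origin haplotype model needs a sum <= 1",
         call. = FALSE)
  pick <- sample.int(length(units) + 1L, nHap, replace = TRUE,
                     prob = c(freqs, 1 - sum(freqs)))
  for (u in seq_along(units))
    H[pick == u, units[[u]]$members] <- 1L
  H
}

#' Simulate pedigrees and genotypes with Mendelian transmission
#'
#' Founders draw haplotype pairs from the pool; each offspring receives one
#' uniformly chosen haplotype from each parent (no recombination within the
#' gene). The truth table records each sample's true diplotype category over
#' the qualifying panel variants — including true cis/trans for variant
#' pairs — before any noise. Noise corrupts only the observed matrix: a true
#' het call becomes a low-depth, balance-skewed hom call with probability
#' `qcHetHomProb`, and calls are flagged low-depth with probability
#' `qcLowDepthProb`.
#'
#' @param config a [simCohortConfig()].
#' @return list: `pedigree` ([Pedigree-class]), `genotypes`
#'   ([GenotypeExperiment-class] with `depth` and `alleleBalance` assays),
#'   `truth` (data.frame: sample, family, role, `category`, `is_rec`),
#'   `trueDosage` (variants x samples, noise-free), `haplotypes` (the two
#'   transmitted haplotype matrices, samples x variants), `config`.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimCohortConfig"))
  set.seed(config$seed)
  panel <- config$panel
  nV <- nrow(panel)

  fams <- list()
  if (config$nTrios > 0)
    fams <- c(fams, lapply(seq_len(config$nTrios), function(i)
      list(fam = sprintf("T%04d", i), kids = 1L)))
  if (config$nQuartets > 0)
    fams <- c(fams, lapply(seq_len(config$nQuartets), function(i)
      list(fam = sprintf("Q%04d", i), kids = 2L)))

  rows <- list(); hapIdx <- list()
  founderCount <- 0L
  for (f in fams) {
    fa <- paste0(f$fam, "_f"); mo <- paste0(f$fam, "_m")
    rows[[length(rows) + 1L]] <- data.frame(
      fam = f$fam, id = c(fa, mo), father = NA, mother = NA, sex = c(1L, 2L),
      stringsAsFactors = FALSE)
    founderCount <- founderCount + 2L
    kids <- paste0(f$fam, "_p", seq_len(f$kids))
    rows[[length(rows) + 1L]] <- data.frame(
      fam = f$fam, id = kids, father = fa, mother = mo,
      sex = 1L + (seq_len(f$kids) %% 2L), stringsAsFactors = FALSE)
  }
  if (config$nSingletons > 0) {
    ids <- sprintf("S%05d_p", seq_len(config$nSingletons))
    rows[[length(rows) + 1L]] <- data.frame(
      fam = sprintf("S%05d", seq_len(config$nSingletons)), id = ids,
      father = NA, mother = NA, sex = 1L + (seq_len(config$nSingletons) %% 2L),
      stringsAsFactors = FALSE)
    founderCount <- founderCount + config$nSingletons
  }
  ped <- do.call(rbind, rows)
  pedigree <- Pedigree(ped)

  H <- .drawHaplotypes(panel, 2L * founderCount, config$cisLinkage)
  isFounder <- is.na(ped$father) & is.na(ped$mother)
  n <- nrow(ped)
  hapA <- matrix(0L, n, nV); hapB <- matrix(0L, n, nV)
  fi <- cumsum(isFounder)
  for (i in which(isFounder)) {
    hapA[i, ] <- H[2L * fi[i] - 1L, ]
    hapB[i, ] <- H[2L * fi[i], ]
  }
  idIndex <- stats::setNames(seq_len(n), ped$id)
  for (i in which(!isFounder)) {
    pa <- idIndex[[ped$father[i]]]; ma <- idIndex[[ped$mother[i]]]
    hapA[i, ] <- if (stats::runif(1) < 0.5) hapA[pa, ] else hapB[pa, ]
    hapB[i, ] <- if (stats::runif(1) < 0.5) hapA[ma, ] else hapB[ma, ]
  }
  trueDosage <- t(hapA + hapB)  # variants x samples
  dimnames(trueDosage) <- list(panel$label, ped$id)

  qual <- .panelQualifying(panel)
  truth <- .truthCategories(hapA, hapB, qual, panel$label, ped)

  # observed matrix + QC channels
  obs <- trueDosage
  depth <- matrix(15 + stats::rpois(length(obs), 25), nrow(obs))
  ab <- matrix(NA_real_, nrow(obs), ncol(obs))
  ab[obs == 0L] <- stats::runif(sum(obs == 0L), 0, 0.02)
  ab[obs == 1L] <- pmin(pmax(stats::rnorm(sum(obs == 1L), 0.5, 0.05),
                             0.2), 0.8)
  ab[obs == 2L] <- stats::runif(sum(obs == 2L), 0.92, 1)
  hetCalls <- which(obs == 1L)
  corrupt <- hetCalls[stats::runif(length(hetCalls)) < config$qcHetHomProb]
  if (length(corrupt)) {
    obs[corrupt] <- 2L
    depth[corrupt] <- floor(stats::runif(length(corrupt), 4, 10))
    ab[corrupt] <- stats::runif(length(corrupt), 0.55, 0.80)
  }
  lowdp <- which(stats::runif(length(obs)) < config$qcLowDepthProb)
  lowdp <- setdiff(lowdp, corrupt)
  depth[lowdp] <- floor(stats::runif(length(lowdp), 3, 10))
  dimnames(depth) <- dimnames(ab) <- dimnames(obs)

  # the simulating population frequency doubles as the external
  # reference-database MAF, so frequency filters see the generative truth
  # rather than cohort sampling noise
  variants <- data.frame(
    chrom = panel$chrom, pos = panel$pos, ref = panel$ref, alt = panel$alt,
    label = panel$label, gene = "NOD2", consequence = panel$consequence,
    votes = panel$votes, maf_external = panel$freq, stringsAsFactors = FALSE)
  ge <- GenotypeExperiment(variants, obs, depth = depth, alleleBalance = ab)

  # haplotype matrices (samples x variants) let tests check true phase
  rownames(hapA) <- rownames(hapB) <- ped$id
  colnames(hapA) <- colnames(hapB) <- panel$label
  list(pedigree = pedigree, genotypes = ge, truth = truth,
       trueDosage = trueDosage, haplotypes = list(A = hapA, B = hapB),
       config = config)
}

.panelQualifying <- function(panel, mafCeiling = 0.05) {
  plof <- panel$consequence %in% PLOF_CONSEQUENCES
  votes <- votesFromString(panel$votes)
  pdns <- panel$consequence == "missense" & rowSums(votes) == 5L
  (plof | pdns) & panel$freq <= mafCeiling
}

.truthCategories <- function(hapA, hapB, qual, labels, ped) {
  qA <- hapA[, qual, drop = FALSE]
  qB <- hapB[, qual, drop = FALSE]
  dos <- qA + qB
  nAlt <- rowSums(dos)
  anyHom <- rowSums(dos == 2L) > 0L
  nHet <- rowSums(dos == 1L)
  category <- rep("REF", nrow(hapA))
  category[nHet == 1L] <- "CARRIER"
  for (i in which(nHet >= 2L & !anyHom)) {
    onA <- qA[i, ] == 1L & qB[i, ] == 0L
    onB <- qB[i, ] == 1L & qA[i, ] == 0L
    category[i] <- if (any(onA) && any(onB)) "CHET_TRANS" else "CIS_ONLY"
  }
  category[anyHom] <- "HOM"
  data.frame(sample = ped$id, family = ped$fam,
             role = ifelse(is.na(ped$father) & is.na(ped$mother),
                           "founder", "offspring"),
             n_alt = nAlt, category = category,
             is_rec = category %in% c("HOM", "CHET_TRANS"),
             stringsAsFactors = FALSE)
}

#' Simulate disease status and diagnosis-code streams
#'
#' Disease is drawn per sample with baseline odds `kappa0/(1-kappa0)`
#' multiplied by `psiHet` for carriers (including carriers of a single
#' multi-variant cis haplotype) or `psiRec` for recessive genotypes
#' (homozygous or true-trans compound het). Affected subjects receive at
#' least two IBD encounter diagnoses on distinct calendar days (satisfying
#' the two-encounter case definition) with onset ages from the configured
#' model — recessive-driven cases 8 years younger by default — plus optional
#' problem-list entries, subtype-conflicting codes, and an anemia comorbidity
#' that precedes the first IBD code in a configurable fraction of subjects.
#' All subjects accrue background (non-IBD) codes.
#'
#' @param cohort output of [simulateCohort()].
#' @return list: `phenotypes` ([PhenotypeTable-class]) and `truth` (the
#'   cohort truth table extended with `affected` and `onset_age`).
#' @export
simulatePhenotypes <- function(cohort) {
  config <- cohort$config
  truth <- cohort$truth
  set.seed(config$seed + 7901L)
  n <- nrow(truth)
  refDate <- as.Date(config$refDate)

  psi <- ifelse(truth$is_rec, config$psiRec,
                ifelse(truth$n_alt >= 1L, config$psiHet, 1))
  odds <- config$kappa0 / (1 - config$kappa0) * psi
  affected <- stats::runif(n) < odds / (1 + odds)

  currentAge <- stats::runif(n, 25, 85)
  onset <- rep(NA_real_, n)
  # onset is drawn from the disease model untruncated above (so group means
  # stay at their configured values); follow-up then extends past onset
  onset[affected] <- pmin(pmax(stats::rnorm(
    sum(affected),
    config$onsetMeanYears - config$recOnsetGapYears * truth$is_rec[affected],
    config$onsetSdYears), 2), 80)
  currentAge[affected] <- pmax(currentAge[affected], onset[affected] + 0.5)
  birth <- refDate - round(currentAge * 365.25)

  ev <- list()
  addEvents <- function(sample, system, code, date, source)
    ev[[length(ev) + 1L]] <<- data.frame(
      sample = sample, system = system, code = code, date = date,
      source = source, stringsAsFactors = FALSE)

  cdSubtype <- truth$is_rec | (stats::runif(n) < config$cdFraction)
  affection <- rep("unaffected", n)
  affection[affected] <- ifelse(cdSubtype[affected], "CD", "UC")

  cdCodes10 <- c("K50.0", "K50.1", "K50.9")
  ucCodes10 <- c("K51.0", "K51.9")
  cdCodes9 <- c("555.0", "555.9"); ucCodes9 <- c("556.9", "556.5")
  bgCodes <- c("I10", "E11.9", "J06.9", "M54.5", "R51.9", "Z00.0",
               "H52.4", "F41.9")

  for (i in which(affected)) {
    onsetDate <- birth[i] + round(onset[i] * 365.25)
    nEv <- 2L + stats::rpois(1, config$ibdEventsMean)
    dates <- onsetDate + c(0, cumsum(ceiling(stats::runif(nEv - 1, 30, 400))))
    icd9 <- stats::runif(nEv) < config$icd9Prob
    codes <- ifelse(icd9,
                    sample(if (cdSubtype[i]) cdCodes9 else ucCodes9,
                           nEv, replace = TRUE),
                    sample(if (cdSubtype[i]) cdCodes10 else ucCodes10,
                           nEv, replace = TRUE))
    addEvents(truth$sample[i], ifelse(icd9, "ICD9", "ICD10"), codes, dates,
              "encounter")
    if (stats::runif(1) < config$problemListProb)
      addEvents(truth$sample[i], "ICD10",
                if (cdSubtype[i]) "K50.9" else "K51.9", dates[1],
                "problem_list")
    if (stats::runif(1) < config$conflictProb)
      addEvents(truth$sample[i], "ICD10",
                if (cdSubtype[i]) "K51.9" else "K50.9",
                dates[1] + 500, "encounter")
    if (stats::runif(1) < config$anemiaProb) {
      prior <- stats::runif(1) < config$anemiaPriorProb
      lead <- if (prior)
        max(stats::rnorm(1, config$anemiaLeadMeanYears,
                         config$anemiaLeadSdYears), 0)
      else -stats::runif(1, 0.1, 5)
      anemiaDate <- max(onsetDate - round(lead * 365.25), birth[i] + 365)
      addEvents(truth$sample[i], "ICD10", "D50.9", anemiaDate, "encounter")
    }
  }
  nbg <- stats::rpois(n, config$backgroundCodeMean)
  bgIdx <- rep(seq_len(n), nbg)
  if (length(bgIdx)) {
    bgAge <- stats::runif(length(bgIdx), 18,
                          pmax(currentAge[bgIdx] - 0.1, 18.5))
    addEvents(truth$sample[bgIdx], "ICD10",
              sample(bgCodes, length(bgIdx), replace = TRUE),
              birth[bgIdx] + round(bgAge * 365.25), "encounter")
  }

  events <- do.call(rbind, ev)
  subjectsDf <- data.frame(
    sample = truth$sample, birth_date = birth,
    sex = c("1" = "M", "2" = "F")[as.character(
      as.data.frame(cohort$pedigree)$sex)],
    affection = affection, stringsAsFactors = FALSE)
  truth$affected <- affected
  truth$onset_age <- onset
  list(phenotypes = PhenotypeTable(subjectsDf, events), truth = truth)
}

#' Write the simulated cohort to the standard file triplet
#'
#' Emits the VCF, PED, phenotype TSV and truth-table TSV for a simulated
#' cohort, so the file-based pipeline entry points can be exercised.
#'
#' @param cohort output of [simulateCohort()].
#' @param phenotypes a [PhenotypeTable-class] (from [simulatePhenotypes()]).
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly.
#' @export
exportCohort <- function(cohort, phenotypes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             ped = file.path(dir, "cohort.ped"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writeVcfGenotypes(cohort$genotypes, paths[["vcf"]])
  writePedigree(cohort$pedigree, paths[["ped"]])
  writePhenotypes(phenotypes, paths[["phenotypes"]])
  utils::write.table(cohort$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
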