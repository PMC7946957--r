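#' Pipeline configuration
#'
#' Assembles the configuration for [runPipeline()]: either a simulation block
#' or the input file triplet, plus the gene, risk-allele list, frequency and
#' QC thresholds, phasing settings, case definition, and models. Any element
#' can be overridden; unknown names are an error. A YAML file with the same
#' structure can be passed to [runPipeline()] directly.
#'
#' @param ... overrides of the defaults.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    simulate = TRUE,
    sim = list(),                       # overrides for simCohortConfig()
    vcf = NULL, ped = NULL, phenotypes = NULL,
    gene = "NOD2",
    commonRisk = c("p.R702W", "p.G908R", "p.L1007fs"),
    rareMax = 0.02, mafCeiling = 0.05, mafInclusive = TRUE,
    classSets = c("plof_only", "plof_plus_pdns"),
    qc = list(minDepth = 10, homAbMin = 0.85, policy = "set_missing"),
    blacklist = defaultCisBlacklist(),
    includePutative = TRUE, transThreshold = 0.95, usePopulation = TRUE,
    caseDef = list(icd9 = c("555", "556"), icd10 = c("K50", "K51"),
                   minDays = 2L),
    phewasPrefixLength = 3L, phewasCorrection = "bonferroni",
    seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown configuration element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "PipelineConfig")
}

#' Run the full recessive-inheritance analysis
#'
#' Orchestrates the pipeline end to end: acquire genotypes (simulated or
#' from the VCF/PED/TSV triplet), classify variants and apply frequency
#' filters, QC suspect homozygous calls, phase candidate compound-het pairs
#' (pedigree first, then population haplotype frequencies), call diplotypes
#' with the cis blacklist, define EHR cases, compute per-variant and
#' composite genetic-model odds ratios plus compound-het and Firth burden
#' results, run the PheWAS, and compare onset ages. Writes TSV outputs, an
#' exclusion-cascade log and a machine-readable run manifest to `outDir`.
#' Deterministic given the seed: two runs with the same configuration
#' produce byte-identical outputs.
#'
#' @param config a [pipelineConfig()] or path to an equivalent YAML file.
#' @param outDir output directory (created if needed).
#' @return list with every intermediate and result object, invisibly.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    config <- do.call(pipelineConfig, raw)
  }
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) message("[pipeline] ", sprintf(...))

  ## 1. inputs
  if (isTRUE(config$simulate)) {
    simCfg <- do.call(simCohortConfig,
                      c(config$sim, list(seed = config$seed)))
    cohort <- simulateCohort(simCfg)
    phen <- simulatePhenotypes(cohort)
    ge <- cohort$genotypes
    pedigree <- cohort$pedigree
    pt <- phen$phenotypes
    truth <- phen$truth
    log("simulated cohort: %d samples, %d variants",
        ncol(ge), nrow(ge))
  } else {
    if (is.null(config$vcf) || is.null(config$phenotypes))
      stop("file-based run needs 'vcf' and 'phenotypes' paths",
           call. = FALSE)
    ge <- readVcfGenotypes(config$vcf)
    pedigree <- if (!is.null(config$ped)) readPedigree(config$ped) else NULL
    pt <- readPhenotypes(config$phenotypes)
    truth <- NULL
    log("loaded cohort: %d samples, %d variants", ncol(ge), nrow(ge))
  }

  ## 2. classification
  mask <- buildClassMask(ge, commonRisk = config$commonRisk,
                         pedigree = pedigree, rareMax = config$rareMax,
                         lowfreqMax = config$mafCeiling)
  qualifying <- selectBurdenVariants(mask, "plof_plus_pdns",
                                     mafCeiling = config$mafCeiling,
                                     inclusive = config$mafInclusive)
  qualifyingPlof <- selectBurdenVariants(mask, "plof_only",
                                         mafCeiling = config$mafCeiling,
                                         inclusive = config$mafInclusive)
  log("qualifying variants: %d (pLoF-only: %d)",
      length(qualifying), length(qualifyingPlof))

  ## 3. genotype QC (pre-QC candidates feed the cascade audit)
  preQc <- .candidateSet(ge, qualifying)
  qc <- qcGenotypes(ge, minDepth = config$qc$minDepth,
                    homAbMin = config$qc$homAbMin,
                    policy = config$qc$policy)
  geQc <- qc$genotypes
  log("QC demoted %d homozygous call(s)", nrow(qc$log))

  ## 4. phasing + diplotypes (per class set and for the composite)
  callFor <- function(q) callDiplotypes(
    geQc, q, pedigree = pedigree, blacklist = config$blacklist,
    includePutative = config$includePutative,
    usePopulation = config$usePopulation,
    transThreshold = config$transThreshold, gene = config$gene)
  dip <- callFor(qualifying)
  dipPlof <- callFor(qualifyingPlof)
  common <- intersect(config$commonRisk, variantInfo(ge)$label)
  dipComposite <- if (length(common)) callFor(common) else NULL

  ## 5. EHR case definition
  caseDef <- do.call(caseDefinition, config$caseDef)
  caseFlags <- defineCases(pt, caseDef)
  log("cases: %d / %d", sum(caseFlags), length(caseFlags))

  ## 6. association
  assocRows <- list()
  for (vlab in common) {
    gc <- buildGenotypeCounts(caseFlags, ge = geQc, variant = vlab,
                              mode = "variant")
    assocRows[[vlab]] <- assocAllModels(gc)
  }
  gcChet <- buildGenotypeCounts(caseFlags, calls = dip$calls,
                                mode = "compound_het",
                                includePutative = config$includePutative)
  assocRows[["compound_het"]] <-
    cbind(exposure = "compound_het", orRecessive(gcChet),
          stringsAsFactors = FALSE)
  if (!is.null(dipComposite)) {
    gcComp <- buildGenotypeCounts(caseFlags, calls = dipComposite$calls,
                                  mode = "burden",
                                  includePutative = config$includePutative,
                                  label = "composite")
    assocRows[["composite"]] <- assocAllModels(gcComp)
  }
  association <- do.call(rbind, assocRows)
  rownames(association) <- NULL

  burdenRows <- list()
  for (cs in config$classSets) {
    calls <- if (cs == "plof_only") dipPlof$calls else dip$calls
    codes <- stats::setNames(
      diplotypeBurdenCode(calls$category, config$includePutative),
      calls$sample)
    for (model in c("additive", "recessive")) {
      key <- paste(cs, model, sep = ".")
      burdenRows[[key]] <- tryCatch(
        burdenTest(codes, caseFlags, model = model, classSet = cs),
        error = function(e) {
          log("burden test %s/%s failed: %s", cs, model,
              conditionMessage(e))
          NULL
        })
    }
  }
  burden <- do.call(rbind, burdenRows)
  if (!is.null(burden)) rownames(burden) <- NULL

  ## 7. PheWAS on the recessive indicator
  indicator <- stats::setNames(dip$calls$burden == 2L, dip$calls$sample)
  phewas <- runPhewas(indicator, pt,
                      prefixLength = config$phewasPrefixLength,
                      correction = config$phewasCorrection)

  ## 8. onset ages: recessive cases vs other cases
  onset <- firstDiagnosisAge(pt, icd9 = config$caseDef$icd9,
                             icd10 = config$caseDef$icd10)
  recCase <- onset$sample %in% names(indicator)[indicator] &
    caseFlags[onset$sample] & !is.na(onset$onset_age)
  otherCase <- !onset$sample %in% names(indicator)[indicator] &
    caseFlags[onset$sample] & !is.na(onset$onset_age)
  onsetCmp <- if (sum(recCase) >= 2 && sum(otherCase) >= 2)
    compareOnsetAge(onset$onset_age[recCase], onset$onset_age[otherCase])
  else NULL

  ## 9. exclusion cascade: the pre-QC candidate set partitioned by outcome
  cascade <- .cascadeAudit(preQc, dip$calls)
  log("cascade: %d initial candidates -> %d retained",
      cascade$n[cascade$step == "initial_candidates"],
      cascade$n[cascade$step == "retained_biallelic"])

  ## 10. outputs
  paths <- c(diplotypes = "diplotypes.tsv", association = "association.tsv",
             burden = "burden.tsv", phewas = "phewas.tsv",
             cascade = "cascade.tsv", qc_log = "qc_log.tsv",
             manifest = "manifest.json")
  paths <- vapply(paths, function(p) file.path(outDir, p), "")
  .writeTsv(dip$calls, paths[["diplotypes"]])
  .writeTsv(association, paths[["association"]])
  if (!is.null(burden)) .writeTsv(burden, paths[["burden"]])
  .writeTsv(phewas, paths[["phewas"]])
  .writeTsv(cascade, paths[["cascade"]])
  .writeTsv(qc$log, paths[["qc_log"]])
  manifest <- list(
    package = "BiallelicBurden",
    version = as.character(utils::packageVersion("BiallelicBurden")),
    seed = config$seed,
    config_hash = configHash(config),
    n_samples = ncol(ge), n_variants = nrow(ge),
    n_cases = sum(caseFlags),
    outputs = as.list(basename(paths)))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(config = config, genotypes = geQc, pedigree = pedigree,
                 phenotypes = pt, truth = truth, mask = mask,
                 qualifying = qualifying, qc = qc, diplotypes = dip,
                 diplotypesPlof = dipPlof, diplotypesComposite = dipComposite,
                 caseFlags = caseFlags, association = association,
                 burden = burden, phewas = phewas, onset = onset,
                 onsetComparison = onsetCmp, cascade = cascade,
                 manifest = manifest, paths = paths))
}

# samples whose raw genotypes put them in recessive candidacy: a hom call or
# two or more het calls at qualifying variants
.candidateSet <- function(ge, qualifying) {
  d <- dosages(ge)[match(qualifying, variantInfo(ge)$label), , drop = FALSE]
  colnames(d)[colSums(d == 2L, na.rm = TRUE) > 0L |
                colSums(d == 1L, na.rm = TRUE) >= 2L]
}

.cascadeAudit <- function(candidates, calls) {
  sub <- calls[match(candidates, calls$sample), , drop = FALSE]
  retained <- sub$category %in% c("HOM", "CHET_CONFIRMED", "CHET_PUTATIVE")
  cis <- sub$category == "CIS_EXCLUDED"
  demoted <- !retained & !cis  # QC or missingness dropped them out
  data.frame(
    step = c("initial_candidates", "excluded_cis", "excluded_qc_or_single",
             "retained_biallelic", "retained_hom", "retained_chet_confirmed",
             "retained_chet_putative"),
    n = c(length(candidates), sum(cis), sum(demoted), sum(retained),
          sum(sub$category == "HOM"), sum(sub$category == "CHET_CONFIRMED"),
          sum(sub$category == "CHET_PUTATIVE")),
    stringsAsFactors = FALSE)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Deterministic configuration hash
#'
#' Polynomial rolling hash (base 131 modulo the Mersenne prime 2^31 - 1) of
#' the deparsed configuration, for the run manifest.
#'
#' @param config any R object.
#' @return 8-character hex string.
#' @export
configHash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Build a fixture cohort reproducing exact genotype counts
#'
#' Constructs a minimal deterministic cohort whose per-variant case/control
#' genotype breakdown equals the given counts exactly, enabling
#' bit-reproducible tests against printed contingency tables. All counts must
#' share the same case and control totals. Cases receive two Crohn's-disease
#' encounter codes on distinct days so the standard case definition
#' recognises them.
#'
#' @param countsList named list of [GenotypeCounts-class]; names become
#'   variant labels (missense, fully deleterious votes, positions in input
#'   order).
#' @return list: `genotypes` ([GenotypeExperiment-class]), `phenotypes`
#'   ([PhenotypeTable-class]), `caseFlags` (named logical).
#' @export
makeFixtureCohort <- function(countsList) {
  stopifnot(length(countsList) >= 1L, !is.null(names(countsList)))
  nCase <- unique(vapply(countsList, function(g) sum(g@cases), 0))
  nCtrl <- unique(vapply(countsList, function(g) sum(g@controls), 0))
  if (length(nCase) != 1L || length(nCtrl) != 1L)
    stop("inconsistent case/control totals across counts", call. = FALSE)
  samples <- c(if (nCase) sprintf("case%06d", seq_len(nCase)),
               if (nCtrl) sprintf("ctrl%06d", seq_len(nCtrl)))
  dosage <- matrix(0L, length(countsList), nCase + nCtrl,
                   dimnames = list(NULL, samples))
  fill <- function(counts) {
    # deterministic layout: rec block first, then het, then ref
    rep(c(2L, 1L, 0L),
        times = counts[c("rec", "het", "ref")])[seq_len(sum(counts))]
  }
  for (i in seq_along(countsList)) {
    gc <- countsList[[i]]
    dosage[i, seq_len(nCase)] <- fill(gc@cases)
    if (nCtrl) dosage[i, nCase + seq_len(nCtrl)] <- fill(gc@controls)
  }
  variants <- data.frame(
    chrom = "16", pos = seq_along(countsList) * 1000L,
    ref = "A", alt = "G", label = names(countsList), gene = "NOD2",
    consequence = "missense", votes = "DDDDD", maf_external = NA_real_,
    stringsAsFactors = FALSE)
  ge <- GenotypeExperiment(variants, dosage)

  isCase <- c(rep(TRUE, nCase), rep(FALSE, nCtrl))
  subjectsDf <- data.frame(
    sample = samples,
    birth_date = rep(as.Date("1970-01-15"), length(samples)),
    sex = rep("M", length(samples)),
    affection = ifelse(isCase, "CD", "unaffected"),
    stringsAsFactors = FALSE)
  caseSamples <- samples[isCase]
  events <- data.frame(
    sample = rep(caseSamples, each = 2L),
    system = rep("ICD10", 2L * length(caseSamples)),
    code = rep("K50.9", 2L * length(caseSamples)),
    date = rep(as.Date(c("2010-03-01", "2010-09-01")),
               times = length(caseSamples)),
    source = rep("encounter", 2L * length(caseSamples)),
    stringsAsFactors = FALSE)
  pt <- PhenotypeTable(subjectsDf, events)
  list(genotypes = ge, phenotypes = pt,
       caseFlags = stats::setNames(isCase, samples))
}
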