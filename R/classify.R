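#' Predicted loss-of-function classification
#'
#' A variant is pLoF iff its consequence is one of [PLOF_CONSEQUENCES]:
#' premature stop gain, start loss, stop loss, canonical splice donor or
#' acceptor disruption, or frameshift. A pure function of the consequence.
#'
#' @param consequence character vector of consequence classes (or a
#'   [GenotypeExperiment-class], whose variant consequences are used).
#' @return logical vector.
#' @examples
#' classifyPlof(c("frameshift", "missense", "synonymous"))
#' @export
classifyPlof <- function(consequence) {
  if (is(consequence, "GenotypeExperiment"))
    consequence <- variantInfo(consequence)$consequence
  consequence %in% PLOF_CONSEQUENCES
}

#' Predicted deleterious missense (pdNS) classification
#'
#' A missense variant is pdNS when the five prediction algorithms (SIFT, LRT,
#' MutationTaster, PolyPhen2-HumDiv, PolyPhen2-HumVar) call it deleterious.
#' The default rule is the conjunction of all five votes; `k` relaxes this to
#' at-least-k-of-five. A missing vote counts as not deleterious.
#'
#' @param ge a [GenotypeExperiment-class], or a data.frame with a
#'   `consequence` column and the five logical vote columns.
#' @param rule `"all_five"` (default) or `"k_of_five"`.
#' @param k vote threshold when `rule = "k_of_five"`.
#' @return logical vector, one entry per variant; always `FALSE` for
#'   non-missense variants.
#' @export
classifyPdns <- function(ge, rule = c("all_five", "k_of_five"), k = 5L) {
  rule <- match.arg(rule)
  v <- if (is(ge, "GenotypeExperiment")) variantInfo(ge) else
    .normalizeVariantTable(ge)
  if (!nrow(v)) return(logical(0))
  votes <- as.matrix(v[PREDICTOR_NAMES])
  votes[is.na(votes)] <- FALSE
  nvotes <- rowSums(votes)
  threshold <- if (rule == "all_five") 5L else as.integer(k)
  unname(v$consequence == "missense" & nvotes >= threshold)
}

#' Cohort minor-allele frequency
#'
#' Alt-allele count over twice the number of non-missing genotyped
#' individuals in scope, per variant. With `foundersOnly = TRUE` the scope is
#' restricted to pedigree founders, so transmitted alleles are not double
#' counted. The alt-allele frequency is returned; fold to the minor allele
#' with `pmin(f, 1 - f)` if needed.
#'
#' @param ge a [GenotypeExperiment-class]
#' @param foundersOnly restrict to pedigree founders?
#' @param pedigree a [Pedigree-class]; required when `foundersOnly`.
#' @return numeric vector of alt-allele frequencies, one per variant.
#'   A variant with zero genotyped individuals in scope is an error.
#' @export
computeMaf <- function(ge, foundersOnly = FALSE, pedigree = NULL) {
  d <- dosages(ge)
  if (foundersOnly) {
    if (is.null(pedigree))
      stop("foundersOnly = TRUE requires a pedigree", call. = FALSE)
    keep <- colnames(d) %in% founders(pedigree)
    d <- d[, keep, drop = FALSE]
  }
  if (!nrow(d)) return(numeric(0))
  n <- rowSums(!is.na(d))
  if (any(n == 0L))
    stop("no genotyped individuals in scope for variant(s): ",
         paste(variantInfo(ge)$label[n == 0L], collapse = ", "),
         call. = FALSE)
  rowSums(d, na.rm = TRUE) / (2 * n)
}

#' Build the per-variant classification mask
#'
#' Combines functional classification and frequency filters into the mask
#' that drives burden-variant selection: pLoF and pdNS flags, the analysis
#' MAF, the rare (`< 0.02`, strict) and low-frequency (`<= 0.05`, inclusive)
#' filters, and a tier assignment (`common_risk` for the configured risk
#' alleles, `rare` for other low-frequency variants, `excluded` above the
#' low-frequency ceiling).
#'
#' MAF precedence: the external reference-database frequency when present,
#' else the cohort frequency (founders only when a pedigree is given) —
#' mirroring a filtering pipeline that consults population control databases
#' first.
#'
#' @param ge a [GenotypeExperiment-class]
#' @param commonRisk character vector of protein labels treated as the
#'   "common" low-frequency risk alleles.
#' @param pedigree optional [Pedigree-class] for founders-only cohort MAF.
#' @param rareMax strict rare-variant ceiling (default 0.02).
#' @param lowfreqMax inclusive low-frequency ceiling (default 0.05).
#' @param pdnsRule,pdnsK forwarded to [classifyPdns()].
#' @param mafSource `"external_first"` (default), `"cohort"` or `"external"`.
#' @return data.frame with one row per variant: `label`, `pos`, `is_plof`,
#'   `is_pdns`, `maf_cohort`, `maf_used`, `passes_rare`, `passes_lowfreq`,
#'   `tier`.
#' @export
buildClassMask <- function(ge,
                           commonRisk = c("p.R702W", "p.G908R", "p.L1007fs"),
                           pedigree = NULL,
                           rareMax = 0.02, lowfreqMax = 0.05,
                           pdnsRule = "all_five", pdnsK = 5L,
                           mafSource = c("external_first", "cohort",
                                         "external")) {
  mafSource <- match.arg(mafSource)
  v <- variantInfo(ge)
  mafCohort <- computeMaf(ge, foundersOnly = !is.null(pedigree),
                          pedigree = pedigree)
  mafCohort <- pmin(mafCohort, 1 - mafCohort)
  mafUsed <- switch(mafSource,
    cohort = mafCohort,
    external = v$maf_external,
    external_first = ifelse(is.na(v$maf_external), mafCohort, v$maf_external))
  if (anyNA(mafUsed))
    stop("external MAF requested but missing for variant(s): ",
         paste(v$label[is.na(mafUsed)], collapse = ", "), call. = FALSE)
  mask <- data.frame(
    label = v$label, pos = v$pos,
    is_plof = classifyPlof(v$consequence),
    is_pdns = classifyPdns(ge, rule = pdnsRule, k = pdnsK),
    maf_cohort = mafCohort,
    maf_used = mafUsed,
    passes_rare = mafUsed < rareMax,
    passes_lowfreq = mafUsed <= lowfreqMax,
    stringsAsFactors = FALSE)
  mask$tier <- ifelse(mask$label %in% commonRisk, "common_risk",
                      ifelse(mask$passes_lowfreq, "rare", "excluded"))
  mask
}

#' Select qualifying variants for the gene burden
#'
#' Applies the variant-class set (`plof_only`, or `plof_plus_pdns` which adds
#' predicted deleterious missense) and the MAF ceiling, returning qualifying
#' variant labels in deterministic position order.
#'
#' @param mask output of [buildClassMask()].
#' @param classSet `"plof_plus_pdns"` (default) or `"plof_only"`.
#' @param mafCeiling frequency ceiling (default 0.05).
#' @param inclusive compare with `<=` (default, "MAF of at most the ceiling")
#'   rather than strict `<`.
#' @return character vector of qualifying variant labels, ordered by position.
#' @export
selectBurdenVariants <- function(mask,
                                 classSet = c("plof_plus_pdns", "plof_only"),
                                 mafCeiling = 0.05, inclusive = TRUE) {
  classSet <- match.arg(classSet)
  inClass <- mask$is_plof |
    (classSet == "plof_plus_pdns" & mask$is_pdns)
  inFreq <- if (inclusive) mask$maf_used <= mafCeiling
            else mask$maf_used < mafCeiling
  keep <- mask[inClass & inFreq, , drop = FALSE]
  keep$label[order(keep$pos)]
}
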