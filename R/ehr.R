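#' IBD case definition over ICD code prefixes
#'
#' The two-encounter EHR rule: a subject is a case iff a problem-list entry
#' matches one of the code prefixes, or matching encounter diagnoses occur on
#' at least `minDays` distinct calendar days. Defaults encode the IBD
#' definition: ICD-9 555* (regional enteritis) / 556* (ulcerative
#' enterocolitis), ICD-10 K50* (Crohn's disease) / K51* (ulcerative colitis),
#' two separate days.
#'
#' @param icd9,icd10 code prefixes per code system.
#' @param minDays minimum distinct calendar days of encounter diagnoses
#'   (default 2).
#' @param sources record sources accepted.
#' @return a `CaseDefinition` list.
#' @export
caseDefinition <- function(icd9 = c("555", "556"), icd10 = c("K50", "K51"),
                           minDays = 2L,
                           sources = c("problem_list", "encounter")) {
  stopifnot(length(icd9) + length(icd10) >= 1L, minDays >= 1L)
  structure(list(icd9 = icd9, icd10 = icd10, minDays = as.integer(minDays),
                 sources = sources),
            class = "CaseDefinition")
}

.matchPrefix <- function(events, icd9, icd10) {
  hit <- rep(FALSE, nrow(events))
  if (length(icd9)) {
    is9 <- events$system == "ICD9"
    for (p in icd9) hit <- hit | (is9 & startsWith(events$code, p))
  }
  if (length(icd10)) {
    is10 <- events$system == "ICD10"
    for (p in icd10) hit <- hit | (is10 & startsWith(events$code, p))
  }
  hit
}

#' Apply a case definition
#'
#' @param pt a [PhenotypeTable-class]
#' @param definition a [caseDefinition()] list.
#' @return named logical vector over all subjects (TRUE = case). Adding
#'   events can only turn non-cases into cases, never the reverse.
#' @export
defineCases <- function(pt, definition = caseDefinition()) {
  s <- subjects(pt)
  e <- diagnosisEvents(pt)
  flags <- stats::setNames(rep(FALSE, nrow(s)), s$sample)
  if (!nrow(e)) return(flags)
  e <- e[e$source %in% definition$sources, , drop = FALSE]
  e <- e[.matchPrefix(e, definition$icd9, definition$icd10), , drop = FALSE]
  if (!nrow(e)) return(flags)
  pl <- unique(e$sample[e$source == "problem_list"])
  enc <- e[e$source == "encounter", , drop = FALSE]
  if (nrow(enc)) {
    days <- tapply(enc$date, enc$sample, function(d) length(unique(d)))
    enough <- names(days)[days >= definition$minDays]
  } else enough <- character()
  flags[unique(c(pl, enough))] <- TRUE
  flags
}

#' Age at first matching diagnosis
#'
#' Age in 365.25-day years at the earliest event matching the prefixes, per
#' subject, with pediatric (< 18 y) and early-onset (< 30 y) flags. Subjects
#' without a matching code get `NA` and reason `"no_matching_code"`. An event
#' predating birth is an error.
#'
#' @param pt a [PhenotypeTable-class]
#' @param icd9,icd10 code prefixes (defaults: the IBD families).
#' @return data.frame: sample, onset_age, pediatric, early_onset, reason.
#' @export
firstDiagnosisAge <- function(pt, icd9 = c("555", "556"),
                              icd10 = c("K50", "K51")) {
  s <- subjects(pt)
  e <- diagnosisEvents(pt)
  e <- e[.matchPrefix(e, icd9, icd10), , drop = FALSE]
  first <- if (nrow(e)) tapply(e$date, e$sample, min) else NULL
  out <- data.frame(sample = s$sample, onset_age = NA_real_,
                    pediatric = NA, early_onset = NA,
                    reason = "no_matching_code", stringsAsFactors = FALSE)
  if (!is.null(first)) {
    i <- match(names(first), s$sample)
    age <- as.numeric(as.Date(first, origin = "1970-01-01") -
                        s$birth_date[i]) / 365.25
    if (any(age < 0))
      stop("diagnosis event predates birth for sample(s): ",
           paste(names(first)[age < 0], collapse = ", "), call. = FALSE)
    out$onset_age[i] <- age
    out$pediatric[i] <- age < 18
    out$early_onset[i] <- age < 30
    out$reason[i] <- ""
  }
  out
}

#' Flag subjects with conflicting disease-subtype codes
#'
#' Subjects carrying codes from both the Crohn's-type (K50*/555*) and
#' ulcerative-colitis-type (K51*/556*) families. Resolution is not attempted
#' (that is a chart-review task); the pipeline only flags the conflict.
#'
#' @param pt a [PhenotypeTable-class]
#' @param cdIcd9,cdIcd10,ucIcd9,ucIcd10 the two prefix families.
#' @return character vector of conflicted sample ids.
#' @export
flagConflictingDiagnoses <- function(pt, cdIcd9 = "555", cdIcd10 = "K50",
                                     ucIcd9 = "556", ucIcd10 = "K51") {
  e <- diagnosisEvents(pt)
  if (!nrow(e)) return(character())
  cd <- unique(e$sample[.matchPrefix(e, cdIcd9, cdIcd10)])
  uc <- unique(e$sample[.matchPrefix(e, ucIcd9, ucIcd10)])
  sort(intersect(cd, uc))
}

#' Lead time between a comorbidity and an index diagnosis
#'
#' Per subject with both code families: lead time in years between the first
#' comorbidity event and the first index event (positive = comorbidity
#' earlier). The summary reports the proportion of subjects whose comorbidity
#' was concurrent or prior (lead >= 0) and the mean lead among those.
#'
#' @param pt a [PhenotypeTable-class]
#' @param indexIcd9,indexIcd10 index-condition prefixes (default IBD).
#' @param comorbidIcd9,comorbidIcd10 comorbidity prefixes (default anemia:
#'   ICD-9 280-285, ICD-10 D50-D64).
#' @return list with `perSample` (sample, lead_years) and `summary`
#'   (n_both, prop_prior, mean_prior_lead).
#' @export
diagnosisLeadTime <- function(pt,
                              indexIcd9 = c("555", "556"),
                              indexIcd10 = c("K50", "K51"),
                              comorbidIcd9 = as.character(280:285),
                              comorbidIcd10 = paste0("D", 50:64)) {
  e <- diagnosisEvents(pt)
  idx <- e[.matchPrefix(e, indexIcd9, indexIcd10), , drop = FALSE]
  com <- e[.matchPrefix(e, comorbidIcd9, comorbidIcd10), , drop = FALSE]
  firstIdx <- tapply(idx$date, idx$sample, min)
  firstCom <- tapply(com$date, com$sample, min)
  both <- intersect(names(firstIdx), names(firstCom))
  lead <- (unclass(firstIdx[both]) - unclass(firstCom[both])) / 365.25
  perSample <- data.frame(sample = both, lead_years = as.numeric(lead),
                          stringsAsFactors = FALSE)
  prior <- perSample$lead_years >= 0
  list(perSample = perSample,
       summary = list(
         n_both = nrow(perSample),
         prop_prior = if (nrow(perSample)) mean(prior) else NA_real_,
         mean_prior_lead = if (any(prior)) mean(perSample$lead_years[prior])
                           else NA_real_))
}
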