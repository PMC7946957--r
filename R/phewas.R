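#' Phenome-wide association scan of a recessive genotype
#'
#' Tests the recessive genotype indicator against every diagnosis-code group
#' in the EHR. Codes are grouped at a configurable prefix length (default 3
#' characters, e.g. `K50.1` under `K50`) within their own code system; each
#' group gets a code-level case definition under the same
#' problem-list-or-two-encounter-days rule, then a 2x2 Fisher exact test
#' against the indicator. Multiple-testing correction is applied across the
#' tested groups (Bonferroni by default). Groups with no code-cases in either
#' arm are skipped.
#'
#' @param indicator named logical vector over samples (TRUE = recessive
#'   genotype); must cover all subjects of `pt`.
#' @param pt a [PhenotypeTable-class]
#' @param prefixLength grouping prefix length (default 3).
#' @param correction `"bonferroni"` or `"bh"` (Benjamini-Hochberg).
#' @param alpha significance level after correction (default 0.05).
#' @param minDays encounter-day threshold of the per-code case definition.
#' @return data.frame sorted by p: code group, system, the 2x2 counts
#'   (exposed/unexposed x case/non-case), odds ratio (cross-product; Haldane
#'   when a cell is zero, flagged), p, adjusted p, significance flag.
#' @export
runPhewas <- function(indicator, pt, prefixLength = 3L,
                      correction = c("bonferroni", "bh"), alpha = 0.05,
                      minDays = 2L) {
  correction <- match.arg(correction)
  s <- subjects(pt)
  if (!all(s$sample %in% names(indicator)))
    stop("indicator must cover every subject", call. = FALSE)
  indicator <- indicator[s$sample]
  e <- diagnosisEvents(pt)
  if (!nrow(e))
    return(data.frame(code = character(), system = character(),
                      n_exp_case = integer(), n_exp_non = integer(),
                      n_unexp_case = integer(), n_unexp_non = integer(),
                      or = numeric(), or_undefined = logical(),
                      p = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  e$group <- substr(e$code, 1L, prefixLength)
  groups <- unique(e[c("system", "group")])

  rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    def <- if (groups$system[i] == "ICD9")
      caseDefinition(icd9 = groups$group[i], icd10 = character(),
                     minDays = minDays)
    else
      caseDefinition(icd9 = character(), icd10 = groups$group[i],
                     minDays = minDays)
    codeCase <- defineCases(pt, def)
    a <- sum(indicator & codeCase);  b <- sum(indicator & !codeCase)
    c_ <- sum(!indicator & codeCase); d <- sum(!indicator & !codeCase)
    if (a + c_ == 0L) next  # no code-cases in either arm
    zero <- a == 0 || b == 0 || c_ == 0 || d == 0
    or <- if (zero) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
          else (a * d) / (b * c_)
    rows[[i]] <- data.frame(
      code = groups$group[i], system = groups$system[i],
      n_exp_case = a, n_exp_non = b, n_unexp_case = c_, n_unexp_non = d,
      or = or, or_undefined = zero,
      p = fisherExactP(matrix(c(a, b, c_, d), 2, byrow = TRUE)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || !nrow(out))
    return(runPhewas(indicator, PhenotypeTable(s), prefixLength))
  out$p_adj <- stats::p.adjust(out$p, method = switch(correction,
                                                      bonferroni = "bonferroni",
                                                      bh = "BH"))
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
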