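#' GenotypeCounts: case/control genotype contingency counts
#'
#' Counts of reference, heterozygous, and recessive (homozygous-alt or
#' compound-het) individuals among cases and controls for one exposure
#' definition (a single variant, the compound-het class, a pooled composite,
#' or a gene burden).
#'
#' @seealso [genotypeCounts()], [buildGenotypeCounts()]
#' @export
setClass("GenotypeCounts",
         representation(cases = "numeric", controls = "numeric",
                        label = "character"))

.validGenotypeCounts <- function(object) {
  msg <- character()
  for (arm in c("cases", "controls")) {
    x <- slot(object, arm)
    if (length(x) != 3L || is.null(names(x)) ||
        !identical(names(x), c("ref", "het", "rec")))
      msg <- c(msg, paste(arm, "must be a named vector c(ref=, het=, rec=)"))
    else if (any(x < 0) || any(x != round(x)))
      msg <- c(msg, paste(arm, "counts must be non-negative integers"))
  }
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeCounts", .validGenotypeCounts)

#' Construct GenotypeCounts
#'
#' @param cases,controls numeric vectors of (ref, het, rec) counts.
#' @param label exposure label (e.g. a variant or class-set name).
#' @return A [GenotypeCounts-class].
#' @examples
#' genotypeCounts(cases = c(857, 116, 11), controls = c(45433, 4727, 145),
#'                label = "p.R702W")
#' @export
genotypeCounts <- function(cases, controls, label = "") {
  nm <- c("ref", "het", "rec")
  new("GenotypeCounts", cases = stats::setNames(as.numeric(cases), nm),
      controls = stats::setNames(as.numeric(controls), nm), label = label)
}

#' @describeIn GenotypeCounts display the 2x3 table
#' @param object a `GenotypeCounts`
#' @export
setMethod("show", "GenotypeCounts", function(object) {
  cat("GenotypeCounts:", object@label, "\n")
  m <- rbind(cases = object@cases, controls = object@controls)
  print(m)
  invisible(NULL)
})

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact hypergeometric summation over all tables with the observed margins
#' whose probability does not exceed the observed table's (the standard
#' two-sided convention); no large-sample approximation.
#'
#' @param tbl 2x2 matrix of non-negative integer counts.
#' @return p-value in (0, 1].
#' @examples
#' fisherExactP(matrix(c(3, 1, 1, 3), 2))  # 34/70
#' @export
fisherExactP <- function(tbl) {
  stopifnot(identical(dim(tbl), c(2L, 2L)), all(tbl >= 0))
  stats::fisher.test(tbl)$p.value
}

#' Score (Pearson chi-square) p-value for a 2x2 table
#'
#' Pearson chi-square without continuity correction — the score test of the
#' corresponding logistic model. This is the convention that reproduces this
#' pipeline's reference association p-values; the exact Fisher p is reported
#' alongside it.
#'
#' @param tbl 2x2 matrix of non-negative counts.
#' @return p-value, or `NA` when a margin is zero.
#' @export
scoreChisqP <- function(tbl) {
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)) return(NA_real_)
  suppressWarnings(stats::chisq.test(tbl, correct = FALSE)$p.value)
}

# core 2x2 machinery: rows = (cases, controls), cols = (exposed, unexposed)
.assoc2x2 <- function(a, b, c, d, model, level = 0.95) {
  tbl <- matrix(c(a, b, c, d), 2, byrow = TRUE,
                dimnames = list(c("case", "control"),
                                c("exposed", "unexposed")))
  zero <- any(tbl == 0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  orH <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  if (zero) {
    or <- ciLow <- ciHigh <- NA_real_
  } else {
    or <- (a * d) / (b * c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)  # Woolf
    ciLow <- or * exp(-z * se)
    ciHigh <- or * exp(z * se)
  }
  data.frame(model = model, or = or, ciLow = ciLow, ciHigh = ciHigh,
             pScore = scoreChisqP(tbl),
             pFisher = fisherExactP(tbl),
             nExposedCases = a, nCases = a + b,
             nExposedControls = c, nControls = c + d,
             undefined = zero, orHaldane = orH,
             method = "fisher_exact", stringsAsFactors = FALSE)
}

#' Additive-model odds ratio
#'
#' Allele-level 2x2: alt alleles `het + 2*rec` versus the remaining
#' chromosomes, per arm. Point estimate is the unconditional cross-product
#' odds ratio, the confidence interval is Woolf (log-normal with
#' `SE = sqrt(sum of reciprocal cells)`), and both the score chi-square and
#' Fisher exact p-values are reported. A zero cell flags the estimate
#' undefined (the Haldane +0.5 odds ratio is reported alongside, never
#' silently substituted).
#'
#' @param gc a [GenotypeCounts-class]
#' @param level confidence level (default 0.95).
#' @return one-row data.frame (model, or, ciLow, ciHigh, pScore, pFisher,
#'   counts, undefined flag, Haldane OR).
#' @export
orAdditive <- function(gc, level = 0.95) {
  ca <- gc@cases; co <- gc@controls
  altCa <- ca[["het"]] + 2 * ca[["rec"]]
  altCo <- co[["het"]] + 2 * co[["rec"]]
  .assoc2x2(altCa, 2 * sum(ca) - altCa, altCo, 2 * sum(co) - altCo,
            "additive", level)
}

#' Genotypic-model odds ratios (heterozygous and homozygous)
#'
#' Two 2x2 tables against the reference-genotype baseline: het vs ref and
#' rec vs ref. With no recessive carriers in either arm the homozygous
#' estimate is undefined (reported NA), matching the convention for a risk
#' allele never observed homozygous in cases.
#'
#' @inheritParams orAdditive
#' @return two-row data.frame (`genotypic_het`, `genotypic_hom`).
#' @export
orGenotypic <- function(gc, level = 0.95) {
  ca <- gc@cases; co <- gc@controls
  rbind(
    .assoc2x2(ca[["het"]], ca[["ref"]], co[["het"]], co[["ref"]],
              "genotypic_het", level),
    .assoc2x2(ca[["rec"]], ca[["ref"]], co[["rec"]], co[["ref"]],
              "genotypic_hom", level))
}

#' Recessive-model odds ratio
#'
#' 2x2 of recessive carriers versus everyone else (ref + het) per arm.
#'
#' @inheritParams orAdditive
#' @return one-row data.frame.
#' @export
orRecessive <- function(gc, level = 0.95) {
  ca <- gc@cases; co <- gc@controls
  .assoc2x2(ca[["rec"]], ca[["ref"]] + ca[["het"]],
            co[["rec"]], co[["ref"]] + co[["het"]],
            "recessive", level)
}

#' Carrier-model odds ratio
#'
#' 2x2 of any-alt carriers (het + rec) versus ref per arm.
#'
#' @inheritParams orAdditive
#' @return one-row data.frame.
#' @export
orCarrier <- function(gc, level = 0.95) {
  ca <- gc@cases; co <- gc@controls
  .assoc2x2(ca[["het"]] + ca[["rec"]], ca[["ref"]],
            co[["het"]] + co[["rec"]], co[["ref"]],
            "carrier", level)
}

#' All genetic-model odds ratios for one exposure
#'
#' @inheritParams orAdditive
#' @return data.frame with additive, genotypic het/hom, recessive and carrier
#'   rows, stamped with the exposure label.
#' @export
assocAllModels <- function(gc, level = 0.95) {
  out <- rbind(orAdditive(gc, level), orGenotypic(gc, level),
               orRecessive(gc, level), orCarrier(gc, level))
  cbind(exposure = gc@label, out, stringsAsFactors = FALSE)
}

#' Tabulate genotype counts from diplotype calls or dosages
#'
#' Builds the case/control x (ref, het, rec) table for one of three exposure
#' definitions:
#'
#' * `"burden"` — the 0/1/2 burden codes of the diplotype calls (the pooled
#'   composite of a set of risk alleles is this mode applied to diplotypes
#'   called on that variant subset);
#' * `"compound_het"` — compound heterozygotes (confirmed, plus putative when
#'   `includePutative`) as the recessive class, no het class;
#' * `"variant"` — a single variant's dosage (het = 1, rec = 2).
#'
#' Diplotype categories partition samples, so no sample can be counted in two
#' exposure classes; the totals are checked against the cohort size.
#'
#' @param caseFlags named logical vector (TRUE = case) covering every sample.
#' @param calls diplotype call data.frame from [callDiplotypes()] (modes
#'   `"burden"` and `"compound_het"`).
#' @param ge a [GenotypeExperiment-class] (mode `"variant"`).
#' @param variant variant label (mode `"variant"`).
#' @param mode exposure definition.
#' @param includePutative count putative compound hets as recessive.
#' @param label exposure label for the result.
#' @return A [GenotypeCounts-class].
#' @export
buildGenotypeCounts <- function(caseFlags, calls = NULL, ge = NULL,
                                variant = NULL,
                                mode = c("burden", "compound_het", "variant"),
                                includePutative = TRUE, label = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("burden", "compound_het")) {
    stopifnot(!is.null(calls))
    miss <- setdiff(calls$sample, names(caseFlags))
    if (length(miss))
      stop("case labels missing for sample(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    flag <- caseFlags[calls$sample]
    if (mode == "burden") {
      code <- diplotypeBurdenCode(calls$category, includePutative)
      cls <- c("ref", "het", "rec")[code + 1L]
    } else {
      chet <- calls$category == "CHET_CONFIRMED" |
        (includePutative & calls$category == "CHET_PUTATIVE")
      cls <- ifelse(chet, "rec", "ref")
    }
    if (is.null(label))
      label <- if (mode == "burden") "burden" else "compound_het"
  } else {
    stopifnot(!is.null(ge), !is.null(variant))
    dos <- dosages(ge)[match(variant, variantInfo(ge)$label), ]
    miss <- setdiff(names(dos), names(caseFlags))
    if (length(miss))
      stop("case labels missing for sample(s): ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    keep <- !is.na(dos)
    flag <- caseFlags[names(dos)[keep]]
    cls <- c("ref", "het", "rec")[dos[keep] + 1L]
    if (is.null(label)) label <- variant
  }
  count3 <- function(x) c(ref = sum(x == "ref"), het = sum(x == "het"),
                          rec = sum(x == "rec"))
  out <- genotypeCounts(cases = count3(cls[flag]),
                        controls = count3(cls[!flag]), label = label)
  stopifnot(sum(out@cases) + sum(out@controls) == length(cls))
  out
}

#' Gene-burden association by Firth logistic regression
#'
#' Regresses case status on the gene-level genotype code: the additive model
#' uses the 0/1/2 code directly, the recessive model an indicator of code 2
#' (biallelic carriers). Estimation is Firth penalized logistic regression
#' ([firthLogistic()]); the result carries the ref/het/rec count breakdown.
#'
#' @param codes integer vector of 0/1/2 burden codes (e.g. the `burden`
#'   column of [callDiplotypes()] calls), named by sample, or a
#'   [GenotypeCounts-class] of grouped counts.
#' @param caseFlags named logical vector (TRUE = case); ignored when `codes`
#'   is a `GenotypeCounts`.
#' @param model `"additive"` or `"recessive"`.
#' @param classSet label describing the variant class set.
#' @param level confidence level.
#' @return one-row data.frame: class set, model, beta, se, or, ci, p (Wald),
#'   iterations, and the genotype-code count breakdown.
#' @export
burdenTest <- function(codes, caseFlags = NULL,
                       model = c("additive", "recessive"),
                       classSet = "", level = 0.95) {
  model <- match.arg(model)
  if (is(codes, "GenotypeCounts")) {
    gc <- codes
    grpCode <- c(0, 1, 2)
    y <- c(gc@cases)
    n <- c(gc@cases + gc@controls)
    counts <- gc
  } else {
    stopifnot(!is.null(caseFlags))
    flag <- caseFlags[names(codes)]
    y <- vapply(0:2, function(k) sum(flag & codes == k), 0)
    n <- vapply(0:2, function(k) sum(codes == k), 0)
    grpCode <- c(0, 1, 2)
    counts <- genotypeCounts(cases = y, controls = n - y, label = classSet)
  }
  x <- if (model == "additive") grpCode else as.numeric(grpCode == 2)
  keep <- n > 0
  fit <- firthLogistic(x[keep], y[keep], trials = n[keep], level = level)
  data.frame(class_set = classSet, model = model,
             beta = unname(fit$coef[2]), se = unname(fit$se[2]),
             or = fit$or, ciLow = fit$ciLow, ciHigh = fit$ciHigh,
             p = fit$p, iterations = fit$iterations,
             cases_ref = counts@cases[["ref"]],
             cases_het = counts@cases[["het"]],
             cases_rec = counts@cases[["rec"]],
             controls_ref = counts@controls[["ref"]],
             controls_het = counts@controls[["het"]],
             controls_rec = counts@controls[["rec"]],
             method = "firth", stringsAsFactors = FALSE)
}

#' Compare age of onset between two groups
#'
#' Two-sample unpaired t test of mean onset age (pooled-variance Student form
#' by default; Welch optional). Zero variance in both groups with equal means
#' returns t = 0, p = 1.
#'
#' @param agesA,agesB numeric vectors (each of length >= 2).
#' @param welch use the Welch unequal-variance form (default FALSE).
#' @return list with `t`, `df`, `p`, `meanA`, `meanB`.
#' @export
compareOnsetAge <- function(agesA, agesB, welch = FALSE) {
  stopifnot(length(agesA) >= 2L, length(agesB) >= 2L)
  if (stats::var(agesA) == 0 && stats::var(agesB) == 0) {
    if (mean(agesA) == mean(agesB))
      return(list(t = 0, df = length(agesA) + length(agesB) - 2L, p = 1,
                  meanA = mean(agesA), meanB = mean(agesB)))
    return(list(t = Inf * sign(mean(agesA) - mean(agesB)),
                df = length(agesA) + length(agesB) - 2L, p = 0,
                meanA = mean(agesA), meanB = mean(agesB)))
  }
  tt <- stats::t.test(agesA, agesB, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanA = mean(agesA), meanB = mean(agesB))
}
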