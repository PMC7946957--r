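#' Default INFO-key mapping for variant annotations
#'
#' Annotations are consumed, not computed: the consequence and the five
#' predictor votes are read from configurable INFO keys in snpEff/dbNSFP
#' style. These are the keys written by [writeVcfGenotypes()].
#'
#' @return named list mapping annotation roles to INFO keys: `gene`, `label`
#'   (protein notation), `consequence`, `votes` (5-character D/T string),
#'   `maf` (external reference-database allele frequency).
#' @export
defaultAnnotationKeys <- function() {
  list(gene = "GENE", label = "AAC", consequence = "CSQ",
       votes = "PRED", maf = "EXTMAF")
}

#' Read genotypes and annotations from a VCF
#'
#' Parses a VCF v4.x file (GT required in FORMAT; DP and AB optional) into a
#' [GenotypeExperiment-class]. Multi-allelic records are split into one
#' variant per alt allele, conserving per-sample non-reference allele counts.
#' Unphased `0/1` and phased `0|1` calls both map to dosage 1: phase
#' separators are deliberately ignored, because phase is derived downstream
#' from pedigrees and population haplotype frequencies.
#'
#' @param path VCF file path.
#' @param annotationKeys INFO-key mapping, see [defaultAnnotationKeys()].
#' @return A [GenotypeExperiment-class]; unknown consequence strings are
#'   mapped to `"other"` with a warning.
#' @seealso [writeVcfGenotypes()]
#' @export
readVcfGenotypes <- function(path, annotationKeys = defaultAnnotationKeys()) {
  sampleIds <- .vcfSampleIds(path)
  vcf <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) stop("malformed VCF ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  nrec <- nrow(vcf@fix)
  if (is.null(nrec) || nrec == 0L)
    return(.emptyGenotypeExperiment(sampleIds))

  fix <- vcf@fix
  info <- fix[, "INFO"]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- .extractNumericFormat(vcf, "DP")
  ab <- .extractNumericFormat(vcf, "AB")

  rows <- vector("list", nrec)
  for (i in seq_len(nrec)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    infoVals <- .parseInfo(info[i])
    alleles <- .parseGtAlleles(gt[i, ])
    for (k in seq_along(alts)) {
      dos <- vapply(alleles, function(a) {
        if (anyNA(a)) NA_integer_ else sum(a == k)
      }, integer(1))
      rows[[i]] <- c(rows[[i]], list(list(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k],
        gene = .infoField(infoVals, annotationKeys$gene, k),
        label = .infoField(infoVals, annotationKeys$label, k),
        consequence = .infoField(infoVals, annotationKeys$consequence, k),
        votes = .infoField(infoVals, annotationKeys$votes, k),
        maf = .infoField(infoVals, annotationKeys$maf, k),
        dosage = dos,
        depth = if (is.null(dp)) NULL else dp[i, ],
        ab = if (is.null(ab)) NULL else ab[i, ])))
    }
  }
  recs <- unlist(rows, recursive = FALSE)
  recs <- recs[!vapply(recs, is.null, logical(1))]

  variants <- data.frame(
    chrom = vapply(recs, `[[`, "", "chrom"),
    pos = vapply(recs, `[[`, 0L, "pos"),
    ref = vapply(recs, `[[`, "", "ref"),
    alt = vapply(recs, `[[`, "", "alt"),
    label = vapply(recs, function(r) .orDefault(r$label, "."), ""),
    gene = vapply(recs, function(r) .orDefault(r$gene, "."), ""),
    consequence = vapply(recs, function(r)
      .orDefault(r$consequence, "other"), ""),
    votes = vapply(recs, function(r) .orDefault(r$votes, "....."), ""),
    maf_external = vapply(recs, function(r)
      suppressWarnings(as.numeric(.orDefault(r$maf, NA))), 0),
    stringsAsFactors = FALSE)

  unknown <- !(variants$consequence %in% CONSEQUENCE_LEVELS)
  if (any(unknown)) {
    warning("unknown consequence string(s) mapped to 'other': ",
            paste(unique(variants$consequence[unknown]), collapse = ", "),
            call. = FALSE)
    variants$consequence[unknown] <- "other"
  }

  dosage <- do.call(rbind, lapply(recs, `[[`, "dosage"))
  colnames(dosage) <- sampleIds
  depth <- if (is.null(dp)) NULL else {
    m <- do.call(rbind, lapply(recs, `[[`, "depth")); colnames(m) <- sampleIds; m
  }
  abal <- if (is.null(ab)) NULL else {
    m <- do.call(rbind, lapply(recs, `[[`, "ab")); colnames(m) <- sampleIds; m
  }
  GenotypeExperiment(variants, dosage, depth = depth, alleleBalance = abal)
}

.vcfSampleIds <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("malformed VCF ", path,
                            ": no #CHROM header line", call. = FALSE)
    if (startsWith(line, "#CHROM")) {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 10L) return(character(0))
      return(fields[-(1:9)])
    }
    if (!startsWith(line, "##") && !startsWith(line, "#CHROM"))
      stop("malformed VCF ", path, ": data before #CHROM header",
           call. = FALSE)
  }
}

.emptyGenotypeExperiment <- function(sampleIds) {
  variants <- data.frame(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         label = character(), gene = character(),
                         consequence = character(), votes = character(),
                         maf_external = numeric(), stringsAsFactors = FALSE)
  dosage <- matrix(integer(), nrow = 0, ncol = length(sampleIds),
                   dimnames = list(NULL, sampleIds))
  GenotypeExperiment(variants, dosage)
}

.extractNumericFormat <- function(vcf, element) {
  fmt <- vcf@gt[, "FORMAT"]
  if (!any(grepl(element, fmt, fixed = TRUE))) return(NULL)
  suppressWarnings(
    vcfR::extract.gt(vcf, element = element, as.numeric = TRUE))
}

.parseInfo <- function(info) {
  if (is.na(info) || info == ".") return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- lapply(kv, function(x) if (length(x) > 1) x[2] else TRUE)
  names(vals) <- vapply(kv, `[[`, "", 1L)
  vals
}

.infoField <- function(infoVals, key, alleleIndex) {
  v <- infoVals[[key]]
  if (is.null(v) || isTRUE(v)) return(NA_character_)
  per <- strsplit(v, ",", fixed = TRUE)[[1]]
  if (length(per) >= alleleIndex) per[alleleIndex] else per[1]
}

.orDefault <- function(x, default) {
  if (is.null(x) || length(x) == 0L || is.na(x)) default else x
}

.parseGtAlleles <- function(gtStrings) {
  lapply(gtStrings, function(g) {
    if (is.na(g)) return(NA_integer_)
    g <- strsplit(g, ":", fixed = TRUE)[[1]][1]
    a <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
    if (any(a == ".")) return(NA_integer_)
    as.integer(a)
  })
}

#' Write a GenotypeExperiment as VCF v4.2
#'
#' Emits one biallelic record per variant (multi-allelic sites are not
#' re-merged), sorted by chromosome and position, with GT (plus DP/AB when QC
#' assays are attached) and the annotation INFO keys that [readVcfGenotypes()]
#' reads back. Dosage `NA` becomes `./.`.
#'
#' @param ge a [GenotypeExperiment-class]
#' @param path output file path.
#' @param annotationKeys INFO-key mapping, see [defaultAnnotationKeys()].
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(ge, path,
                              annotationKeys = defaultAnnotationKeys()) {
  v <- variantInfo(ge)
  d <- dosages(ge)
  dp <- depths(ge)
  ab <- alleleBalances(ge)
  k <- annotationKeys

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Gene symbol\">", k$gene),
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Protein notation\">", k$label),
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Functional consequence\">", k$consequence),
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Deleteriousness votes %s (D/T)\">",
            k$votes, paste(PREDICTOR_NAMES, collapse = ",")),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"External reference MAF\">", k$maf),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AB,Number=1,Type=Float,Description=\"Alt allele balance\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(d)), collapse = "\t"))

  if (nrow(v)) {
    ord <- order(.chromRank(v$chrom), v$pos)
    v <- v[ord, , drop = FALSE]
    d <- d[ord, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[ord, , drop = FALSE]
    if (!is.null(ab)) ab <- ab[ord, , drop = FALSE]

    votes <- apply(as.matrix(v[PREDICTOR_NAMES]), 1L,
                   function(x) paste(ifelse(x, "D", "T"), collapse = ""))
    info <- sprintf("%s=%s;%s=%s;%s=%s;%s=%s",
                    k$gene, v$gene, k$label, v$label,
                    k$consequence, v$consequence, k$votes, votes)
    hasMaf <- !is.na(v$maf_external)
    info[hasMaf] <- paste0(info[hasMaf], ";", k$maf, "=",
                           format(v$maf_external[hasMaf], digits = 10,
                                  scientific = FALSE, trim = TRUE))
    fmt <- "GT"
    gtOf <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    calls <- matrix(gtOf[as.character(d)], nrow = nrow(d))
    calls[is.na(d)] <- "./."
    if (!is.null(dp)) {
      fmt <- paste0(fmt, ":DP")
      dpc <- matrix(as.character(round(dp)), nrow = nrow(d))
      dpc[is.na(dp)] <- "."
      calls <- matrix(paste(calls, dpc, sep = ":"), nrow = nrow(d))
    }
    if (!is.null(ab)) {
      fmt <- paste0(fmt, ":AB")
      abc <- matrix(format(ab, digits = 4, trim = TRUE), nrow = nrow(d))
      abc[is.na(ab)] <- "."
      calls <- matrix(paste(calls, abc, sep = ":"), nrow = nrow(d))
    }
    body <- vapply(seq_len(nrow(v)), function(i) {
      paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", ".",
              info[i], fmt, calls[i, ]), collapse = "\t")
    }, character(1))
    header <- c(header, body)
  }
  writeLines(header, path)
  invisible(path)
}

.chromRank <- function(chrom) {
  stripped <- sub("^chr", "", chrom)
  rank <- suppressWarnings(as.numeric(stripped))
  rank[stripped %in% c("X")] <- 23
  rank[stripped %in% c("Y")] <- 24
  rank[stripped %in% c("M", "MT")] <- 25
  if (anyNA(rank))
    stop("cannot sort chromosome label(s): ",
         paste(unique(chrom[is.na(rank)]), collapse = ", "), call. = FALSE)
  rank
}
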