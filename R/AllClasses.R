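#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames rowData rowData<- colData
NULL

## Controlled vocabularies -----------------------------------------------------

#' Functional consequence vocabulary
#'
#' The consequence classes recognised by the classifier. Anything else read
#' from an annotation source is mapped to `"other"` with a warning.
#'
#' @export
CONSEQUENCE_LEVELS <- c(
  "missense", "stop_gain", "start_loss", "stop_loss",
  "splice_donor", "splice_acceptor", "frameshift",
  "inframe_indel", "synonymous", "other"
)

#' Consequences counted as predicted loss-of-function
#'
#' Premature stop, start/stop loss, canonical splice-site disruption, and
#' frameshift indels.
#'
#' @export
PLOF_CONSEQUENCES <- c(
  "stop_gain", "start_loss", "stop_loss",
  "splice_donor", "splice_acceptor", "frameshift"
)

#' Deleteriousness predictor panel
#'
#' The five in-silico predictors whose votes define the predicted-deleterious
#' missense (pdNS) class, in their fixed order.
#'
#' @export
PREDICTOR_NAMES <- c("SIFT", "LRT", "MutationTaster",
                     "PolyPhen2_HumDiv", "PolyPhen2_HumVar")

.DIPLOTYPE_CATEGORIES <- c("REF", "CARRIER", "HOM",
                           "CHET_CONFIRMED", "CHET_PUTATIVE", "CIS_EXCLUDED")

## GenotypeExperiment ----------------------------------------------------------

#' GenotypeExperiment: annotated dosage matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one row per
#' (split, biallelic) variant and one column per sample. The `"dosage"` assay
#' stores unphased alt-allele dosage in `{0, 1, 2, NA}`; optional `"depth"`
#' and `"alleleBalance"` assays carry per-call QC values. Row metadata carries
#' the variant annotations: position, alleles, protein label, gene symbol,
#' functional consequence, the five deleteriousness predictor votes, and an
#' optional external reference-database allele frequency.
#'
#' Phase is never stored here: it is a derived annotation produced by the
#' phasing functions.
#'
#' @seealso [GenotypeExperiment()], [readVcfGenotypes()], [dosages()]
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

.validGenotypeExperiment <- function(object) {
  msg <- character()
  if (!"dosage" %in% assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    if (!all(d %in% c(0L, 1L, 2L) | is.na(d)))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  rd <- rowData(object)
  need <- c("chrom", "pos", "ref", "alt", "label", "gene", "consequence",
            PREDICTOR_NAMES)
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("missing variant annotation column(s): ",
                         paste(miss, collapse = ", ")))
  if ("pos" %in% colnames(rd) && nrow(rd) && any(rd$pos < 1))
    msg <- c(msg, "variant positions must be >= 1")
  if (all(c("ref", "alt") %in% colnames(rd)) && nrow(rd) &&
      any(rd$ref == rd$alt))
    msg <- c(msg, "ref and alt alleles must differ")
  if ("consequence" %in% colnames(rd) && nrow(rd) &&
      !all(rd$consequence %in% CONSEQUENCE_LEVELS))
    msg <- c(msg, "unknown consequence level (map unknowns to 'other')")
  if ("maf_external" %in% colnames(rd)) {
    m <- rd$maf_external
    if (any(!is.na(m) & (m < 0 | m > 0.5)))
      msg <- c(msg, "maf_external must lie in [0, 0.5]")
  }
  if (length(msg)) msg else TRUE
}
setValidity("GenotypeExperiment", .validGenotypeExperiment)

#' Construct a GenotypeExperiment
#'
#' @param variants data.frame of variant annotations, one row per biallelic
#'   variant, with columns `chrom`, `pos`, `ref`, `alt`, `label`, `gene`,
#'   `consequence`, the five predictor vote columns (logical; see
#'   [PREDICTOR_NAMES]) and optionally `maf_external`. A `votes` column of
#'   5-character strings (`"D"` deleterious / `"T"` tolerated / `"."` missing,
#'   missing counting as not deleterious) may be given instead of the five
#'   logical columns.
#' @param dosage integer matrix, variants x samples, values in
#'   `{0, 1, 2, NA}`; column names are sample ids.
#' @param depth,alleleBalance optional numeric matrices of the same shape with
#'   per-call read depth and alt-allele balance.
#' @return A [GenotypeExperiment-class] object.
#' @examples
#' v <- data.frame(chrom = "16", pos = 101L, ref = "C", alt = "T",
#'                 label = "p.R702W", gene = "NOD2", consequence = "missense",
#'                 votes = "DDDDD")
#' ge <- GenotypeExperiment(v, matrix(c(0L, 1L, 2L), 1,
#'                          dimnames = list(NULL, c("s1", "s2", "s3"))))
#' dosages(ge)
#' @export
GenotypeExperiment <- function(variants, dosage,
                               depth = NULL, alleleBalance = NULL) {
  variants <- .normalizeVariantTable(variants)
  dosage <- .asDosageMatrix(dosage, nrow(variants))
  assays <- list(dosage = dosage)
  if (!is.null(depth)) assays$depth <- .asShapedMatrix(depth, dim(dosage))
  if (!is.null(alleleBalance))
    assays$alleleBalance <- .asShapedMatrix(alleleBalance, dim(dosage))
  se <- SummarizedExperiment(assays = assays,
                             rowData = DataFrame(variants))
  rownames(se) <- variants$label
  new("GenotypeExperiment", se)
}

.normalizeVariantTable <- function(variants) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if ("votes" %in% colnames(variants) &&
      !all(PREDICTOR_NAMES %in% colnames(variants))) {
    vm <- votesFromString(variants$votes)
    variants <- cbind(variants[setdiff(colnames(variants), "votes")], vm)
  }
  for (p in PREDICTOR_NAMES) {
    if (!p %in% colnames(variants)) variants[[p]] <- FALSE
    variants[[p]][is.na(variants[[p]])] <- FALSE  # missing vote = tolerated
  }
  if (!"maf_external" %in% colnames(variants))
    variants$maf_external <- NA_real_
  variants$pos <- as.integer(variants$pos)
  variants$chrom <- as.character(variants$chrom)
  variants
}

.asDosageMatrix <- function(dosage, nvar) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (nrow(dosage) != nvar)
    stop("dosage matrix must have one row per variant", call. = FALSE)
  dosage
}

.asShapedMatrix <- function(x, dims) {
  x <- as.matrix(x)
  if (!identical(dim(x), dims))
    stop("QC matrix dimensions must match the dosage matrix", call. = FALSE)
  x
}

#' Decode predictor-vote strings
#'
#' Turns 5-character vote strings (e.g. `"DDDDT"`) into a logical matrix with
#' one column per predictor. `"D"` is a deleterious vote; anything else
#' (including `"."` for a missing prediction) counts as not deleterious.
#'
#' @param votes character vector of 5-character codes.
#' @return logical matrix with columns [PREDICTOR_NAMES].
#' @export
votesFromString <- function(votes) {
  votes <- as.character(votes)
  if (!length(votes))
    return(matrix(logical(0), 0, 5,
                  dimnames = list(NULL, PREDICTOR_NAMES)))
  bad <- !is.na(votes) & nchar(votes) != 5L
  if (any(bad))
    stop("predictor vote strings must have exactly 5 characters: ",
         paste(unique(votes[bad]), collapse = ", "), call. = FALSE)
  votes[is.na(votes)] <- "....."
  m <- do.call(rbind, strsplit(votes, "", fixed = TRUE)) == "D"
  colnames(m) <- PREDICTOR_NAMES
  m
}

#' @describeIn GenotypeExperiment compact display
#' @param object a `GenotypeExperiment`
#' @export
setMethod("show", "GenotypeExperiment", function(object) {
  cat(sprintf("GenotypeExperiment: %d variant(s) x %d sample(s)\n",
              nrow(object), ncol(object)))
  cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
  if (nrow(object)) {
    rd <- rowData(object)
    cat("genes:", paste(unique(rd$gene), collapse = ", "), "\n")
    cat("consequences:",
        paste(sprintf("%s(%d)", names(table(rd$consequence)),
                      table(rd$consequence)), collapse = " "), "\n")
  }
  invisible(NULL)
})

## Pedigree --------------------------------------------------------------------

#' Pedigree: family structure
#'
#' Individuals with family id, optional father/mother ids, sex, and a derived
#' founder flag (founder iff both parents absent). Parent references must be
#' closed under the id set and parentage must be acyclic.
#'
#' @seealso [Pedigree()], [readPedigree()]
#' @export
setClass("Pedigree", representation(individuals = "data.frame"))

.validPedigree <- function(object) {
  df <- object@individuals
  msg <- character()
  need <- c("fam", "id", "father", "mother", "sex", "founder")
  if (!all(need %in% colnames(df)))
    return(paste("pedigree table needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$id))
    msg <- c(msg, paste("duplicated individual id(s):",
                        paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  for (col in c("father", "mother")) {
    ref <- df[[col]]
    bad <- !is.na(ref) & !(ref %in% df$id)
    if (any(bad))
      msg <- c(msg, paste0(col, " id(s) not present in pedigree: ",
                           paste(unique(ref[bad]), collapse = ", ")))
  }
  if (!length(msg) && nrow(df)) {
    if (.pedigreeHasCycle(df))
      msg <- c(msg, "cyclic parentage: an individual is its own ancestor")
    derived <- is.na(df$father) & is.na(df$mother)
    if (!identical(as.logical(df$founder), derived))
      msg <- c(msg, "founder flag must be TRUE iff both parents are absent")
  }
  if (length(msg)) msg else TRUE
}
setValidity("Pedigree", .validPedigree)

.pedigreeHasCycle <- function(df) {
  # walk up from every individual; a pedigree DAG has depth <= n
  idx <- match(df$id, df$id)
  fa <- match(df$father, df$id)
  mo <- match(df$mother, df$id)
  for (start in idx) {
    frontier <- start
    for (step in seq_len(nrow(df) + 1L)) {
      frontier <- unique(stats::na.omit(c(fa[frontier], mo[frontier])))
      if (!length(frontier)) break
      if (start %in% frontier) return(TRUE)
    }
    if (length(frontier)) return(TRUE)
  }
  FALSE
}

#' Construct a Pedigree
#'
#' @param fam,id,father,mother,sex vectors (or `fam` may be a data.frame with
#'   those columns). Use `NA` or `"0"` for an absent parent; sex is 1 = male,
#'   2 = female, 0/NA = unknown.
#' @return A [Pedigree-class] object with founder flags derived.
#' @examples
#' trio <- Pedigree(fam = "F1", id = c("dad", "mum", "kid"),
#'                  father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"),
#'                  sex = c(1, 2, 1))
#' founders(trio)
#' @export
Pedigree <- function(fam, id = NULL, father = NULL, mother = NULL, sex = NULL) {
  if (is.data.frame(fam)) {
    df <- fam
  } else {
    df <- data.frame(fam = fam, id = id, father = father, mother = mother,
                     sex = sex, stringsAsFactors = FALSE)
  }
  for (col in c("fam", "id", "father", "mother"))
    df[[col]] <- as.character(df[[col]])
  df$father[df$father %in% c("0", "")] <- NA_character_
  df$mother[df$mother %in% c("0", "")] <- NA_character_
  df$sex <- suppressWarnings(as.integer(df$sex))
  df$founder <- is.na(df$father) & is.na(df$mother)
  rownames(df) <- NULL
  new("Pedigree", individuals = df)
}

#' @describeIn Pedigree compact display
#' @param object a `Pedigree`
#' @export
setMethod("show", "Pedigree", function(object) {
  df <- object@individuals
  cat(sprintf("Pedigree: %d individual(s) in %d family(ies); %d founder(s)\n",
              nrow(df), length(unique(df$fam)), sum(df$founder)))
  invisible(NULL)
})

## PhenotypeTable --------------------------------------------------------------

#' PhenotypeTable: subjects and their diagnosis events
#'
#' Per-subject birth date, sex and affection label (`CD`, `UC`, `IBDU`,
#' `unaffected` or `unknown`), plus a long table of diagnosis events
#' (ICD-9 or ICD-10 code, calendar date, and whether the record came from a
#' problem list or an encounter).
#'
#' @seealso [PhenotypeTable()], [readPhenotypes()], [defineCases()]
#' @export
setClass("PhenotypeTable",
         representation(subjects = "data.frame", events = "data.frame"))

.AFFECTION_LEVELS <- c("CD", "UC", "IBDU", "unaffected", "unknown")

.validPhenotypeTable <- function(object) {
  msg <- character()
  s <- object@subjects; e <- object@events
  if (!all(c("sample", "birth_date", "sex", "affection") %in% colnames(s)))
    msg <- c(msg, "subjects needs columns sample, birth_date, sex, affection")
  if (!all(c("sample", "system", "code", "date", "source") %in% colnames(e)))
    msg <- c(msg, "events needs columns sample, system, code, date, source")
  if (!length(msg)) {
    if (anyDuplicated(s$sample))
      msg <- c(msg, "duplicated subject sample id")
    if (nrow(e) && !all(e$sample %in% s$sample))
      msg <- c(msg, "every diagnosis event must belong to a known subject")
    if (nrow(e) && any(is.na(e$date)))
      msg <- c(msg, "event dates must be valid calendar dates")
    if (nrow(e) && any(!nzchar(e$code) | is.na(e$code)))
      msg <- c(msg, "event codes must be non-empty")
    if (nrow(s) && !all(s$affection %in% .AFFECTION_LEVELS))
      msg <- c(msg, paste("affection labels must be one of:",
                          paste(.AFFECTION_LEVELS, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
}
setValidity("PhenotypeTable", .validPhenotypeTable)

#' Construct a PhenotypeTable
#'
#' @param subjects data.frame with columns `sample`, `birth_date` (Date or
#'   parseable string), `sex`, and optionally `affection` (defaults to
#'   `"unknown"`).
#' @param events data.frame with columns `sample`, `system` (`"ICD9"` or
#'   `"ICD10"`), `code`, `date`, `source` (`"problem_list"` or `"encounter"`).
#'   May be empty.
#' @return A [PhenotypeTable-class] object.
#' @export
PhenotypeTable <- function(subjects, events = NULL) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  subjects$sample <- as.character(subjects$sample)
  subjects$birth_date <- as.Date(subjects$birth_date)
  if (!"affection" %in% colnames(subjects))
    subjects$affection <- "unknown"
  subjects$affection[is.na(subjects$affection)] <- "unknown"
  if (is.null(events) || !nrow(as.data.frame(events))) {
    events <- data.frame(sample = character(), system = character(),
                         code = character(), date = as.Date(character()),
                         source = character(), stringsAsFactors = FALSE)
  } else {
    events <- as.data.frame(events, stringsAsFactors = FALSE)
    events$sample <- as.character(events$sample)
    events$code <- as.character(events$code)
    events$date <- as.Date(events$date)
  }
  rownames(subjects) <- rownames(events) <- NULL
  new("PhenotypeTable", subjects = subjects, events = events)
}

#' @describeIn PhenotypeTable compact display
#' @param object a `PhenotypeTable`
#' @export
setMethod("show", "PhenotypeTable", function(object) {
  cat(sprintf("PhenotypeTable: %d subject(s), %d diagnosis event(s)\n",
              nrow(object@subjects), nrow(object@events)))
  if (nrow(object@subjects)) {
    tab <- table(object@subjects$affection)
    cat("affection:",
        paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  }
  invisible(NULL)
})
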