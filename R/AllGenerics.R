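#' Dosage matrix accessor
#'
#' Returns the variants x samples alt-allele dosage matrix (`{0,1,2,NA}`).
#'
#' @param x a [GenotypeExperiment-class]
#' @return integer matrix, one row per variant, one column per sample.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname dosages
#' @export
setMethod("dosages", "GenotypeExperiment", function(x) assay(x, "dosage"))

#' Variant annotation accessor
#'
#' @param x a [GenotypeExperiment-class]
#' @return data.frame of variant annotations (one row per variant).
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @rdname variantInfo
#' @export
setMethod("variantInfo", "GenotypeExperiment",
          function(x) as.data.frame(rowData(x)))

#' Per-call read depth accessor
#'
#' @param x a [GenotypeExperiment-class]
#' @return numeric matrix or NULL when no depth assay is attached.
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))

#' @rdname depths
#' @export
setMethod("depths", "GenotypeExperiment", function(x) {
  if ("depth" %in% assayNames(x)) assay(x, "depth") else NULL
})

#' Per-call allele balance accessor
#'
#' Alt-allele read fraction of each call, when available.
#'
#' @param x a [GenotypeExperiment-class]
#' @return numeric matrix or NULL.
#' @export
setGeneric("alleleBalances", function(x) standardGeneric("alleleBalances"))

#' @rdname alleleBalances
#' @export
setMethod("alleleBalances", "GenotypeExperiment", function(x) {
  if ("alleleBalance" %in% assayNames(x)) assay(x, "alleleBalance") else NULL
})

#' Founder ids of a pedigree
#'
#' @param x a [Pedigree-class]
#' @return character vector of individual ids with both parents absent.
#' @export
setGeneric("founders", function(x) standardGeneric("founders"))

#' @rdname founders
#' @export
setMethod("founders", "Pedigree",
          function(x) x@individuals$id[x@individuals$founder])

#' Parents of an individual
#'
#' @param x a [Pedigree-class]
#' @param id individual id
#' @return named character vector `c(father = ..., mother = ...)`; `NA` for an
#'   absent parent. Errors if `id` is not in the pedigree.
#' @export
setGeneric("parentsOf", function(x, id) standardGeneric("parentsOf"))

#' @rdname parentsOf
#' @export
setMethod("parentsOf", "Pedigree", function(x, id) {
  df <- x@individuals
  i <- match(id, df$id)
  if (is.na(i)) stop("individual not in pedigree: ", id, call. = FALSE)
  c(father = df$father[i], mother = df$mother[i])
})

#' @rdname Pedigree-class
#' @param x a `Pedigree`
#' @param ... unused
#' @export
setMethod("as.data.frame", "Pedigree", function(x, ...) x@individuals)

#' Subject table accessor
#'
#' @param x a [PhenotypeTable-class]
#' @return data.frame of subjects (sample, birth_date, sex, affection).
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname subjects
#' @export
setMethod("subjects", "PhenotypeTable", function(x) x@subjects)

#' Diagnosis event accessor
#'
#' @param x a [PhenotypeTable-class]
#' @return long data.frame of diagnosis events.
#' @export
setGeneric("diagnosisEvents", function(x) standardGeneric("diagnosisEvents"))

#' @rdname diagnosisEvents
#' @export
setMethod("diagnosisEvents", "PhenotypeTable", function(x) x@events)
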