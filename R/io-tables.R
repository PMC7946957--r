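#' Read a 6-column PED/FAM pedigree file
#'
#' Whitespace-delimited columns: family, individual, father, mother, sex,
#' phenotype. `"0"` marks an absent parent. The phenotype column is ignored
#' (phenotypes come from a [PhenotypeTable-class]). Founder flags are derived:
#' founder iff both parents absent. Duplicated ids, parent ids missing from
#' the file, and cyclic parentage are errors.
#'
#' @param path PED/FAM file path.
#' @return A [Pedigree-class].
#' @export
readPedigree <- function(path) {
  df <- utils::read.table(path, header = FALSE, colClasses = "character",
                          col.names = c("fam", "id", "father", "mother",
                                        "sex", "phenotype"))
  Pedigree(df[c("fam", "id", "father", "mother", "sex")])
}

#' Write a pedigree as a 6-column PED/FAM file
#'
#' The phenotype column is written as `-9` (unknown).
#'
#' @param pedigree a [Pedigree-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(pedigree, path) {
  df <- as.data.frame(pedigree)
  out <- data.frame(df$fam, df$id,
                    ifelse(is.na(df$father), "0", df$father),
                    ifelse(is.na(df$mother), "0", df$mother),
                    ifelse(is.na(df$sex), 0L, df$sex),
                    -9L)
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a long-format phenotype/diagnosis TSV
#'
#' Tab-delimited with header: `sample`, `birth_date`, `sex`, `code_system`,
#' `code`, `event_date`, `source`, and optionally `affection`. One row per
#' diagnosis event; a row with an empty `code` registers an event-less
#' subject. Dates must be ISO `YYYY-MM-DD`; an unparseable date is an error
#' reporting the offending line number.
#'
#' @param path TSV path.
#' @return A [PhenotypeTable-class].
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("sample", "birth_date", "sex", "code_system", "code",
            "event_date", "source")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("phenotype table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  hasEvent <- !is.na(df$code) & nzchar(df$code)

  .parseDates <- function(x, what, rows) {
    d <- as.Date(x, format = "%Y-%m-%d")
    bad <- rows & is.na(d) & !is.na(x) & nzchar(x)
    badAll <- rows & is.na(d)
    if (any(badAll))
      stop("unparseable ", what, " at line(s) ",
           paste(which(badAll) + 1L, collapse = ", "), " of ", path,
           call. = FALSE)
    d
  }
  birth <- .parseDates(df$birth_date, "birth_date", rep(TRUE, nrow(df)))
  eventDate <- .parseDates(df$event_date, "event_date", hasEvent)

  first <- !duplicated(df$sample)
  subjectsDf <- data.frame(
    sample = df$sample[first],
    birth_date = birth[first],
    sex = df$sex[first],
    affection = if ("affection" %in% colnames(df))
      df$affection[first] else rep("unknown", sum(first)),
    stringsAsFactors = FALSE)
  subjectsDf$affection[!nzchar(subjectsDf$affection) |
                         is.na(subjectsDf$affection)] <- "unknown"
  eventsDf <- data.frame(
    sample = df$sample[hasEvent],
    system = df$code_system[hasEvent],
    code = df$code[hasEvent],
    date = eventDate[hasEvent],
    source = df$source[hasEvent],
    stringsAsFactors = FALSE)
  PhenotypeTable(subjectsDf, eventsDf)
}

#' Write a PhenotypeTable as a long-format TSV
#'
#' Inverse of [readPhenotypes()]: one row per event; subjects without events
#' get one row with empty code fields.
#'
#' @param pt a [PhenotypeTable-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(pt, path) {
  s <- subjects(pt)
  e <- diagnosisEvents(pt)
  idx <- match(e$sample, s$sample)
  rows <- data.frame(
    sample = e$sample,
    birth_date = as.character(s$birth_date[idx]),
    sex = s$sex[idx],
    code_system = e$system,
    code = e$code,
    event_date = as.character(e$date),
    source = e$source,
    affection = s$affection[idx],
    stringsAsFactors = FALSE)
  eventless <- !(s$sample %in% e$sample)
  if (any(eventless)) {
    rows <- rbind(rows, data.frame(
      sample = s$sample[eventless],
      birth_date = as.character(s$birth_date[eventless]),
      sex = s$sex[eventless],
      code_system = "", code = "", event_date = "", source = "",
      affection = s$affection[eventless], stringsAsFactors = FALSE))
  }
  rows <- rows[order(match(rows$sample, s$sample)), ]
  utils::write.table(rows, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
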