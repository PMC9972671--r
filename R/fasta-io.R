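# FASTA reading/writing with UniProtKB and NCBI description-line dialects.
# Record splitting and wrapping go through Biostrings; the dialect grammar of
# the description line is handled here.

.countHeaderLines <- function(text) {
  sum(grepl("^>", strsplit(text, "\n", fixed = TRUE)[[1]]))
}

# split "Hemoglobin subunit alpha OS=Homo sapiens GN=HBA1 PE=1" into the
# leading free text and a named vector of TAG=value modifiers
.splitHeaderTags <- function(desc) {
  m <- gregexpr("\\b[A-Z]{2}=", desc)[[1]]
  if (m[1] == -1L)
    return(list(lead = trimws(desc), tags = character()))
  starts <- as.integer(m)
  lead <- trimws(substr(desc, 1L, starts[1] - 1L))
  ends <- c(starts[-1] - 1L, nchar(desc))
  tags <- character()
  for (i in seq_along(starts)) {
    piece <- trimws(substr(desc, starts[i], ends[i]))
    code <- substr(piece, 1L, 2L)
    tags[code] <- substr(piece, 4L, nchar(piece))
  }
  list(lead = lead, tags = tags)
}

.parseUniprotHeader <- function(header) {
  if (lengths(gregexpr("|", header, fixed = TRUE)) < 2L ||
      !grepl("^[^|]+\\|[^|]+\\|", header))
    stop("uniprotkb dialect error: header lacks the two 'db|id|entry' separators: ",
         header)
  m <- regexec("^([^|]+)\\|([^|]+)\\|(\\S+)\\s*(.*)$", header)
  parts <- regmatches(header, m)[[1]]
  fields <- list(db = parts[2], unique_identifier = parts[3],
                 entry_name = parts[4])
  split <- .splitHeaderTags(parts[5])
  if (nzchar(split$lead)) fields$protein_name <- split$lead
  tags <- split$tags
  if ("OS" %in% names(tags)) fields$organism_name <- tags[["OS"]]
  if ("GN" %in% names(tags)) fields$gene_name <- tags[["GN"]]
  if ("PE" %in% names(tags)) fields$protein_existence <- as.integer(tags[["PE"]])
  extra <- tags[setdiff(names(tags), c("OS", "GN", "PE"))]
  if (length(extra)) fields$extra_tags <- extra
  fields
}

.parseNcbiHeader <- function(header) {
  accession <- sub("\\s.*$", "", header)
  rest <- trimws(sub("^\\S+\\s*", "", header))
  fields <- list(accession = accession)
  orgMatch <- regexec("\\[([^][]*)\\]\\s*$", rest)
  org <- regmatches(rest, orgMatch)[[1]]
  if (length(org)) {
    fields$organism <- org[2]
    rest <- trimws(sub("\\[[^][]*\\]\\s*$", "", rest))
  }
  if (nzchar(rest)) fields$description <- rest
  fields
}

#' Parse FASTA text into records
#'
#' Splits the text into records at `>` description lines and, for the
#' `uniprotkb` and `ncbi` dialects, parses the description line into named
#' fields. Residues are uppercased; gap symbols are preserved. Optional fields
#' that are absent from a header are absent from `parsedFields`, never empty
#' strings. No record is ever dropped: the number of returned records equals
#' the number of `>` lines.
#'
#' Dialects:
#' * `uniprotkb` — `>db|UniqueIdentifier|EntryName ProteinName OS=... GN=...
#'   PE=N`; modifiers other than `OS`/`GN`/`PE` (e.g. `OX`, `SV`) are retained
#'   verbatim under `extra_tags`.
#' * `ncbi` — `>accession description [organism]`.
#' * `raw` — the header is kept unparsed.
#'
#' @param text FASTA text (the whole file as one string).
#' @param dialect `"raw"`, `"uniprotkb"` or `"ncbi"`.
#' @return list of [FastaRecord-class].
#' @examples
#' recs <- parseFasta(">sp|P69905|HBA_HUMAN Hemoglobin subunit alpha OS=Homo sapiens GN=HBA1 PE=1\nMVLSPADKTN",
#'                    dialect = "uniprotkb")
#' recs[[1]]@parsedFields$unique_identifier  # "P69905"
#' @export
parseFasta <- function(text, dialect = c("raw", "uniprotkb", "ncbi")) {
  dialect <- match.arg(dialect)
  if (!length(text) || !nzchar(trimws(text)))
    stop("FASTA format error: empty input")
  if (!startsWith(trimws(text), ">"))
    stop("FASTA format error: input does not start with '>'")
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(text, tf)
  set <- Biostrings::readBStringSet(tf)
  nHeaders <- .countHeaderLines(text)
  if (length(set) != nHeaders)
    stop(sprintf("FASTA format error: %d '>' lines but %d parsable records",
                 nHeaders, length(set)))
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    fields <- switch(dialect,
      raw       = list(),
      uniprotkb = .parseUniprotHeader(header),
      ncbi      = .parseNcbiHeader(header))
    new("FastaRecord", rawHeader = header, parsedFields = fields,
        residues = toupper(as.character(set[[i]])))
  })
}

#' Read a FASTA file
#'
#' @param file path to a FASTA file.
#' @inheritParams parseFasta
#' @return list of [FastaRecord-class].
#' @export
readFasta <- function(file, dialect = c("raw", "uniprotkb", "ncbi")) {
  parseFasta(paste(readLines(file), collapse = "\n"), dialect)
}

.proteinRecordFromFields <- function(fields, dialect) {
  if (dialect == "uniprotkb") {
    ProteinRecord(
      accessionNumber = fields$unique_identifier,
      entryName = fields$entry_name %||% NA_character_,
      proteinName = fields$protein_name %||% NA_character_,
      organismName = fields$organism_name %||% NA_character_,
      geneName = fields$gene_name %||% NA_character_,
      proteinExistence = fields$protein_existence %||% NA_integer_,
      dbTag = fields$db %||% NA_character_)
  } else {
    ProteinRecord(
      accessionNumber = fields$accession,
      proteinName = fields$description %||% NA_character_,
      organismName = fields$organism %||% NA_character_)
  }
}

.headerForRecord <- function(record, dialect) {
  fields <- record@parsedFields
  if (dialect == "raw" || !length(fields)) return(record@rawHeader)
  header <- if (dialect == "uniprotkb") {
    h <- uniprotHeader(.proteinRecordFromFields(fields, dialect))
    extra <- fields$extra_tags
    if (length(extra))
      h <- paste(h, paste0(names(extra), "=", extra, collapse = " "))
    h
  } else {
    ncbiHeader(.proteinRecordFromFields(fields, dialect))
  }
  sub("^>", "", header)
}

#' Write FASTA records
#'
#' Headers are regenerated from `parsedFields` through the description-line
#' builders ([uniprotHeader()], [ncbiHeader()]) when fields are present;
#' records without parsed fields (and the `raw` dialect) emit `rawHeader`
#' verbatim. Parsing the output back with the same dialect reproduces
#' `parsedFields` and `residues` exactly.
#'
#' @param records list of [FastaRecord-class].
#' @inheritParams parseFasta
#' @param lineWidth residue wrapping width (default 60).
#' @param file optional path; when `NULL` the FASTA text is returned.
#' @return the FASTA text, invisibly when `file` is given.
#' @export
writeFasta <- function(records, dialect = c("raw", "uniprotkb", "ncbi"),
                       lineWidth = 60L, file = NULL) {
  dialect <- match.arg(dialect)
  seqs <- Biostrings::BStringSet(
    vapply(records, function(r) r@residues, character(1)))
  names(seqs) <- vapply(records, .headerForRecord, character(1), dialect)
  tf <- if (is.null(file)) tempfile(fileext = ".fasta") else file
  Biostrings::writeXStringSet(seqs, tf, width = as.integer(lineWidth))
  text <- paste(readLines(tf), collapse = "\n")
  if (is.null(file)) { unlink(tf); text } else invisible(text)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
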