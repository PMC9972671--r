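# Constructors, accessors and column derivation for the alignment model.

#' @rdname Feature-class
#' @param ftype,fstart,fstop,fnote,fscore see the class slots.
#' @return a [Feature-class]
#' @export
Feature <- function(ftype, fstart, fstop, fnote = NA_character_,
                    fscore = NA_real_) {
  new("Feature", ftype = as.character(ftype),
      fstart = as.integer(fstart), fstop = as.integer(fstop),
      fnote = as.character(fnote), fscore = as.numeric(fscore))
}

#' @rdname AlignmentSequence-class
#' @param identifier,accessionNumber,residues,organism,keywords,molecule,features
#'   see the class slots.
#' @param length aligned length; derived from `residues` (gaps included) when
#'   omitted.
#' @return an [AlignmentSequence-class]
#' @export
AlignmentSequence <- function(identifier, residues,
                              accessionNumber = NA_character_,
                              length = NULL, organism = NA_character_,
                              keywords = character(), molecule = "Protein",
                              features = list(), passthrough = character()) {
  if (is.null(length)) length <- nchar(residues)
  new("AlignmentSequence", identifier = as.character(identifier),
      accessionNumber = as.character(accessionNumber),
      residues = as.character(residues), length = as.integer(length),
      organism = as.character(organism), keywords = as.character(keywords),
      molecule = molecule, features = features,
      passthrough = as.character(passthrough))
}

#' @rdname ConstructionMethod-class
#' @param name,approach see the class slots.
#' @return a [ConstructionMethod-class]
#' @export
ConstructionMethod <- function(name, approach) {
  new("ConstructionMethod", name = as.character(name), approach = approach)
}

#' @rdname SubAlignment-class
#' @param name,sequences,constructionMethod see the class slots.
#' @param gapCharacter the gap symbol; detected from the sequences via
#'   [detectGapCharacter()] when omitted.
#' @return a [SubAlignment-class]
#' @export
SubAlignment <- function(sequences, name = "", constructionMethod = NULL,
                         gapCharacter = NULL, passthrough = character()) {
  if (is.null(gapCharacter))
    gapCharacter <- detectGapCharacter(
      vapply(sequences, function(s) s@residues, character(1)))
  new("SubAlignment", name = as.character(name), sequences = sequences,
      constructionMethod = constructionMethod,
      gapCharacter = as.character(gapCharacter),
      passthrough = as.character(passthrough))
}

#' @rdname ScoreFunction-class
#' @param name,kind,scoreMin,scoreMax,optimization see the class slots.
#' @return a [ScoreFunction-class]
#' @export
ScoreFunction <- function(name, kind, scoreMin = NA_real_, scoreMax = NA_real_,
                          optimization = "maximization") {
  new("ScoreFunction", name = as.character(name), kind = kind,
      scoreMin = as.numeric(scoreMin), scoreMax = as.numeric(scoreMax),
      optimization = optimization)
}

#' @rdname Score-class
#' @param value,scoreFunction see the class slots.
#' @return a [Score-class]
#' @export
Score <- function(value, scoreFunction) {
  new("Score", value = as.numeric(value), scoreFunction = scoreFunction)
}

#' @rdname ReliabilityMeasure-class
#' @param name,scoreCutoff,unreliableWhen,scoreMin,scoreMax see the class
#'   slots. `unreliableWhen` has no default and must be given.
#' @return a [ReliabilityMeasure-class]
#' @export
ReliabilityMeasure <- function(name, scoreCutoff, unreliableWhen,
                               scoreMin = NA_real_, scoreMax = NA_real_) {
  new("ReliabilityMeasure", name = as.character(name),
      scoreCutoff = as.numeric(scoreCutoff), unreliableWhen = unreliableWhen,
      scoreMin = as.numeric(scoreMin), scoreMax = as.numeric(scoreMax))
}

#' @rdname AlignmentColumn-class
#' @param atSequenceIndex,column,consensusCharacter,columnWeight,columnScores
#'   see the class slots.
#' @return an [AlignmentColumn-class]
#' @export
AlignmentColumn <- function(atSequenceIndex, column,
                            consensusCharacter = NA_character_,
                            columnWeight = NA_integer_, columnScores = list()) {
  new("AlignmentColumn", atSequenceIndex = as.integer(atSequenceIndex),
      column = as.character(column),
      consensusCharacter = as.character(consensusCharacter),
      columnWeight = as.integer(columnWeight), columnScores = columnScores)
}

#' @rdname Alignment-class
#' @param alignmentId,subAlignments,alignmentScores,columns see the class
#'   slots.
#' @return an [Alignment-class]
#' @export
Alignment <- function(alignmentId, subAlignments = list(),
                      alignmentScores = list(), columns = list()) {
  new("Alignment", alignmentId = as.character(alignmentId),
      subAlignments = subAlignments, alignmentScores = alignmentScores,
      columns = columns)
}

#' @rdname ProteinRecord-class
#' @param accessionNumber,entryName,proteinName,organismName,geneName,proteinExistence,dbTag,ncbiId,pdbIds
#'   see the class slots.
#' @return a [ProteinRecord-class]
#' @export
ProteinRecord <- function(accessionNumber, entryName = NA_character_,
                          proteinName = NA_character_,
                          organismName = NA_character_,
                          geneName = NA_character_,
                          proteinExistence = NA_integer_,
                          dbTag = NA_character_, ncbiId = NA_character_,
                          pdbIds = character()) {
  new("ProteinRecord", accessionNumber = as.character(accessionNumber),
      entryName = as.character(entryName),
      proteinName = as.character(proteinName),
      organismName = as.character(organismName),
      geneName = as.character(geneName),
      proteinExistence = as.integer(proteinExistence),
      dbTag = as.character(dbTag), ncbiId = as.character(ncbiId),
      pdbIds = as.character(pdbIds))
}

# ---- accessors -------------------------------------------------------------

#' @rdname Alignment-class
setMethod("alignmentId", "Alignment", function(x) x@alignmentId)
#' @rdname Alignment-class
setMethod("subAlignments", "Alignment", function(x) x@subAlignments)
#' @rdname Alignment-class
setMethod("alignmentScores", "Alignment", function(x) x@alignmentScores)
#' @rdname SubAlignment-class
setMethod("subAlignmentName", "SubAlignment", function(x) x@name)
#' @rdname SubAlignment-class
setMethod("alignmentSequences", "SubAlignment", function(x) x@sequences)
#' @rdname SubAlignment-class
setMethod("gapCharacter", "SubAlignment", function(x) x@gapCharacter)
#' @rdname SubAlignment-class
setMethod("constructionMethod", "SubAlignment", function(x) x@constructionMethod)
#' @rdname AlignmentSequence-class
setMethod("seqIdentifier", "AlignmentSequence", function(x) x@identifier)
#' @rdname AlignmentSequence-class
setMethod("accessionNumber", "AlignmentSequence", function(x) x@accessionNumber)
#' @rdname AlignmentSequence-class
setMethod("accessionNumber", "ProteinRecord", function(x) x@accessionNumber)
#' @rdname AlignmentSequence-class
setMethod("residues", "AlignmentSequence", function(x) x@residues)
#' @rdname AlignmentSequence-class
setMethod("features", "AlignmentSequence", function(x) x@features)
#' @rdname AlignmentSequence-class
setMethod("moleculeType", "AlignmentSequence", function(x) x@molecule)
#' @rdname Score-class
setMethod("scoreValue", "Score", function(x) x@value)
#' @rdname Score-class
setMethod("scoreFunction", "Score", function(x) x@scoreFunction)

# ---- column derivation -----------------------------------------------------

#' Detect the gap character used by a set of aligned strings
#'
#' The recognized gap alphabet is `-` and `.`; any other symbol is a residue.
#' A gapless alignment defaults to `-`.
#'
#' @param sequences character vector of aligned strings.
#' @return a single character, `"-"` or `"."`.
#' @examples
#' detectGapCharacter(c("AC-", "A-C"))  # "-"
#' @export
detectGapCharacter <- function(sequences) {
  if (!length(sequences)) stop("at least one sequence is required")
  all <- paste(sequences, collapse = "")
  hasDash <- grepl("-", all, fixed = TRUE)
  hasDot  <- grepl(".", all, fixed = TRUE)
  if (hasDash && hasDot)
    stop("mixed gap characters: both '-' and '.' occur in the alignment")
  if (hasDot) "." else "-"
}

#' Consensus character of a column
#'
#' The most frequent non-gap character; ties are broken by lexicographic
#' order of the tied characters (deterministic). An all-gap column yields the
#' gap character itself.
#'
#' @param column string of per-sequence characters.
#' @param gapCharacter the gap symbol.
#' @return a single character.
#' @examples
#' consensusCharacter("AAAC", "-")  # "A"
#' consensusCharacter("AC", "-")    # "A" (lexicographic tie-break)
#' @export
consensusCharacter <- function(column, gapCharacter = "-") {
  if (!length(column) || !nzchar(column)) stop("column must be non-empty")
  chars <- strsplit(column, "", fixed = TRUE)[[1]]
  chars <- chars[chars != gapCharacter]
  if (!length(chars)) return(gapCharacter)
  tab <- table(chars)
  top <- names(tab)[tab == max(tab)]
  sort(top)[1L]
}

#' Derive the columns of a sub-alignment
#'
#' Transposes the aligned sequences into one [AlignmentColumn-class] per
#' position (1-based `atSequenceIndex`), with the consensus character
#' populated.
#'
#' @param sub a [SubAlignment-class] with at least one sequence.
#' @return list of [AlignmentColumn-class], in column order.
#' @examples
#' sub <- SubAlignment(list(AlignmentSequence("s1", "AC"),
#'                          AlignmentSequence("s2", "A-")))
#' vapply(buildColumns(sub), function(col) col@column, character(1))
#' @export
buildColumns <- function(sub) {
  stopifnot(is(sub, "SubAlignment"))
  seqs <- sub@sequences
  if (!length(seqs)) stop("sub-alignment has no sequences")
  lens <- vapply(seqs, function(s) nchar(s@residues), integer(1))
  if (length(unique(lens)) > 1L) {
    off <- seqs[[which(lens != lens[1L])[1L]]]@identifier
    stop(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                 off, lens[lens != lens[1L]][1L], lens[1L]))
  }
  mat <- vapply(seqs, function(s) strsplit(s@residues, "", fixed = TRUE)[[1]],
                character(lens[1L]))
  if (lens[1L] == 1L) mat <- matrix(mat, nrow = 1L)
  lapply(seq_len(lens[1L]), function(i) {
    colStr <- paste(mat[i, ], collapse = "")
    AlignmentColumn(i, colStr,
                    consensusCharacter = consensusCharacter(colStr, sub@gapCharacter))
  })
}

#' Columns of an alignment
#'
#' Returns the materialized `columns` slot when populated, otherwise derives
#' columns from the sub-alignments via [buildColumns()] (concatenated in
#' sub-alignment order).
#'
#' @param alignment an [Alignment-class]
#' @return list of [AlignmentColumn-class]
#' @export
alignmentColumns <- function(alignment) {
  stopifnot(is(alignment, "Alignment"))
  if (length(alignment@columns)) return(alignment@columns)
  unlist(lapply(alignment@subAlignments, buildColumns), recursive = FALSE)
}

# ---- show ------------------------------------------------------------------

setMethod("show", "Alignment", function(object) {
  nseq <- sum(vapply(object@subAlignments, function(s) length(s@sequences),
                     integer(1)))
  cat("Alignment '", object@alignmentId, "': ",
      length(object@subAlignments), " sub-alignment(s), ",
      nseq, " sequence(s), ", length(object@alignmentScores),
      " alignment score(s)\n", sep = "")
})

setMethod("show", "SubAlignment", function(object) {
  len <- if (length(object@sequences)) nchar(object@sequences[[1]]@residues) else 0L
  cat("SubAlignment '", object@name, "': ", length(object@sequences),
      " sequence(s) x ", len, " column(s), gap '", object@gapCharacter,
      "'\n", sep = "")
})

setMethod("show", "AlignmentSequence", function(object) {
  cat(object@molecule, "AlignmentSequence '", object@identifier, "' (",
      object@length, " aligned chars, ", length(object@features),
      " feature(s))\n", sep = "")
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport: verdict", object@verdict, "with",
      length(object@violations), "violation(s);",
      length(object@unreliableColumns), "unreliable column(s)\n")
})
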