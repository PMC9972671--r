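# Column and alignment score functions: column entropy, percent totally
# conserved columns, percent non-gaps, and reliability-based column flagging.

.ENTROPY_COLUMN_MAX <- log2(20)   # 20 standard amino acids; prints as 4.322

.columnChars <- function(column) {
  if (!length(column) || is.na(column) || !nzchar(column))
    stop("column must be non-empty")
  strsplit(column, "", fixed = TRUE)[[1]]
}

#' Shannon entropy of an alignment column
#'
#' Base-2 entropy of the residue frequency distribution, gaps excluded. A
#' single-residue column scores 0; a column in which all 20 standard amino
#' acids appear equally scores `log2(20)`, i.e. 4.322 bits. Only a base-2
#' logarithm over the 20-symbol amino-acid alphabet yields that maximum,
#' which is why gaps are not counted as a 21st symbol.
#'
#' @param column string of per-sequence characters at one position.
#' @param gapCharacter the gap symbol, excluded from the frequency vector.
#' @return entropy in bits.
#' @examples
#' columnEntropy("AAAA")                      # 0
#' columnEntropy("AACC")                      # 1 bit
#' columnEntropy(paste(LETTERS[1:4], collapse = ""))
#' @export
columnEntropy <- function(column, gapCharacter = "-") {
  chars <- .columnChars(column)
  chars <- chars[chars != gapCharacter]
  if (!length(chars))
    stop("entropy is undefined for an all-gap column")
  p <- as.numeric(table(chars)) / length(chars)
  -sum(p * log2(p))
}

#' Totally-conserved score of a column (0 or 1)
#'
#' 1 exactly when every character is identical and none is the gap character:
#' "totally" is read strictly, so any gap breaks conservation.
#'
#' @inheritParams columnEntropy
#' @return 0 or 1.
#' @export
conservedColumnScore <- function(column, gapCharacter = "-") {
  chars <- .columnChars(column)
  if (any(chars == gapCharacter)) return(0)
  if (length(unique(chars)) == 1L) 1 else 0
}

#' Non-gap score of a column (0 or 1)
#'
#' 1 exactly when no character equals the gap character.
#'
#' @inheritParams columnEntropy
#' @return 0 or 1.
#' @export
nonGapColumnScore <- function(column, gapCharacter = "-") {
  chars <- .columnChars(column)
  if (any(chars == gapCharacter)) 0 else 1
}

#' Alignment-level percentage from 0/1 column scores
#'
#' `100 * sum(columnScores) / length(columnScores)`, the whole-alignment
#' counterpart (range 0 to 100) of the binary column scores.
#'
#' @param columnScores numeric vector of 0/1 column scores.
#' @return percentage in `[0, 100]`.
#' @examples
#' alignmentPercentageScore(c(1, 0, 1, 0))  # 50
#' @export
alignmentPercentageScore <- function(columnScores) {
  if (!length(columnScores)) stop("no column scores given")
  100 * sum(columnScores) / length(columnScores)
}

#' Alignment-level entropy
#'
#' Sum of [columnEntropy()] over the columns. The corresponding score
#' function's maximum is `length(columns) * log2(20)` (each column
#' contributes at most 4.322 bits).
#'
#' @param columns character vector of column strings.
#' @inheritParams columnEntropy
#' @return total entropy in bits.
#' @export
alignmentEntropyScore <- function(columns, gapCharacter = "-") {
  if (!length(columns)) stop("no columns given")
  sum(vapply(columns, columnEntropy, numeric(1),
             gapCharacter = gapCharacter))
}

#' Flag unreliable columns under a reliability measure
#'
#' Returns the 1-based indices whose confidence score falls strictly below
#' the cutoff (`below_cutoff` mode) or strictly above it (`above_cutoff`
#' mode); a score equal to the cutoff passes in both modes. Scores outside
#' the measure's declared range are a range violation, not clamped.
#'
#' @param columnScores numeric vector of per-column confidence scores.
#' @param measure a [ReliabilityMeasure-class].
#' @return integer vector of flagged column indices (possibly empty).
#' @examples
#' guidance <- ReliabilityMeasure("GUIDANCE", scoreCutoff = 0.5,
#'                                unreliableWhen = "below_cutoff",
#'                                scoreMin = 0, scoreMax = 1)
#' flagUnreliableColumns(c(0.9, 0.2, 0.95), guidance)  # 2
#' @export
flagUnreliableColumns <- function(columnScores, measure) {
  stopifnot(is(measure, "ReliabilityMeasure"))
  if (!length(columnScores)) return(integer())
  if (!is.na(measure@scoreMin) && any(columnScores < measure@scoreMin))
    stop(sprintf("score %s below the declared minimum %s of measure '%s'",
                 min(columnScores), measure@scoreMin, measure@name))
  if (!is.na(measure@scoreMax) && any(columnScores > measure@scoreMax))
    stop(sprintf("score %s above the declared maximum %s of measure '%s'",
                 max(columnScores), measure@scoreMax, measure@name))
  if (measure@unreliableWhen == "below_cutoff")
    which(columnScores < measure@scoreCutoff)
  else
    which(columnScores > measure@scoreCutoff)
}

#' The built-in score function catalog
#'
#' One entry per built-in metric, each holding the column-level and
#' alignment-level [ScoreFunction-class] definitions (with their bounds), the
#' per-column scorer and the aggregator to the alignment level:
#'
#' * `percent_totally_conserved` — column in `{0, 1}`, alignment in
#'   `[0, 100]`.
#' * `percent_non_gaps` — column in `{0, 1}`, alignment in `[0, 100]`.
#' * `entropy` — column in `[0, log2(20)]` bits, alignment bounded by
#'   `nColumns * log2(20)`.
#'
#' @param nColumns number of columns, used for the entropy alignment-level
#'   maximum; `NA` leaves that bound unset.
#' @return named list of catalog entries.
#' @export
scoreFunctionCatalog <- function(nColumns = NA_integer_) {
  entMax <- if (is.na(nColumns)) NA_real_ else nColumns * .ENTROPY_COLUMN_MAX
  list(
    percent_totally_conserved = list(
      column = ScoreFunction("percent_totally_conserved", "column", 0, 1),
      alignment = ScoreFunction("percent_totally_conserved", "alignment", 0, 100),
      scorer = conservedColumnScore,
      aggregate = alignmentPercentageScore),
    percent_non_gaps = list(
      column = ScoreFunction("percent_non_gaps", "column", 0, 1),
      alignment = ScoreFunction("percent_non_gaps", "alignment", 0, 100),
      scorer = nonGapColumnScore,
      aggregate = alignmentPercentageScore),
    entropy = list(
      column = ScoreFunction("entropy", "column", 0, .ENTROPY_COLUMN_MAX),
      alignment = ScoreFunction("entropy", "alignment", 0, entMax),
      scorer = columnEntropy,
      aggregate = sum)
  )
}

#' Score an alignment with a built-in score function
#'
#' Derives the columns, applies the per-column scorer and aggregates to the
#' alignment level.
#'
#' @param alignment an [Alignment-class].
#' @param functionName a name from [scoreFunctionCatalog()].
#' @param gapCharacter gap symbol; defaults to the first sub-alignment's.
#' @return list with `columnScores` (numeric vector), `alignmentScore`
#'   (a [Score-class] under the catalog's alignment-level function) and
#'   `columnFunction` (the column-level [ScoreFunction-class]).
#' @examples
#' aln <- generateAlignment(nSequences = 3, nColumns = 10,
#'                          conservation = 1, gapRate = 0, seed = 7)
#' scoreAlignment(aln, "percent_totally_conserved")$alignmentScore@value # 100
#' @export
scoreAlignment <- function(alignment, functionName, gapCharacter = NULL) {
  catalog <- scoreFunctionCatalog()
  if (!functionName %in% names(catalog))
    stop("unknown score function '", functionName, "'; available: ",
         paste(names(catalog), collapse = ", "))
  cols <- alignmentColumns(alignment)
  if (!length(cols)) stop("alignment has no columns")
  if (is.null(gapCharacter))
    gapCharacter <- if (length(alignment@subAlignments))
      alignment@subAlignments[[1]]@gapCharacter else "-"
  entry <- scoreFunctionCatalog(nColumns = length(cols))[[functionName]]
  colStrings <- vapply(cols, function(c) c@column, character(1))
  colScores <- vapply(colStrings, entry$scorer, numeric(1),
                      gapCharacter = gapCharacter, USE.NAMES = FALSE)
  list(columnScores = colScores,
       alignmentScore = Score(entry$aggregate(colScores), entry$alignment),
       columnFunction = entry$column)
}
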