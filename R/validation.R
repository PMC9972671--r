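# Native implementation of the alignment correctness rules: the four
# score-bound incorrectness rules, the minimum-cardinality constraints, and
# reliability-based unreliable-column flagging. Equivalent SWRL rule texts
# are exported for users who run an OWL reasoner instead.

.violation <- function(ruleId, subject, detail)
  new("Violation", ruleId = ruleId, subject = subject, detail = detail)

#' @rdname Violation-class
setMethod("ruleId", "Violation", function(x) x@ruleId)
setMethod("show", "Violation", function(object) {
  cat("[", object@ruleId, "] ", object@subject, ": ", object@detail, "\n",
      sep = "")
})

#' @rdname ValidationReport-class
setMethod("verdict", "ValidationReport", function(x) x@verdict)
#' @rdname ValidationReport-class
setMethod("violations", "ValidationReport", function(x) x@violations)
#' @rdname ValidationReport-class
setMethod("unreliableColumns", "ValidationReport", function(x) x@unreliableColumns)

#' Check one score against its function's declared bounds
#'
#' Bounds are inclusive: a score exactly at `scoreMin` or `scoreMax` is
#' correct (a column scoring 1 under a `[0, 1]` function must validate). At
#' most one of the four incorrectness rules can fire for a single score. A
#' function with no declared bound on a side disables that side's check,
#' with a warning.
#'
#' @param score a [Score-class].
#' @param subject label used in the violation report.
#' @return list of [Violation-class] (empty, or exactly one).
#' @examples
#' fn <- ScoreFunction("percent_conserved", "alignment", 0, 100)
#' length(checkScoreBounds(Score(95, fn)))   # 0
#' length(checkScoreBounds(Score(101, fn)))  # 1
#' @export
checkScoreBounds <- function(score, subject = "score") {
  stopifnot(is(score, "Score"))
  fn <- score@scoreFunction
  prefix <- if (fn@kind == "alignment") "alignment_score" else "column_score"
  if (is.na(fn@scoreMin) && is.na(fn@scoreMax)) {
    warning("score function '", fn@name,
            "' declares no bounds; bound check skipped")
    return(list())
  }
  if (!is.na(fn@scoreMax) && score@value > fn@scoreMax)
    return(list(.violation(paste0(prefix, "_gt_max"), subject,
      sprintf("score %s exceeds scoreMax %s of function '%s'",
              .fmtNum(score@value), .fmtNum(fn@scoreMax), fn@name))))
  if (!is.na(fn@scoreMin) && score@value < fn@scoreMin)
    return(list(.violation(paste0(prefix, "_lt_min"), subject,
      sprintf("score %s is below scoreMin %s of function '%s'",
              .fmtNum(score@value), .fmtNum(fn@scoreMin), fn@name))))
  list()
}

#' Check the minimum-cardinality constraints of an alignment
#'
#' An alignment contains at least one sub-alignment; a sub-alignment has at
#' least two alignment sequences.
#'
#' @param alignment an [Alignment-class].
#' @return list of [Violation-class].
#' @export
checkCardinality <- function(alignment) {
  stopifnot(is(alignment, "Alignment"))
  out <- list()
  if (!length(alignment@subAlignments))
    out <- c(out, list(.violation("alignment_min_subalignments",
      alignment@alignmentId,
      "alignment has 0 sub-alignments; at least 1 is required")))
  for (si in seq_along(alignment@subAlignments)) {
    sub <- alignment@subAlignments[[si]]
    n <- length(sub@sequences)
    if (n < 2L)
      out <- c(out, list(.violation("subalignment_min_sequences",
        paste0(alignment@alignmentId, "/",
               if (nzchar(sub@name)) sub@name else paste0("sub", si)),
        sprintf("sub-alignment has %d sequence(s); at least 2 are required", n))))
  }
  out
}

.columnReliabilityScores <- function(alignment, measure) {
  cols <- alignmentColumns(alignment)
  vapply(seq_along(cols), function(i) {
    for (s in cols[[i]]@columnScores)
      if (identical(s@scoreFunction@name, measure@name)) return(s@value)
    stop(sprintf("column %d has no score under reliability measure '%s'",
                 i, measure@name))
  }, numeric(1))
}

#' Flag unreliable columns of an alignment
#'
#' Reads each column's score under the given measure (from the materialized
#' column scores, or from `columnScores` when supplied) and delegates to
#' [flagUnreliableColumns()]. One `unreliable_column` violation is produced
#' per flagged index. Unreliability does not make an alignment incorrect:
#' it marks regions to filter before downstream analysis.
#'
#' @param alignment an [Alignment-class].
#' @param measure a [ReliabilityMeasure-class].
#' @param columnScores optional numeric vector of per-column confidence
#'   scores, overriding the materialized ones.
#' @return list of [Violation-class] with ruleId `unreliable_column`.
#' @export
checkReliability <- function(alignment, measure, columnScores = NULL) {
  if (is.null(columnScores))
    columnScores <- .columnReliabilityScores(alignment, measure)
  flagged <- flagUnreliableColumns(columnScores, measure)
  lapply(flagged, function(i) .violation("unreliable_column",
    sprintf("column %d", i),
    sprintf("confidence %s %s cutoff %s of measure '%s'",
            .fmtNum(columnScores[i]),
            if (measure@unreliableWhen == "below_cutoff") "below" else "above",
            .fmtNum(measure@scoreCutoff), measure@name)))
}

#' Validate an alignment
#'
#' Aggregates, in one deterministic pass: score-bound checks over every
#' alignment-level and column-level score, the minimum-cardinality
#' constraints, unreliable-column flagging per reliability measure, and a
#' schema assertion pass over every relation the model maps to. All problems
#' are reported, never thrown. The verdict is `"correct"` exactly when no
#' violation other than `unreliable_column` entries was found.
#'
#' @param alignment an [Alignment-class].
#' @param registry a [SchemaRegistry-class].
#' @param measures list of [ReliabilityMeasure-class] to apply.
#' @param policy [IriPolicy-class] used for the schema assertion pass.
#' @return a [ValidationReport-class].
#' @examples
#' fn <- ScoreFunction("percent_conserved", "alignment", 0, 100)
#' aln <- generateAlignment(nSequences = 2, nColumns = 6, seed = 1)
#' aln@alignmentScores <- list(Score(95, fn))
#' verdict(validateAlignment(aln))   # "correct"
#' @export
validateAlignment <- function(alignment, registry = builtinSchema(),
                              measures = list(), policy = iriPolicy()) {
  stopifnot(is(alignment, "Alignment"))
  out <- checkCardinality(alignment)
  for (s in seq_along(alignment@alignmentScores))
    out <- c(out, checkScoreBounds(alignment@alignmentScores[[s]],
                                   paste0("alignmentScore[", s, "]")))
  cols <- alignmentColumns(alignment)
  for (i in seq_along(cols))
    for (m in seq_along(cols[[i]]@columnScores))
      out <- c(out, checkScoreBounds(cols[[i]]@columnScores[[m]],
                                     sprintf("column[%d].score[%d]", i, m)))
  unreliable <- integer()
  for (measure in measures) {
    rel <- tryCatch(checkReliability(alignment, measure),
                    error = function(e) e)
    if (inherits(rel, "error")) {
      out <- c(out, list(.violation("schema_assertion",
        paste0("reliability:", measure@name), conditionMessage(rel))))
    } else {
      out <- c(out, rel)
      unreliable <- c(unreliable, vapply(rel, function(v)
        as.integer(sub("^column ", "", v@subject)), integer(1)))
    }
  }
  if (length(alignment@subAlignments) &&
      all(vapply(alignment@subAlignments,
                 function(s) length(s@sequences) > 0L, logical(1)))) {
    schema <- tryCatch(
      graphSchemaViolations(toRdf(alignment, registry, policy), registry),
      error = function(e) list(.violation("schema_assertion",
        alignment@alignmentId, conditionMessage(e))))
    out <- c(out, schema)
  }
  hard <- Filter(function(v) v@ruleId != "unreliable_column", out)
  new("ValidationReport",
      verdict = if (length(hard)) "incorrect" else "correct",
      violations = out,
      unreliableColumns = sort(unique(unreliable)))
}

#' Render a validation report as JSON
#'
#' @param report a [ValidationReport-class].
#' @return a JSON string.
#' @export
reportAsJson <- function(report) {
  as.character(jsonlite::toJSON(list(
    verdict = report@verdict,
    violations = lapply(report@violations, function(v)
      list(rule_id = v@ruleId, subject = v@subject, detail = v@detail)),
    unreliable_columns = report@unreliableColumns
  ), auto_unbox = TRUE, pretty = TRUE))
}

#' Equivalent SWRL rule texts
#'
#' The validator runs natively; these rule texts express the same semantics
#' in SWRL for users who prefer an OWL reasoner with rule support. Names:
#' one generic correctness rule, four incorrectness rules (one per bound
#' violation), and the unreliable-column rule.
#'
#' @return named character vector of rule texts.
#' @export
swrlRuleTexts <- function() {
  c(
    correctness = paste0(
      "Alignment(?a) ^ hasAlignmentScore(?a, ?s) ^ score(?s, ?v) ^ ",
      "hasAlignmentScoreFunction(?s, ?f) ^ scoreMin(?f, ?mn) ^ ",
      "scoreMax(?f, ?mx) ^ swrlb:greaterThanOrEqual(?v, ?mn) ^ ",
      "swrlb:lessThanOrEqual(?v, ?mx) -> CorrectAlignment(?a)"),
    column_score_gt_max = paste0(
      "AlignmentColumn(?c) ^ hasColumnScore(?c, ?s) ^ score(?s, ?v) ^ ",
      "hasColumnScoreFunction(?s, ?f) ^ scoreMax(?f, ?mx) ^ ",
      "swrlb:greaterThan(?v, ?mx) -> IncorrectColumn(?c)"),
    column_score_lt_min = paste0(
      "AlignmentColumn(?c) ^ hasColumnScore(?c, ?s) ^ score(?s, ?v) ^ ",
      "hasColumnScoreFunction(?s, ?f) ^ scoreMin(?f, ?mn) ^ ",
      "swrlb:lessThan(?v, ?mn) -> IncorrectColumn(?c)"),
    alignment_score_gt_max = paste0(
      "Alignment(?a) ^ hasAlignmentScore(?a, ?s) ^ score(?s, ?v) ^ ",
      "hasAlignmentScoreFunction(?s, ?f) ^ scoreMax(?f, ?mx) ^ ",
      "swrlb:greaterThan(?v, ?mx) -> IncorrectAlignment(?a)"),
    alignment_score_lt_min = paste0(
      "Alignment(?a) ^ hasAlignmentScore(?a, ?s) ^ score(?s, ?v) ^ ",
      "hasAlignmentScoreFunction(?s, ?f) ^ scoreMin(?f, ?mn) ^ ",
      "swrlb:lessThan(?v, ?mn) -> IncorrectAlignment(?a)"),
    unreliable_column = paste0(
      "AlignmentColumn(?c) ^ hasColumnScore(?c, ?s) ^ score(?s, ?v) ^ ",
      "hasColumnScoreFunction(?s, ?f) ^ ReliabilityMeasure(?f) ^ ",
      "scoreCutoff(?f, ?k) ^ swrlb:lessThan(?v, ?k) -> UnreliableColumn(?c)")
  )
}
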