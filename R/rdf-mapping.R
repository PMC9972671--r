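# Mapping between the alignment model and SALON RDF triples. Forward and
# inverse relation triples are both materialized so stores without inference
# still answer inverse queries; every entity gets a minted IRI (no blank
# nodes) and every literal is typed per the registry datatype.

.XSD_INTEGER <- paste0(.XSD_NS, "integer")
.XSD_DECIMAL <- paste0(.XSD_NS, "decimal")

.fmtNum <- function(x) {
  if (!is.na(x) && x == round(x) && abs(x) < 1e15)
    return(format(x, scientific = FALSE))
  format(x, digits = 17, scientific = FALSE)
}

.datatypeIri <- function(kind) {
  switch(kind, integer = .XSD_INTEGER, decimal = .XSD_DECIMAL, NA_character_)
}

.kindOfDatatype <- function(dt) {
  if (is.na(dt)) "string"
  else if (dt == .XSD_INTEGER) "integer"
  else if (dt == .XSD_DECIMAL) "decimal"
  else "string"
}

# mutable triple accumulator
.tripleSink <- function(base) {
  env <- new.env(parent = emptyenv())
  env$rows <- list()
  env$base <- base
  env
}

.sinkAdd <- function(sink, s, p, o, type = "iri", dt = NA_character_) {
  sink$rows[[length(sink$rows) + 1L]] <- .tripleRow(s, p, o, type, dt)
}

.sinkType <- function(sink, s, class) {
  .sinkAdd(sink, s, .RDF_TYPE, paste0(sink$base, class))
}

.sinkRel <- function(sink, s, prop, o, inverse = NA_character_) {
  .sinkAdd(sink, s, paste0(sink$base, prop), o)
  if (!is.na(inverse)) .sinkAdd(sink, o, paste0(sink$base, inverse), s)
}

.sinkLit <- function(sink, s, prop, value, kind) {
  if (is.null(value) || length(value) == 0L) return(invisible())
  for (v in value) {
    if (is.na(v)) next
    lex <- if (is.numeric(v)) .fmtNum(v) else as.character(v)
    .sinkAdd(sink, s, paste0(sink$base, prop), lex, "literal",
             .datatypeIri(kind))
  }
}

.scoreFunctionClass <- function(fn) {
  stem <- if (fn@kind == "alignment") "AlignmentScoreFunction"
          else "ColumnScoreFunction"
  if (fn@optimization == "maximization") paste0("Maximization", stem) else stem
}

.scoreFunctionIri <- function(base, fn) {
  # the kind is part of the IRI: an alignment-level and a column-level
  # function may share a name but are distinct individuals
  paste0(base, "function_", fn@kind, "_", .sanitizeLocal(fn@name))
}

.emitScore <- function(sink, ownerIri, score, scoreIri, kind) {
  rel <- if (kind == "alignment") "hasAlignmentScore" else "hasColumnScore"
  fnRel <- if (kind == "alignment") "hasAlignmentScoreFunction"
           else "hasColumnScoreFunction"
  scoreClass <- if (kind == "alignment") "AlignmentScore" else "ColumnScore"
  .sinkType(sink, scoreIri, scoreClass)
  .sinkRel(sink, ownerIri, rel, scoreIri)
  .sinkLit(sink, scoreIri, "score", score@value, "decimal")
  fn <- score@scoreFunction
  fnIri <- .scoreFunctionIri(sink$base, fn)
  .sinkType(sink, fnIri, .scoreFunctionClass(fn))
  .sinkRel(sink, scoreIri, fnRel, fnIri)
  .sinkLit(sink, fnIri, "scoreMin", fn@scoreMin, "decimal")
  .sinkLit(sink, fnIri, "scoreMax", fn@scoreMax, "decimal")
}

.emitColumn <- function(sink, alnIri, col, colIri) {
  .sinkType(sink, colIri, "AlignmentColumn")
  .sinkRel(sink, alnIri, "hasColumn", colIri, "isColumnOf")
  .sinkLit(sink, colIri, "atSequenceIndex", col@atSequenceIndex, "integer")
  .sinkLit(sink, colIri, "column", col@column, "string")
  .sinkLit(sink, colIri, "consensusCharacter", col@consensusCharacter, "short")
  .sinkLit(sink, colIri, "columnWeight", col@columnWeight, "integer")
  for (m in seq_along(col@columnScores))
    .emitScore(sink, colIri, col@columnScores[[m]],
               paste0(colIri, "_score", m), "column")
}

#' Map an alignment to SALON RDF triples
#'
#' Every entity receives an `rdf:type` for its SALON class (the molecule
#' subclass for sequences, the optimization subclass for score functions),
#' every relation is emitted both as the forward property and, where the
#' vocabulary declares one, its inverse, and every populated model field
#' becomes a literal typed per the registry. Columns are taken from the
#' materialized `columns` slot when present, otherwise derived per
#' sub-alignment. Each emitted statement is checked against the schema; the
#' function stops if any assertion fails.
#'
#' @param alignment a valid [Alignment-class] with at least one sub-alignment.
#' @param registry a [SchemaRegistry-class]; default [builtinSchema()].
#' @param policy an [IriPolicy-class]; default the SALON namespace.
#' @return a [TripleGraph-class]
#' @examples
#' aln <- generateAlignment(nSequences = 2, nColumns = 6, seed = 3)
#' graph <- toRdf(aln)
#' @export
toRdf <- function(alignment, registry = builtinSchema(), policy = iriPolicy()) {
  validObject(alignment)
  if (!length(alignment@subAlignments))
    stop("cannot map an alignment with no sub-alignments: ",
         "an Alignment contains at least one SubAlignment")
  base <- policy@base
  alnId <- alignment@alignmentId
  alnIri <- paste0(base, .sanitizeLocal(alnId))
  sink <- .tripleSink(base)
  .sinkType(sink, alnIri, "Alignment")
  for (si in seq_along(alignment@subAlignments)) {
    sub <- alignment@subAlignments[[si]]
    subLocal <- if (nzchar(sub@name)) sub@name else paste0("sub", si)
    subIri <- mintIri(policy, alnId, subLocal)
    .sinkType(sink, subIri, "SubAlignment")
    .sinkRel(sink, alnIri, "hasSubAlignment", subIri, "isSubalignmentOf")
    if (nzchar(sub@name)) .sinkLit(sink, subIri, "subAlignmentName", sub@name, "string")
    .sinkLit(sink, subIri, "gapCharacter", sub@gapCharacter, "short")
    cm <- sub@constructionMethod
    if (!is.null(cm)) {
      cmIri <- mintIri(policy, alnId,
                       paste0(subLocal, "_method_", cm@name))
      .sinkType(sink, cmIri, if (cm@approach == "deterministic")
        "DeterministicApproach" else "StochasticApproach")
      .sinkRel(sink, subIri, "hasConstructionMethod", cmIri)
    }
    for (seq in sub@sequences) {
      seqIri <- mintIri(policy, alnId, seq@identifier)
      .sinkType(sink, seqIri, if (seq@molecule == "DNA")
        "DNAAlignmentSequence" else "ProteinAlignmentSequence")
      .sinkRel(sink, subIri, "hasSequence", seqIri, "isSequenceOf")
      .sinkLit(sink, seqIri, "identifier", seq@identifier, "string")
      .sinkLit(sink, seqIri, "accessionNumber", seq@accessionNumber, "string")
      .sinkLit(sink, seqIri, "sequence", seq@residues, "string")
      .sinkLit(sink, seqIri, "length", seq@length, "integer")
      .sinkLit(sink, seqIri, "organism", seq@organism, "string")
      .sinkLit(sink, seqIri, "keyword", seq@keywords, "string")
      for (fi in seq_along(seq@features)) {
        f <- seq@features[[fi]]
        fIri <- mintIri(policy, alnId, paste0(seq@identifier, "_f", fi))
        .sinkType(sink, fIri, "Feature")
        .sinkRel(sink, seqIri, "hasFeature", fIri, "isFeatureOf")
        .sinkLit(sink, fIri, "FType", f@ftype, "string")
        .sinkLit(sink, fIri, "FStart", f@fstart, "integer")
        .sinkLit(sink, fIri, "FStop", f@fstop, "integer")
        .sinkLit(sink, fIri, "FNote", f@fnote, "string")
        .sinkLit(sink, fIri, "FScore", f@fscore, "decimal")
      }
    }
  }
  if (length(alignment@columns)) {
    for (col in alignment@columns)
      .emitColumn(sink, alnIri, col,
                  mintIri(policy, alnId, paste0("col", col@atSequenceIndex)))
  } else {
    for (si in seq_along(alignment@subAlignments)) {
      sub <- alignment@subAlignments[[si]]
      if (!length(sub@sequences)) next
      subLocal <- if (nzchar(sub@name)) sub@name else paste0("sub", si)
      cols <- buildColumns(sub)
      for (col in cols)
        .emitColumn(sink, alnIri, col,
                    mintIri(policy, alnId,
                            paste0(subLocal, "_col", col@atSequenceIndex)))
    }
  }
  for (s in seq_along(alignment@alignmentScores))
    .emitScore(sink, alnIri, alignment@alignmentScores[[s]],
               mintIri(policy, alnId, paste0("score", s)), "alignment")
  graph <- TripleGraph(do.call(rbind, c(list(.emptyTriples()), sink$rows)), base)
  bad <- graphSchemaViolations(graph, registry)
  if (length(bad))
    stop("schema assertion failed during mapping: ", bad[[1]]@detail)
  graph
}

#' Check every statement of a graph against the schema registry
#'
#' Each triple is tested with [checkAssertion()] using the `rdf:type` of its
#' subject (and, for object properties, of its object). Problems are
#' collected, never thrown.
#'
#' @param graph a [TripleGraph-class]
#' @param registry a [SchemaRegistry-class]
#' @return list of [Violation-class] (empty when the graph conforms)
#' @export
graphSchemaViolations <- function(graph, registry = builtinSchema()) {
  tr <- graph@triples
  base <- graph@baseNamespace
  typeOf <- new.env(parent = emptyenv())
  isType <- tr$predicate == .RDF_TYPE
  for (i in which(isType)) {
    cls <- sub(base, "", tr$object[i], fixed = TRUE)
    if (!exists(tr$subject[i], typeOf)) assign(tr$subject[i], cls, typeOf)
  }
  out <- list()
  bad <- function(ruleId, subject, detail)
    out[[length(out) + 1L]] <<- new("Violation", ruleId = ruleId,
                                    subject = subject, detail = detail)
  classNames <- registry@classes$name
  for (i in seq_len(nrow(tr))) {
    s <- tr$subject[i]; p <- tr$predicate[i]
    if (isType[i]) {
      cls <- sub(base, "", tr$object[i], fixed = TRUE)
      if (!cls %in% classNames)
        bad("schema_assertion", s, paste0("rdf:type names unregistered class '",
                                          cls, "'"))
      next
    }
    if (!startsWith(p, base)) {
      bad("schema_assertion", s, paste0("predicate outside vocabulary: ", p))
      next
    }
    prop <- sub(base, "", p, fixed = TRUE)
    if (!exists(s, typeOf)) {
      bad("schema_assertion", s,
          paste0("subject of ", prop, " has no rdf:type"))
      next
    }
    subjectClass <- get(s, typeOf)
    objectKind <- if (tr$objectType[i] == "iri") {
      if (!exists(tr$object[i], typeOf)) {
        bad("schema_assertion", tr$object[i],
            paste0("object of ", prop, " has no rdf:type"))
        next
      }
      get(tr$object[i], typeOf)
    } else {
      .kindOfDatatype(tr$datatype[i])
    }
    res <- checkAssertion(registry, subjectClass, prop, objectKind)
    if (!res$ok)
      bad("schema_assertion", s, paste0(res$kind, ": ", res$detail))
  }
  out
}

# ---- graph -> model --------------------------------------------------------

.forwardNormalize <- function(tr, base, registry) {
  op <- registry@objectProperties
  inv <- op[op$isInverse, , drop = FALSE]
  extra <- list()
  for (i in seq_len(nrow(inv))) {
    pIri <- paste0(base, inv$name[i])
    fIri <- paste0(base, inv$inverseOf[i])
    hit <- tr$predicate == pIri
    for (j in which(hit))
      extra[[length(extra) + 1L]] <- .tripleRow(tr$object[j], fIri, tr$subject[j])
  }
  if (length(extra)) tr <- rbind(tr, do.call(rbind, extra))
  tr[!duplicated(tr[c("subject", "predicate", "object", "objectType")]), ,
     drop = FALSE]
}

.graphReader <- function(tr, base) {
  list(
    objs = function(s, prop) {
      tr$object[tr$subject == s & tr$predicate == paste0(base, prop) &
                tr$objectType == "iri"]
    },
    lit = function(s, prop) {
      v <- tr$object[tr$subject == s & tr$predicate == paste0(base, prop) &
                     tr$objectType == "literal"]
      if (length(v)) v[1] else NA_character_
    },
    lits = function(s, prop) {
      tr$object[tr$subject == s & tr$predicate == paste0(base, prop) &
                tr$objectType == "literal"]
    },
    typeOf = function(s) {
      v <- tr$object[tr$subject == s & tr$predicate == .RDF_TYPE]
      if (length(v)) sub(base, "", v[1], fixed = TRUE) else NA_character_
    }
  )
}

.readScoreFunction <- function(rd, fnIri, base, kind) {
  name <- sub(paste0("^function_", kind, "_"), "",
              sub(base, "", fnIri, fixed = TRUE))
  cls <- rd$typeOf(fnIri)
  opt <- if (!is.na(cls) && startsWith(cls, "Maximization")) "maximization"
         else "minimization"
  mn <- rd$lit(fnIri, "scoreMin"); mx <- rd$lit(fnIri, "scoreMax")
  ScoreFunction(name, kind,
                scoreMin = if (is.na(mn)) NA_real_ else as.numeric(mn),
                scoreMax = if (is.na(mx)) NA_real_ else as.numeric(mx),
                optimization = opt)
}

.readScore <- function(rd, scoreIri, base, kind) {
  fnRel <- if (kind == "alignment") "hasAlignmentScoreFunction"
           else "hasColumnScoreFunction"
  fnIri <- rd$objs(scoreIri, fnRel)
  fn <- if (length(fnIri)) .readScoreFunction(rd, fnIri[1], base, kind)
        else ScoreFunction("unknown", kind)
  Score(as.numeric(rd$lit(scoreIri, "score")), fn)
}

#' Reconstruct the alignment model from a graph
#'
#' Inverse of [toRdf()]. Inverse relation triples are normalized to their
#' forward form first, so a graph carrying only `isSequenceOf` statements
#' reconstructs identically to one carrying `hasSequence`. Schema
#' violations (unknown predicates, missing `rdf:type`, domain/range
#' mismatches) are collected and returned alongside the model, never dropped.
#'
#' @param graph a [TripleGraph-class]
#' @param registry a [SchemaRegistry-class]
#' @return list with elements `alignment` (an [Alignment-class]) and
#'   `violations` (list of [Violation-class])
#' @export
alignmentFromGraph <- function(graph, registry = builtinSchema()) {
  base <- graph@baseNamespace
  violations <- graphSchemaViolations(graph, registry)
  tr <- .forwardNormalize(graph@triples, base, registry)
  rd <- .graphReader(tr, base)
  alnIris <- unique(tr$subject[tr$predicate == .RDF_TYPE &
                               tr$object == paste0(base, "Alignment")])
  if (!length(alnIris))
    stop("no subject typed as Alignment found in the graph")
  alnIri <- alnIris[1]
  alnId <- sub(base, "", alnIri, fixed = TRUE)
  subs <- lapply(rd$objs(alnIri, "hasSubAlignment"), function(subIri) {
    seqs <- lapply(rd$objs(subIri, "hasSequence"), function(seqIri) {
      res <- rd$lit(seqIri, "sequence")
      if (is.na(res))
        stop("sequence node ", seqIri, " carries no 'sequence' literal")
      feats <- lapply(rd$objs(seqIri, "hasFeature"), function(fIri) {
        fscore <- rd$lit(fIri, "FScore")
        Feature(ftype = rd$lit(fIri, "FType"),
                fstart = as.integer(rd$lit(fIri, "FStart")),
                fstop = as.integer(rd$lit(fIri, "FStop")),
                fnote = rd$lit(fIri, "FNote"),
                fscore = if (is.na(fscore)) NA_real_ else as.numeric(fscore))
      })
      molecule <- if (identical(rd$typeOf(seqIri), "DNAAlignmentSequence"))
        "DNA" else "Protein"
      len <- rd$lit(seqIri, "length")
      AlignmentSequence(
        identifier = rd$lit(seqIri, "identifier"),
        residues = res,
        accessionNumber = rd$lit(seqIri, "accessionNumber"),
        length = if (is.na(len)) NULL else as.integer(len),
        organism = rd$lit(seqIri, "organism"),
        keywords = rd$lits(seqIri, "keyword"),
        molecule = molecule, features = feats)
    })
    cmIri <- rd$objs(subIri, "hasConstructionMethod")
    cm <- if (length(cmIri)) {
      ConstructionMethod(
        name = sub("^.*_method_", "", cmIri[1]),
        approach = if (identical(rd$typeOf(cmIri[1]), "StochasticApproach"))
          "stochastic" else "deterministic")
    } else NULL
    nm <- rd$lit(subIri, "subAlignmentName")
    gap <- rd$lit(subIri, "gapCharacter")
    SubAlignment(sequences = seqs, name = if (is.na(nm)) "" else nm,
                 constructionMethod = cm,
                 gapCharacter = if (is.na(gap)) NULL else gap)
  })
  colIris <- rd$objs(alnIri, "hasColumn")
  columns <- lapply(colIris, function(colIri) {
    scores <- lapply(rd$objs(colIri, "hasColumnScore"), .readScore,
                     rd = rd, base = base, kind = "column")
    w <- rd$lit(colIri, "columnWeight")
    AlignmentColumn(
      atSequenceIndex = as.integer(rd$lit(colIri, "atSequenceIndex")),
      column = rd$lit(colIri, "column"),
      consensusCharacter = rd$lit(colIri, "consensusCharacter"),
      columnWeight = if (is.na(w)) NA_integer_ else as.integer(w),
      columnScores = scores)
  })
  if (length(columns))
    columns <- columns[order(vapply(columns, function(c) c@atSequenceIndex,
                                    integer(1)))]
  alnScores <- lapply(rd$objs(alnIri, "hasAlignmentScore"), .readScore,
                      rd = rd, base = base, kind = "alignment")
  list(
    alignment = Alignment(alignmentId = alnId, subAlignments = subs,
                          alignmentScores = alnScores, columns = columns),
    violations = violations
  )
}

#' Parse an RDF document and reconstruct the alignment model
#'
#' @param text RDF text in one of the four supported serializations.
#' @param format one of `"turtle"`, `"rdfxml"`, `"ntriples"`, `"jsonld"`.
#' @param registry a [SchemaRegistry-class]
#' @param base the namespace the instances were minted under.
#' @return list with elements `alignment` and `violations`; see
#'   [alignmentFromGraph()].
#' @export
fromRdf <- function(text, format, registry = builtinSchema(),
                    base = .SALON_NS) {
  alignmentFromGraph(parseRdf(text, format, base), registry)
}
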