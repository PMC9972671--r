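#' @import methods
NULL

# ---- schema registry -------------------------------------------------------

#' SchemaRegistry: the SALON vocabulary as queryable metadata
#'
#' Holds the SALON classes (with their subclass hierarchy), object properties
#' (with domains, ranges and inverse pairs), data properties (with domains and
#' datatypes) and minimum-cardinality rules, as plain tabular metadata that the
#' RDF mapping and the validator consult.
#'
#' @slot classes data.frame with columns `name`, `parent` (`NA` for top-level
#'   classes) and `topLevel`.
#' @slot objectProperties data.frame with columns `name`, `domain`, `range`,
#'   `inverseOf` (`NA` when the property has no declared inverse).
#' @slot dataProperties data.frame with columns `name`, `domains`
#'   (comma-separated class names) and `datatype` (one of `"string"`,
#'   `"integer"`, `"decimal"`, `"short"`).
#' @slot cardinalityRules data.frame with columns `onClass`, `property`,
#'   `minCount`.
#' @slot aliases named list mapping a domain name that appears only in a
#'   property declaration (e.g. `SequenceAlignment`) to the registered classes
#'   it stands for.
#'
#' @seealso [builtinSchema()], [checkAssertion()]
#' @exportClass SchemaRegistry
setClass("SchemaRegistry",
  representation(
    classes          = "data.frame",
    objectProperties = "data.frame",
    dataProperties   = "data.frame",
    cardinalityRules = "data.frame",
    aliases          = "list"
  )
)

setValidity("SchemaRegistry", function(object) {
  msg <- character()
  cls <- object@classes
  known <- c(cls$name, names(object@aliases))
  bad <- setdiff(stats::na.omit(cls$parent), cls$name)
  if (length(bad))
    msg <- c(msg, paste0("unresolved parent class(es): ", paste(bad, collapse = ", ")))
  # parent relation must be acyclic
  for (nm in cls$name) {
    seen <- character(); cur <- nm
    while (!is.na(cur)) {
      if (cur %in% seen) { msg <- c(msg, paste0("cycle in class hierarchy at ", nm)); break }
      seen <- c(seen, cur)
      cur <- cls$parent[match(cur, cls$name)]
    }
  }
  op <- object@objectProperties
  for (i in seq_len(nrow(op))) {
    inv <- op$inverseOf[i]
    if (is.na(inv)) next
    j <- match(inv, op$name)
    if (is.na(j)) { msg <- c(msg, paste0("inverse ", inv, " not registered")); next }
    if (!identical(op$domain[j], op$range[i]) || !identical(op$range[j], op$domain[i]))
      msg <- c(msg, paste0("inverse pair ", op$name[i], "/", inv,
                           " has inconsistent domain/range"))
  }
  if (any(!nzchar(object@dataProperties$domains)))
    msg <- c(msg, "data property with no domain")
  if (any(object@cardinalityRules$minCount < 0))
    msg <- c(msg, "negative minCount")
  bad <- setdiff(object@cardinalityRules$property, op$name)
  if (length(bad))
    msg <- c(msg, paste0("cardinality rule on unknown property: ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

# ---- alignment model -------------------------------------------------------

#' Feature: an annotated region of an alignment sequence
#'
#' Coordinates are 1-based and inclusive, following the MACSIM `fstart`/`fstop`
#' convention.
#'
#' @slot ftype feature type label (e.g. `"DOMAIN"`).
#' @slot fstart,fstop 1-based inclusive bounds, `fstart <= fstop`.
#' @slot fnote optional free-text note (`NA` when absent).
#' @slot fscore optional feature score (`NA` when absent).
#' @exportClass Feature
setClass("Feature",
  representation(ftype = "character", fstart = "integer", fstop = "integer",
                 fnote = "character", fscore = "numeric")
)

setValidity("Feature", function(object) {
  if (length(object@fstart) != 1L || length(object@fstop) != 1L)
    return("fstart and fstop must be scalar")
  if (is.na(object@fstart) || is.na(object@fstop))
    return("fstart and fstop must not be NA")
  if (object@fstart < 1L) return("fstart must be >= 1")
  if (object@fstart > object@fstop) return("fstart must be <= fstop")
  TRUE
})

#' AlignmentSequence: one aligned sequence with its annotations
#'
#' The subclass split between DNA and protein sequences is carried in the
#' `molecule` slot; the RDF mapping types instances as `DNAAlignmentSequence`
#' or `ProteinAlignmentSequence` accordingly.
#'
#' @slot identifier sequence name (MACSIM `<seq-name>`); non-empty.
#' @slot accessionNumber optional database accession (`NA` when absent).
#' @slot residues the aligned string, gap characters included.
#' @slot length number of characters of `residues` (gaps included).
#' @slot organism optional source organism (`NA` when absent).
#' @slot keywords character vector of free-text keywords.
#' @slot molecule `"Protein"` or `"DNA"`.
#' @slot features list of [Feature-class] objects; bounds are checked against
#'   the aligned length on construction.
#' @slot passthrough character vector of XML snippets for MACSIM elements the
#'   mapping does not model; re-emitted verbatim so richer files survive
#'   round-trips.
#' @exportClass AlignmentSequence
setClass("AlignmentSequence",
  representation(identifier = "character", accessionNumber = "character",
                 residues = "character", length = "integer",
                 organism = "character", keywords = "character",
                 molecule = "character", features = "list",
                 passthrough = "character")
)

setValidity("AlignmentSequence", function(object) {
  if (!length(object@identifier) || !nzchar(object@identifier))
    return("identifier must be non-empty")
  if (length(object@residues) != 1L || !nzchar(object@residues))
    return("residues must be a single non-empty string")
  if (object@length != nchar(object@residues))
    return(sprintf("length (%d) must equal the aligned residue count (%d)",
                   object@length, nchar(object@residues)))
  if (!object@molecule %in% c("DNA", "Protein"))
    return("molecule must be 'DNA' or 'Protein'")
  for (f in object@features) {
    if (!is(f, "Feature")) return("features must contain Feature objects")
    if (f@fstop > object@length)
      return(sprintf("feature [%d,%d] exceeds sequence length %d",
                     f@fstart, f@fstop, object@length))
  }
  TRUE
})

#' ConstructionMethod: how a sub-alignment was produced
#'
#' @slot name method name (e.g. `"MAFFT"`).
#' @slot approach `"deterministic"` or `"stochastic"`; must be set explicitly.
#' @exportClass ConstructionMethod
setClass("ConstructionMethod",
  representation(name = "character", approach = "character")
)

setValidity("ConstructionMethod", function(object) {
  if (!length(object@approach) || !object@approach %in% c("deterministic", "stochastic"))
    return("approach must be 'deterministic' or 'stochastic'")
  TRUE
})

#' SubAlignment: a cluster of mutually aligned sequences
#'
#' @slot name sub-alignment name (MACSIM `<aln-name>`; may be empty).
#' @slot sequences list of [AlignmentSequence-class]; all of equal aligned
#'   length.
#' @slot constructionMethod a [ConstructionMethod-class] or `NULL`.
#' @slot gapCharacter the single gap symbol used by the member sequences.
#' @slot passthrough character vector of unmodeled MACSIM XML snippets,
#'   preserved across read/write.
#' @exportClass SubAlignment
setClass("SubAlignment",
  representation(name = "character", sequences = "list",
                 constructionMethod = "ANY", gapCharacter = "character",
                 passthrough = "character")
)

setValidity("SubAlignment", function(object) {
  if (length(object@gapCharacter) != 1L || nchar(object@gapCharacter) != 1L)
    return("gapCharacter must be one character")
  if (!is.null(object@constructionMethod) &&
      !is(object@constructionMethod, "ConstructionMethod"))
    return("constructionMethod must be NULL or a ConstructionMethod")
  lens <- vapply(object@sequences, function(s) nchar(s@residues), integer(1))
  if (length(unique(lens)) > 1L) {
    off <- object@sequences[[which(lens != lens[1L])[1L]]]@identifier
    return(sprintf("ragged alignment: sequence '%s' has a different aligned length", off))
  }
  TRUE
})

#' ScoreFunction: a score metric with declared bounds
#'
#' @slot name function name (e.g. `"entropy"`).
#' @slot kind `"alignment"` or `"column"`.
#' @slot scoreMin,scoreMax declared bounds; `NA` disables bound checking for
#'   scores under this function.
#' @slot optimization `"maximization"` or `"minimization"`.
#' @exportClass ScoreFunction
setClass("ScoreFunction",
  representation(name = "character", kind = "character",
                 scoreMin = "numeric", scoreMax = "numeric",
                 optimization = "character")
)

setValidity("ScoreFunction", function(object) {
  if (!object@kind %in% c("alignment", "column"))
    return("kind must be 'alignment' or 'column'")
  if (!object@optimization %in% c("maximization", "minimization"))
    return("optimization must be 'maximization' or 'minimization'")
  if (!is.na(object@scoreMin) && !is.na(object@scoreMax) &&
      object@scoreMin > object@scoreMax)
    return("scoreMin must be <= scoreMax")
  TRUE
})

#' Score: a score value attached to a score function
#'
#' No bound check happens at construction; out-of-range values are the
#' validator's business (that is what the incorrectness rules detect).
#'
#' @slot value the numeric score.
#' @slot scoreFunction the [ScoreFunction-class] that produced it.
#' @exportClass Score
setClass("Score",
  representation(value = "numeric", scoreFunction = "ScoreFunction")
)

#' ReliabilityMeasure: a per-column confidence score with a cutoff
#'
#' Covers measures such as GUIDANCE (confidence in `[0, 1]`, columns *below*
#' the cutoff filtered) and Heads-or-Tails. The flagging direction must be
#' stated explicitly: published usage is not uniform about whether a column
#' falling below or rising above the cutoff is the unreliable one.
#'
#' @slot name measure name.
#' @slot scoreCutoff the cutoff value.
#' @slot unreliableWhen `"below_cutoff"` or `"above_cutoff"`; no default.
#' @slot scoreMin,scoreMax declared range of the confidence score (`NA` when
#'   unstated); scores outside it are surfaced as range violations.
#' @exportClass ReliabilityMeasure
setClass("ReliabilityMeasure",
  representation(name = "character", scoreCutoff = "numeric",
                 unreliableWhen = "character",
                 scoreMin = "numeric", scoreMax = "numeric")
)

setValidity("ReliabilityMeasure", function(object) {
  if (!length(object@unreliableWhen) ||
      !object@unreliableWhen %in% c("below_cutoff", "above_cutoff"))
    return("unreliableWhen must be set to 'below_cutoff' or 'above_cutoff'")
  TRUE
})

#' AlignmentColumn: one column of an alignment
#'
#' @slot atSequenceIndex 1-based column position.
#' @slot column the per-sequence characters at this position, in sequence
#'   order.
#' @slot consensusCharacter most frequent non-gap character (`NA` until
#'   derived).
#' @slot columnWeight optional integer weight (`NA` when absent).
#' @slot columnScores list of [Score-class] objects.
#' @exportClass AlignmentColumn
setClass("AlignmentColumn",
  representation(atSequenceIndex = "integer", column = "character",
                 consensusCharacter = "character", columnWeight = "integer",
                 columnScores = "list")
)

setValidity("AlignmentColumn", function(object) {
  if (is.na(object@atSequenceIndex) || object@atSequenceIndex < 1L)
    return("atSequenceIndex must be >= 1")
  if (!nzchar(object@column))
    return("column must be non-empty")
  TRUE
})

#' Alignment: a pairwise or multiple sequence alignment
#'
#' An alignment aggregates one or more sub-alignments (clusters of sequences),
#' alignment-level scores and, when materialized, its columns. The "at least
#' one sub-alignment" and "at least two sequences per sub-alignment"
#' constraints are deliberately *not* construction errors: incomplete
#' alignments can be represented, and [validateAlignment()] reports them as
#' cardinality violations.
#'
#' @slot alignmentId non-empty identifier (e.g. `"BB11001"`).
#' @slot subAlignments list of [SubAlignment-class].
#' @slot alignmentScores list of [Score-class].
#' @slot columns list of [AlignmentColumn-class]; usually derived via
#'   [alignmentColumns()].
#' @exportClass Alignment
setClass("Alignment",
  representation(alignmentId = "character", subAlignments = "list",
                 alignmentScores = "list", columns = "list")
)

setValidity("Alignment", function(object) {
  if (!length(object@alignmentId) || !nzchar(object@alignmentId))
    return("alignmentId must be non-empty")
  if (!all(vapply(object@subAlignments, is, logical(1), class2 = "SubAlignment")))
    return("subAlignments must contain SubAlignment objects")
  TRUE
})

#' ProteinRecord: protein metadata as retrieved from UniProtKB
#'
#' Field names follow the UniProtKB description-line vocabulary (db tag,
#' unique identifier = accession, entry name, protein name, organism name,
#' gene name, protein existence evidence code).
#'
#' @slot accessionNumber the UniProtKB accession; non-empty.
#' @slot entryName,proteinName,organismName,geneName optional (`NA` absent).
#' @slot proteinExistence optional evidence code 1-5 (`NA` absent).
#' @slot dbTag `"sp"` (Swiss-Prot) or `"tr"` (TrEMBL); `NA` when unknown.
#' @slot ncbiId optional cross-referenced NCBI identifier.
#' @slot pdbIds character vector of cross-referenced PDB identifiers.
#' @exportClass ProteinRecord
setClass("ProteinRecord",
  representation(accessionNumber = "character", entryName = "character",
                 proteinName = "character", organismName = "character",
                 geneName = "character", proteinExistence = "integer",
                 dbTag = "character", ncbiId = "character",
                 pdbIds = "character")
)

setValidity("ProteinRecord", function(object) {
  if (!length(object@accessionNumber) || is.na(object@accessionNumber) ||
      !nzchar(object@accessionNumber))
    return("accessionNumber must be non-empty")
  TRUE
})

#' EnrichmentResult: the selected protein record plus any ambiguous matches
#'
#' When one lookup key (typically a PDB identifier shared by close homologs)
#' maps to several UniProtKB entries, the selected record is in `protein` and
#' every other candidate is kept in `ambiguousMatches` for expert review.
#'
#' @slot key the accession or PDB identifier that was queried.
#' @slot protein the selected [ProteinRecord-class].
#' @slot ambiguousMatches list of the non-selected candidate records.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(key = "character", protein = "ProteinRecord",
                 ambiguousMatches = "list")
)

# ---- I/O -------------------------------------------------------------------

#' FastaRecord: one FASTA record with its (possibly parsed) description line
#'
#' @slot rawHeader the description line without the leading `>` and without a
#'   newline.
#' @slot parsedFields named list of dialect fields (UniProtKB: `db`,
#'   `unique_identifier`, `entry_name`, `protein_name`, `organism_name`,
#'   `gene_name`, `protein_existence`; NCBI: `accession`, `description`,
#'   `organism`); empty for the raw dialect. Absent optional fields are
#'   absent from the list, never empty strings.
#' @slot residues the sequence, unwrapped.
#' @exportClass FastaRecord
setClass("FastaRecord",
  representation(rawHeader = "character", parsedFields = "list",
                 residues = "character")
)

setValidity("FastaRecord", function(object) {
  if (grepl("[\r\n]", object@rawHeader))
    return("rawHeader must not contain a newline")
  if (length(object@residues) != 1L || !nzchar(object@residues))
    return("residues must be non-empty")
  TRUE
})

# ---- RDF -------------------------------------------------------------------

#' TripleGraph: a set of RDF statements
#'
#' Subjects and predicates are absolute IRIs; objects are either IRIs or
#' typed/plain literals. The graph is kept duplicate-free. Blank nodes are
#' never used: every entity carries a minted IRI.
#'
#' @slot triples data.frame with columns `subject`, `predicate`, `object`,
#'   `objectType` (`"iri"` or `"literal"`) and `datatype` (an XSD datatype IRI
#'   for typed literals, `NA` for plain literals and IRIs).
#' @slot baseNamespace the vocabulary/instance namespace IRI.
#' @exportClass TripleGraph
setClass("TripleGraph",
  representation(triples = "data.frame", baseNamespace = "character")
)

setValidity("TripleGraph", function(object) {
  tr <- object@triples
  need <- c("subject", "predicate", "object", "objectType", "datatype")
  if (!all(need %in% names(tr)))
    return(paste0("triples must have columns ", paste(need, collapse = ", ")))
  if (anyDuplicated(tr[c("subject", "predicate", "object", "objectType")]))
    return("duplicate triples")
  if (nrow(tr) && !all(tr$objectType %in% c("iri", "literal")))
    return("objectType must be 'iri' or 'literal'")
  TRUE
})

#' IriPolicy: deterministic IRI minting rules
#'
#' Instance IRIs follow the pattern `base + alignmentId + "_" + localId`, with
#' every character outside `[A-Za-z0-9_]` replaced by `_`.
#'
#' @slot base absolute namespace IRI ending in `#` or `/`.
#' @exportClass IriPolicy
setClass("IriPolicy", representation(base = "character"))

setValidity("IriPolicy", function(object) {
  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*://", object@base))
    return("base must be an absolute IRI")
  TRUE
})

# ---- validation ------------------------------------------------------------

.RULE_IDS <- c("column_score_gt_max", "column_score_lt_min",
               "alignment_score_gt_max", "alignment_score_lt_min",
               "unreliable_column", "subalignment_min_sequences",
               "alignment_min_subalignments", "schema_assertion")

#' Violation: one rule verdict against an alignment
#'
#' @slot ruleId one of the closed set of rule identifiers: the four
#'   score-bound incorrectness rules (`column_score_gt_max`,
#'   `column_score_lt_min`, `alignment_score_gt_max`,
#'   `alignment_score_lt_min`), `unreliable_column`,
#'   `subalignment_min_sequences`, `alignment_min_subalignments` and
#'   `schema_assertion`.
#' @slot subject model path or IRI of the offending entity.
#' @slot detail human-readable description including the offending values.
#' @exportClass Violation
setClass("Violation",
  representation(ruleId = "character", subject = "character", detail = "character")
)

setValidity("Violation", function(object) {
  if (!object@ruleId %in% .RULE_IDS)
    return(paste0("unknown ruleId: ", object@ruleId))
  TRUE
})

#' ValidationReport: aggregated rule verdicts for one alignment
#'
#' The verdict is `"correct"` exactly when no violation other than
#' `unreliable_column` entries is present: unreliable columns are a filtering
#' aid, not an incorrectness.
#'
#' @slot verdict `"correct"` or `"incorrect"`.
#' @slot violations list of [Violation-class].
#' @slot unreliableColumns integer vector of 1-based flagged column indices.
#' @exportClass ValidationReport
setClass("ValidationReport",
  representation(verdict = "character", violations = "list",
                 unreliableColumns = "integer")
)

setValidity("ValidationReport", function(object) {
  hard <- Filter(function(v) v@ruleId != "unreliable_column", object@violations)
  want <- if (length(hard)) "incorrect" else "correct"
  if (!identical(object@verdict, want))
    return(sprintf("verdict '%s' inconsistent with %d non-reliability violation(s)",
                   object@verdict, length(hard)))
  TRUE
})
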