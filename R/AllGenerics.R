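# Accessor generics. Slot access from user code goes through these.

#' @rdname Alignment-class
#' @param x an object of the documented class
#' @export
setGeneric("alignmentId", function(x) standardGeneric("alignmentId"))
#' @rdname Alignment-class
#' @export
setGeneric("subAlignments", function(x) standardGeneric("subAlignments"))
#' @rdname Alignment-class
#' @export
setGeneric("alignmentScores", function(x) standardGeneric("alignmentScores"))

#' @rdname SubAlignment-class
#' @param x an object of the documented class
#' @export
setGeneric("subAlignmentName", function(x) standardGeneric("subAlignmentName"))
#' @rdname SubAlignment-class
#' @export
setGeneric("alignmentSequences", function(x) standardGeneric("alignmentSequences"))
#' @rdname SubAlignment-class
#' @export
setGeneric("gapCharacter", function(x) standardGeneric("gapCharacter"))
#' @rdname SubAlignment-class
#' @export
setGeneric("constructionMethod", function(x) standardGeneric("constructionMethod"))

#' @rdname AlignmentSequence-class
#' @param x an object of the documented class
#' @export
setGeneric("seqIdentifier", function(x) standardGeneric("seqIdentifier"))
#' @rdname AlignmentSequence-class
#' @export
setGeneric("accessionNumber", function(x) standardGeneric("accessionNumber"))
#' @rdname AlignmentSequence-class
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname AlignmentSequence-class
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname AlignmentSequence-class
#' @export
setGeneric("moleculeType", function(x) standardGeneric("moleculeType"))

#' @rdname Score-class
#' @param x an object of the documented class
#' @export
setGeneric("scoreValue", function(x) standardGeneric("scoreValue"))
#' @rdname Score-class
#' @export
setGeneric("scoreFunction", function(x) standardGeneric("scoreFunction"))

#' @rdname TripleGraph-class
#' @param x an object of the documented class
#' @export
setGeneric("triples", function(x) standardGeneric("triples"))
#' @rdname TripleGraph-class
#' @export
setGeneric("baseNamespace", function(x) standardGeneric("baseNamespace"))

#' @rdname ValidationReport-class
#' @param x an object of the documented class
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))
#' @rdname ValidationReport-class
#' @export
setGeneric("violations", function(x) standardGeneric("violations"))
#' @rdname ValidationReport-class
#' @export
setGeneric("unreliableColumns", function(x) standardGeneric("unreliableColumns"))
#' @rdname Violation-class
#' @param x an object of the documented class
#' @export
setGeneric("ruleId", function(x) standardGeneric("ruleId"))
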