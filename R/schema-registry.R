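# The SALON vocabulary encoded as an in-code registry. The RDF mapping emits
# only predicates registered here, and the validator's schema assertions are
# answered from the same tables.

.salonClasses <- function() {
  top <- c("Alignment", "AlignmentColumn", "AlignmentScore",
           "AlignmentScoreFunction", "AlignmentSequence", "ColumnScore",
           "ColumnScoreFunction", "ConstructionMethod", "Feature", "Protein",
           "SubAlignment")
  sub <- rbind(
    data.frame(name = "DNAAlignmentSequence",     parent = "AlignmentSequence"),
    data.frame(name = "ProteinAlignmentSequence", parent = "AlignmentSequence"),
    data.frame(name = "DeterministicApproach",    parent = "ConstructionMethod"),
    data.frame(name = "StochasticApproach",       parent = "ConstructionMethod"),
    data.frame(name = "MaximizationAlignmentScoreFunction",
               parent = "AlignmentScoreFunction"),
    data.frame(name = "MaximizationColumnScoreFunction",
               parent = "ColumnScoreFunction"),
    # per-column confidence functions (GUIDANCE, Heads-or-Tails) are modeled
    # as a column score function specialization
    data.frame(name = "ReliabilityMeasure",       parent = "ColumnScoreFunction")
  )
  rbind(
    data.frame(name = top, parent = NA_character_, topLevel = TRUE),
    cbind(sub, topLevel = FALSE)
  )
}

.salonObjectProperties <- function() {
  p <- function(name, domain, range, inverseOf = NA_character_)
    data.frame(name = name, domain = domain, range = range, inverseOf = inverseOf)
  forward <- rbind(
    p("hasConstructionMethod",     "SubAlignment",      "ConstructionMethod"),
    p("hasAlignmentScore",         "Alignment",         "AlignmentScore"),
    p("hasAlignmentScoreFunction", "AlignmentScore",    "AlignmentScoreFunction"),
    p("hasColumn",                 "Alignment",         "AlignmentColumn", "isColumnOf"),
    p("hasColumnScore",            "AlignmentColumn",   "ColumnScore"),
    p("hasColumnScoreFunction",    "ColumnScore",       "ColumnScoreFunction"),
    p("hasSubAlignment",           "Alignment",         "SubAlignment", "isSubalignmentOf"),
    p("hasFeature",                "AlignmentSequence", "Feature", "isFeatureOf"),
    p("hasSequence",               "SubAlignment",      "AlignmentSequence", "isSequenceOf"),
    p("hasAssociationWithProtein", "SequenceAlignment", "Protein")
  )
  inverse <- rbind(
    p("isColumnOf",       "AlignmentColumn",   "Alignment",         "hasColumn"),
    p("isSubalignmentOf", "SubAlignment",      "Alignment",         "hasSubAlignment"),
    p("isFeatureOf",      "Feature",           "AlignmentSequence", "hasFeature"),
    p("isSequenceOf",     "AlignmentSequence", "SubAlignment",      "hasSequence")
  )
  rbind(cbind(forward, isInverse = FALSE), cbind(inverse, isInverse = TRUE))
}

.salonDataProperties <- function() {
  d <- function(name, domains, datatype)
    data.frame(name = name, domains = domains, datatype = datatype)
  rbind(
    d("atSequenceIndex",    "AlignmentColumn",                                "integer"),
    d("column",             "AlignmentColumn",                                "string"),
    d("score",              "AlignmentScore,ColumnScore",                     "decimal"),
    d("scoreMax",           "AlignmentScoreFunction,ColumnScoreFunction",     "decimal"),
    d("scoreMin",           "AlignmentScoreFunction,ColumnScoreFunction",     "decimal"),
    d("scoreCutoff",        "ReliabilityMeasure",                             "decimal"),
    d("FScore",             "Feature",                                        "decimal"),
    d("columnWeight",       "AlignmentColumn",                                "integer"),
    d("consensusCharacter", "AlignmentColumn",                                "short"),
    d("gapCharacter",       "SubAlignment",                                   "short"),
    d("accessionNumber",    "AlignmentSequence,Protein",                      "string"),
    d("identifier",         "AlignmentSequence",                              "string"),
    d("length",             "AlignmentSequence",                              "integer"),
    d("organism",           "AlignmentSequence",                              "string"),
    # properties carried by the MACSIM mapping and the class-definition prose
    d("subAlignmentName",   "SubAlignment",                                   "string"),
    d("sequence",           "AlignmentSequence",                              "string"),
    d("keyword",            "AlignmentSequence",                              "string"),
    d("FType",              "Feature",                                        "string"),
    d("FStart",             "Feature",                                        "integer"),
    d("FStop",              "Feature",                                        "integer"),
    d("FNote",              "Feature",                                        "string")
  )
}

#' The built-in SALON schema registry
#'
#' Builds the [SchemaRegistry-class] holding the SALON classes and hierarchy,
#' the 14 object properties (10 forward, 4 inverse pairs), the data
#' properties with their datatypes, and the two minimum-cardinality rules: an
#' alignment contains at least one sub-alignment, and a sub-alignment has at
#' least two alignment sequences.
#'
#' `SequenceAlignment`, which appears only as the declared domain of
#' `hasAssociationWithProtein`, is registered as an alias resolving to
#' `Alignment` and `AlignmentSequence`, so protein associations can hang off
#' either.
#'
#' @return a validated [SchemaRegistry-class].
#' @examples
#' reg <- builtinSchema()
#' nrow(objectProperties(reg))          # 14
#' lookupProperty(reg, "hasColumn")
#' @export
builtinSchema <- function() {
  new("SchemaRegistry",
    classes          = .salonClasses(),
    objectProperties = .salonObjectProperties(),
    dataProperties   = .salonDataProperties(),
    cardinalityRules = rbind(
      data.frame(onClass = "Alignment",    property = "hasSubAlignment", minCount = 1L),
      data.frame(onClass = "SubAlignment", property = "hasSequence",     minCount = 2L)
    ),
    aliases = list(SequenceAlignment = c("Alignment", "AlignmentSequence"))
  )
}

#' @describeIn builtinSchema the class table of a registry.
#' @param registry a [SchemaRegistry-class]
#' @export
schemaClasses <- function(registry) registry@classes

#' @describeIn builtinSchema the object-property table of a registry.
#' @export
objectProperties <- function(registry) registry@objectProperties

#' @describeIn builtinSchema the data-property table of a registry.
#' @export
dataProperties <- function(registry) registry@dataProperties

#' @describeIn builtinSchema the minimum-cardinality rules of a registry.
#' @export
cardinalityRules <- function(registry) registry@cardinalityRules

#' Look up a property definition by name
#'
#' @param registry a [SchemaRegistry-class]
#' @param name property name, case-sensitive.
#' @return a one-row data.frame (object property: columns `name`, `domain`,
#'   `range`, `inverseOf`, `isInverse`; data property: columns `name`,
#'   `domains`, `datatype`), or `NULL` when unknown.
#' @export
lookupProperty <- function(registry, name) {
  op <- registry@objectProperties
  i <- match(name, op$name)
  if (!is.na(i)) return(op[i, , drop = FALSE])
  dp <- registry@dataProperties
  i <- match(name, dp$name)
  if (!is.na(i)) return(dp[i, , drop = FALSE])
  NULL
}

#' Ancestors of a class in the registry hierarchy
#'
#' @inheritParams lookupProperty
#' @param name class name.
#' @return character vector of parent classes, nearest first; empty for a
#'   top-level class.
#' @examples
#' classParents(builtinSchema(), "ProteinAlignmentSequence")
#' @export
classParents <- function(registry, name) {
  cls <- registry@classes
  out <- character()
  cur <- cls$parent[match(name, cls$name)]
  while (length(cur) == 1L && !is.na(cur)) {
    out <- c(out, cur)
    cur <- cls$parent[match(cur, cls$name)]
  }
  out
}

# resolve a declared domain name to the concrete classes it admits
.resolveDomain <- function(registry, domain) {
  split <- strsplit(domain, ",", fixed = TRUE)[[1]]
  unlist(lapply(split, function(d) {
    if (d %in% names(registry@aliases)) registry@aliases[[d]] else d
  }), use.names = FALSE)
}

.isClassOrDescendant <- function(registry, cls, targets) {
  any(cls %in% targets) || any(classParents(registry, cls) %in% targets)
}

#' Check a (subject class, property, object kind) assertion against the schema
#'
#' Enforces the declared domains and ranges of the object properties and the
#' declared domains and datatypes of the data properties. Subject classes
#' match the declared domain or any descendant of it. The check is total: any
#' assertion over a known property yields `ok` or a typed violation, never an
#' error.
#'
#' @inheritParams lookupProperty
#' @param subjectClass class of the statement's subject.
#' @param property property name.
#' @param objectKind for an object property, the class of the object; for a
#'   data property, one of `"string"`, `"integer"`, `"decimal"`, `"short"`.
#' @return a list with `ok` (logical) and, on violation, `kind` (one of
#'   `"unknown-property"`, `"domain"`, `"range"`, `"datatype"`) and `detail`.
#' @examples
#' reg <- builtinSchema()
#' checkAssertion(reg, "SubAlignment", "hasSequence", "AlignmentSequence")$ok
#' checkAssertion(reg, "Alignment", "hasSequence", "AlignmentSequence")$kind
#' @export
checkAssertion <- function(registry, subjectClass, property, objectKind) {
  def <- lookupProperty(registry, property)
  if (is.null(def))
    return(list(ok = FALSE, kind = "unknown-property",
                detail = paste0("property '", property, "' is not registered")))
  if ("range" %in% names(def)) {        # object property
    domains <- .resolveDomain(registry, def$domain)
    if (!.isClassOrDescendant(registry, subjectClass, domains))
      return(list(ok = FALSE, kind = "domain",
                  detail = sprintf("domain of %s is %s, not %s",
                                   property, def$domain, subjectClass)))
    if (!.isClassOrDescendant(registry, objectKind, def$range))
      return(list(ok = FALSE, kind = "range",
                  detail = sprintf("range of %s is %s, not %s",
                                   property, def$range, objectKind)))
  } else {                              # data property
    domains <- .resolveDomain(registry, def$domains)
    if (!.isClassOrDescendant(registry, subjectClass, domains))
      return(list(ok = FALSE, kind = "domain",
                  detail = sprintf("domain of %s is {%s}, not %s",
                                   property, def$domains, subjectClass)))
    # a decimal slot accepts integer-valued literals ("Integer or float")
    okType <- objectKind == def$datatype ||
      (def$datatype == "decimal" && objectKind == "integer") ||
      (def$datatype == "short" && objectKind == "string")
    if (!okType)
      return(list(ok = FALSE, kind = "datatype",
                  detail = sprintf("datatype of %s is %s, not %s",
                                   property, def$datatype, objectKind)))
  }
  list(ok = TRUE)
}

#' Export the registry as a flat, machine-readable summary
#'
#' One record per entity, suitable for documentation or diffing against the
#' published vocabulary.
#'
#' @inheritParams lookupProperty
#' @return data.frame with columns `entity` (`class`, `objectProperty`,
#'   `dataProperty`, `cardinalityRule`), `name` and `detail`.
#' @export
schemaSummary <- function(registry) {
  cls <- registry@classes
  op  <- registry@objectProperties
  dp  <- registry@dataProperties
  cr  <- registry@cardinalityRules
  rbind(
    data.frame(entity = "class", name = cls$name,
               detail = ifelse(cls$topLevel, "top-level",
                               paste0("subClassOf ", cls$parent))),
    data.frame(entity = "objectProperty", name = op$name,
               detail = paste0(op$domain, " -> ", op$range,
                               ifelse(is.na(op$inverseOf), "",
                                      paste0(" (inverseOf ", op$inverseOf, ")")))),
    data.frame(entity = "dataProperty", name = dp$name,
               detail = paste0("{", dp$domains, "} -> ", dp$datatype)),
    data.frame(entity = "cardinalityRule",
               name = paste0(cr$onClass, ".", cr$property),
               detail = paste0("min ", cr$minCount))
  )
}

setMethod("show", "SchemaRegistry", function(object) {
  cat("SALON SchemaRegistry:", nrow(object@classes), "classes,",
      nrow(object@objectProperties), "object properties (",
      sum(object@objectProperties$isInverse), "inverse ),",
      nrow(object@dataProperties), "data properties,",
      nrow(object@cardinalityRules), "cardinality rules\n")
})
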