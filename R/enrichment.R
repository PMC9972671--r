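# UniProtKB enrichment: federated SPARQL query builders, an injectable
# endpoint client, graph merging of protein associations, and FASTA
# description-line generation in the UniProtKB and NCBI dialects.

.UNIPROT_ENDPOINT <- "https://sparql.uniprot.org/sparql"

.sparqlEscape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  gsub("\"", "\\\"", x, fixed = TRUE)
}

#' Default UniProt predicate mapping
#'
#' The exact UniProt core predicates used by the enrichment queries, as a
#' configurable mapping so deployments tracking a different endpoint or
#' vocabulary revision can override them.
#'
#' @return named list of prefix and predicate-path strings.
#' @export
uniprotPredicateMap <- function() {
  list(
    uniprotBase      = "http://purl.uniprot.org/uniprot/",
    core             = "http://purl.uniprot.org/core/",
    pdbDatabase      = "http://purl.uniprot.org/database/PDB",
    mnemonic         = "up:mnemonic",
    proteinName      = "up:recommendedName/up:fullName",
    organismName     = "up:organism/up:scientificName",
    geneName         = "up:encodedBy/skos:prefLabel",
    proteinExistence = "up:existence",
    seeAlso          = "rdfs:seeAlso"
  )
}

.sparqlPrologue <- function(predicates) {
  paste0(
    "PREFIX up: <", predicates$core, ">\n",
    "PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>\n",
    "PREFIX skos: <http://www.w3.org/2004/02/skos/core#>\n")
}

#' Build the federated accession enrichment query
#'
#' A SPARQL `SELECT` with a `SERVICE` clause against the UniProt endpoint,
#' keyed on the sequence's accession number, retrieving the protein name,
#' organism, gene and cross-referenced NCBI identifier. The text is
#' deterministic for fixed inputs and the accession appears only inside a
#' properly escaped literal.
#'
#' @param accession UniProtKB accession (non-empty).
#' @param endpoint SPARQL endpoint IRI.
#' @param predicates predicate mapping; see [uniprotPredicateMap()].
#' @return SPARQL query text.
#' @examples
#' cat(buildAccessionQuery("1D2N"))
#' @export
buildAccessionQuery <- function(accession, endpoint = .UNIPROT_ENDPOINT,
                                predicates = uniprotPredicateMap()) {
  if (!length(accession) || is.na(accession) || !nzchar(accession))
    stop("accession must be non-empty")
  paste0(
    .sparqlPrologue(predicates),
    "SELECT ?protein ?entryName ?proteinName ?organismName ?geneName",
    " ?proteinExistence ?ncbiId\nWHERE {\n",
    "  VALUES ?accession { \"", .sparqlEscape(accession), "\" }\n",
    "  SERVICE <", endpoint, "> {\n",
    "    BIND(IRI(CONCAT(\"", predicates$uniprotBase,
    "\", ?accession)) AS ?protein)\n",
    "    ?protein a up:Protein .\n",
    "    OPTIONAL { ?protein ", predicates$mnemonic, " ?entryName . }\n",
    "    OPTIONAL { ?protein ", predicates$proteinName, " ?proteinName . }\n",
    "    OPTIONAL { ?protein ", predicates$organismName, " ?organismName . }\n",
    "    OPTIONAL { ?protein ", predicates$geneName, " ?geneName . }\n",
    "    OPTIONAL { ?protein ", predicates$proteinExistence,
    " ?proteinExistence . }\n",
    "    OPTIONAL { ?protein ", predicates$seeAlso, " ?ncbiId . }\n",
    "  }\n}\n")
}

#' Build the PDB cross-reference query
#'
#' Retrieves, for every UniProtKB entry cross-referenced to the given PDB
#' identifier, the seven description-line fields: db, unique identifier,
#' entry name, protein name, organism name, gene name and protein existence.
#'
#' @param pdbId PDB identifier (non-empty).
#' @inheritParams buildAccessionQuery
#' @return SPARQL query text.
#' @export
buildPdbQuery <- function(pdbId, endpoint = .UNIPROT_ENDPOINT,
                          predicates = uniprotPredicateMap()) {
  if (!length(pdbId) || is.na(pdbId) || !nzchar(pdbId))
    stop("pdbId must be non-empty")
  paste0(
    .sparqlPrologue(predicates),
    "SELECT ?db ?uniqueIdentifier ?entryName ?proteinName ?organismName",
    " ?geneName ?proteinExistence\nWHERE {\n",
    "  VALUES ?pdbId { \"", .sparqlEscape(pdbId), "\" }\n",
    "  SERVICE <", endpoint, "> {\n",
    "    ?protein ", predicates$seeAlso, " ?xref .\n",
    "    ?xref up:database <", predicates$pdbDatabase, "> .\n",
    "    FILTER(STRENDS(STR(?xref), ?pdbId))\n",
    "    BIND(STRAFTER(STR(?protein), \"", predicates$uniprotBase,
    "\") AS ?uniqueIdentifier)\n",
    "    ?protein up:reviewed ?reviewed .\n",
    "    BIND(IF(?reviewed, \"sp\", \"tr\") AS ?db)\n",
    "    OPTIONAL { ?protein ", predicates$mnemonic, " ?entryName . }\n",
    "    OPTIONAL { ?protein ", predicates$proteinName, " ?proteinName . }\n",
    "    OPTIONAL { ?protein ", predicates$organismName, " ?organismName . }\n",
    "    OPTIONAL { ?protein ", predicates$geneName, " ?geneName . }\n",
    "    OPTIONAL { ?protein ", predicates$proteinExistence,
    " ?proteinExistence . }\n",
    "  }\n}\n")
}

# ---- endpoint clients ------------------------------------------------------

.clientExecute <- function(client, query) {
  if (is.function(client)) return(client(query))
  if (is.list(client) && is.function(client$execute))
    return(client$execute(query))
  stop("client must be a function(query) or a list with an $execute function")
}

.queryKey <- function(query) {
  m <- regmatches(query, regexec(
    "VALUES \\?(accession|pdbId) \\{ \"((?:[^\"\\\\]|\\\\.)*)\" \\}",
    query, perl = TRUE))[[1]]
  if (!length(m)) stop("query carries no VALUES key")
  m[3]
}

#' An offline endpoint client backed by canned responses
#'
#' Returns a client function for [enrichAlignment()] and [lookupProtein()]
#' that answers queries from a fixed table instead of the network. The key
#' (accession or PDB id) is recovered from the query's `VALUES` clause.
#'
#' @param responses named list: key -> data.frame of result rows (columns
#'   among `accession`, `db`, `entry_name`, `protein_name`, `organism_name`,
#'   `gene_name`, `protein_existence`, `ncbi_id`). A missing key yields zero
#'   rows.
#' @param failFor character vector of keys for which the client simulates a
#'   transport failure.
#' @return a client `function(query)`.
#' @export
fixtureEndpointClient <- function(responses = list(), failFor = character()) {
  force(responses); force(failFor)
  function(query) {
    key <- .queryKey(query)
    if (key %in% failFor)
      stop("simulated endpoint failure for key '", key, "'")
    resp <- responses[[key]]
    if (is.null(resp)) return(data.frame())
    resp
  }
}

.recordFromRow <- function(row, key) {
  g <- function(col, default = NA_character_) {
    v <- row[[col]]
    if (is.null(v) || length(v) == 0L || is.na(v)) default else v
  }
  pe <- g("protein_existence", NA_integer_)
  ProteinRecord(
    accessionNumber = g("accession", key),
    entryName = g("entry_name"),
    proteinName = g("protein_name"),
    organismName = g("organism_name"),
    geneName = g("gene_name"),
    proteinExistence = if (is.na(pe)) NA_integer_ else as.integer(pe),
    dbTag = g("db"),
    ncbiId = g("ncbi_id"))
}

.selectRecord <- function(records) {
  # strongest protein-existence evidence first (code 1 = evidence at protein
  # level), missing evidence last; ties by accession sort
  pe <- vapply(records, function(r)
    if (is.na(r@proteinExistence)) 99L else r@proteinExistence, integer(1))
  acc <- vapply(records, function(r) r@accessionNumber, character(1))
  records[order(pe, acc)]
}

.rowsToResult <- function(rows, key) {
  records <- lapply(seq_len(nrow(rows)), function(i)
    .recordFromRow(rows[i, , drop = FALSE], key))
  ranked <- .selectRecord(records)
  new("EnrichmentResult", key = key, protein = ranked[[1]],
      ambiguousMatches = ranked[-1])
}

#' Look up a protein record through an endpoint client
#'
#' @param key accession or PDB identifier.
#' @param client endpoint client (see [fixtureEndpointClient()]).
#' @param type `"accession"` or `"pdb"`, selecting the query builder.
#' @param endpoint SPARQL endpoint IRI.
#' @return an [EnrichmentResult-class], or `NULL` when no entry matched.
#' @export
lookupProtein <- function(key, client, type = c("accession", "pdb"),
                          endpoint = .UNIPROT_ENDPOINT) {
  type <- match.arg(type)
  query <- if (type == "accession") buildAccessionQuery(key, endpoint)
           else buildPdbQuery(key, endpoint)
  rows <- .clientExecute(client, query)
  if (!NROW(rows)) return(NULL)
  .rowsToResult(rows, key)
}

#' Enrich an alignment with UniProtKB protein records
#'
#' For each distinct accession number carried by the alignment's sequences,
#' one federated query is executed through the injected client; returned
#' rows become [ProteinRecord-class]s, and each matched sequence is linked
#' to its protein via a `hasAssociationWithProtein` triple merged into the
#' graph. The alignment itself is never mutated. Endpoint failures degrade
#' gracefully: the failing accession is reported and the rest proceed.
#' Where one key maps to several entries, the record with the strongest
#' protein-existence evidence (lowest PE code; ties by accession) is
#' selected and the other candidates are surfaced as `ambiguousMatches` for
#' expert review.
#'
#' @param alignment an [Alignment-class] whose sequences carry accessions.
#' @param client endpoint client (see [fixtureEndpointClient()]).
#' @param registry a [SchemaRegistry-class].
#' @param policy an [IriPolicy-class].
#' @param graph optional [TripleGraph-class] to merge into; defaults to
#'   `toRdf(alignment, registry, policy)`.
#' @param endpoint SPARQL endpoint IRI used in the generated queries.
#' @return list with `results` (list of [EnrichmentResult-class]),
#'   `failures` (named character: accession -> reason) and `graph` (the
#'   updated [TripleGraph-class]).
#' @export
enrichAlignment <- function(alignment, client, registry = builtinSchema(),
                            policy = iriPolicy(), graph = NULL,
                            endpoint = .UNIPROT_ENDPOINT) {
  stopifnot(is(alignment, "Alignment"))
  if (is.null(graph)) graph <- toRdf(alignment, registry, policy)
  base <- policy@base
  alnId <- alignment@alignmentId
  seqAcc <- list()
  for (sub in alignment@subAlignments)
    for (seq in sub@sequences)
      if (!is.na(seq@accessionNumber))
        seqAcc[[length(seqAcc) + 1L]] <-
          c(id = seq@identifier, acc = seq@accessionNumber)
  accs <- unique(vapply(seqAcc, `[[`, character(1), "acc"))
  results <- list()
  failures <- character()
  newRows <- list()
  for (acc in accs) {
    rows <- tryCatch(
      .clientExecute(client, buildAccessionQuery(acc, endpoint)),
      error = function(e) e)
    if (inherits(rows, "error")) {
      failures[acc] <- conditionMessage(rows)
      next
    }
    if (!NROW(rows)) {
      failures[acc] <- "no matching UniProtKB entry"
      next
    }
    result <- .rowsToResult(rows, acc)
    results[[length(results) + 1L]] <- result
    proteinIri <- paste0(base, "protein_", .sanitizeLocal(acc))
    newRows[[length(newRows) + 1L]] <-
      .tripleRow(proteinIri, .RDF_TYPE, paste0(base, "Protein"))
    newRows[[length(newRows) + 1L]] <-
      .tripleRow(proteinIri, paste0(base, "accessionNumber"),
                 result@protein@accessionNumber, "literal", NA_character_)
    for (sa in seqAcc)
      if (sa[["acc"]] == acc)
        newRows[[length(newRows) + 1L]] <-
          .tripleRow(mintIri(policy, alnId, sa[["id"]]),
                     paste0(base, "hasAssociationWithProtein"), proteinIri)
  }
  if (length(newRows))
    graph <- addTriples(graph, do.call(rbind, newRows))
  list(results = results, failures = failures, graph = graph)
}

# ---- description lines -----------------------------------------------------

#' Generate a UniProtKB FASTA description line
#'
#' `>db|UniqueIdentifier|EntryName ProteinName OS=OrganismName GN=GeneName
#' PE=N`, in that order; an absent optional field omits its token entirely.
#' `db` defaults to `"sp"`; a missing entry name is rendered as `UNKNOWN` to
#' keep the mandatory `db|id|entry` triplet well-formed.
#'
#' @param record a [ProteinRecord-class].
#' @return the description line, including the leading `>`, no newline.
#' @examples
#' rec <- ProteinRecord("P69905", entryName = "HBA_HUMAN",
#'                      proteinName = "Hemoglobin subunit alpha",
#'                      organismName = "Homo sapiens", geneName = "HBA1",
#'                      proteinExistence = 1L, dbTag = "sp")
#' uniprotHeader(rec)
#' @export
uniprotHeader <- function(record) {
  stopifnot(is(record, "ProteinRecord"))
  acc <- record@accessionNumber
  if (is.na(acc) || !nzchar(acc)) stop("record has no unique identifier")
  db <- if (is.na(record@dbTag)) "sp" else record@dbTag
  entry <- if (is.na(record@entryName)) "UNKNOWN" else record@entryName
  h <- paste0(">", db, "|", acc, "|", entry)
  if (!is.na(record@proteinName)) h <- paste(h, record@proteinName)
  if (!is.na(record@organismName)) h <- paste0(h, " OS=", record@organismName)
  if (!is.na(record@geneName)) h <- paste0(h, " GN=", record@geneName)
  if (!is.na(record@proteinExistence))
    h <- paste0(h, " PE=", record@proteinExistence)
  if (grepl("[\r\n]", h)) stop("header fields must not contain newlines")
  h
}

#' Generate an NCBI-style FASTA description line
#'
#' `>accession description [OrganismName]`; the organism bracket is omitted
#' when the organism is unknown.
#'
#' @inheritParams uniprotHeader
#' @return the description line, including the leading `>`, no newline.
#' @export
ncbiHeader <- function(record) {
  stopifnot(is(record, "ProteinRecord"))
  acc <- record@accessionNumber
  if (is.na(acc) || !nzchar(acc)) stop("record has no accession")
  h <- paste0(">", acc)
  if (!is.na(record@proteinName)) h <- paste(h, record@proteinName)
  if (!is.na(record@organismName))
    h <- paste0(h, " [", record@organismName, "]")
  if (grepl("[\r\n]", h)) stop("header fields must not contain newlines")
  h
}
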