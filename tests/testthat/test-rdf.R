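test_that("IRI minting is deterministic and follows the instance pattern", {
  pol <- iriPolicy()
  expect_equal(mintIri(pol, "BB11001", "1aab_"),
               "https://w3id.org/salon#BB11001_1aab_")
  expect_equal(mintIri(pol, "A B", "x/y"),
               "https://w3id.org/salon#A_B_x_y")
  expect_identical(mintIri(pol, "BB11001", "1aab_"),
                   mintIri(pol, "BB11001", "1aab_"))
  expect_error(mintIri(pol, "", "x"), "non-empty")
  expect_error(mintIri(pol, "x", ""), "non-empty")
  custom <- iriPolicy("http://example.org/aln#")
  expect_match(mintIri(custom, "A", "b"), "^http://example.org/aln#A_b$")
  expect_error(iriPolicy("not-an-iri"), "absolute")
})

test_that("forward and inverse relation triples are both materialized", {
  aln <- generateAlignment(nSequences = 2, nColumns = 5, seed = 2)
  g <- toRdf(aln)
  tr <- triples(g)
  ns <- baseNamespace(g)
  count <- function(p) sum(tr$predicate == paste0(ns, p))
  expect_equal(count("hasSequence"), 2L)
  expect_equal(count("isSequenceOf"), 2L)
  expect_equal(count("hasSubAlignment"), 1L)
  expect_equal(count("isSubalignmentOf"), 1L)
  expect_equal(count("hasColumn"), count("isColumnOf"))
  expect_equal(count("hasFeature"), count("isFeatureOf"))
  # literal for the accession is present and typed as a plain string
  accRows <- tr[tr$predicate == paste0(ns, "accessionNumber"), , drop = FALSE]
  expect_true("P00001" %in% accRows$object)
  expect_true(all(accRows$objectType == "literal"))
})

test_that("every emitted predicate is registered in the schema", {
  reg <- builtinSchema()
  aln <- generateAlignment(nSequences = 3, nColumns = 8, nFeatures = 2,
                           seed = 5)
  g <- toRdf(aln, reg)
  expect_length(graphSchemaViolations(g, reg), 0L)
  tr <- triples(g)
  ns <- baseNamespace(g)
  rdfType <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  locals <- sub(ns, "", tr$predicate[tr$predicate != rdfType], fixed = TRUE)
  registered <- c(objectProperties(reg)$name, dataProperties(reg)$name)
  expect_true(all(locals %in% registered))
})

test_that("mapping an alignment without sub-alignments is refused", {
  expect_error(toRdf(Alignment("empty")), "at least one SubAlignment")
})

test_that("all four serializations round-trip the triple set", {
  aln <- generateAlignment(nSequences = 3, nColumns = 6, nFeatures = 1,
                           seed = 9)
  g <- toRdf(aln)
  for (f in c("turtle", "rdfxml", "ntriples", "jsonld")) {
    expect_true(sameTripleSet(parseRdf(serializeRdf(g, f), f), g), info = f)
  }
  # empty graphs serialize to valid documents in every format
  empty <- TripleGraph()
  for (f in c("turtle", "rdfxml", "ntriples", "jsonld")) {
    expect_true(sameTripleSet(parseRdf(serializeRdf(empty, f), f), empty),
                info = f)
  }
  expect_error(serializeRdf(g, "csv"), "turtle, rdfxml, ntriples, jsonld")
})

test_that("literals with quotes, newlines and tabs survive serialization", {
  rows <- rbind(
    data.frame(subject = "https://w3id.org/salon#X_s1",
               predicate = "http://www.w3.org/1999/02/22-rdf-syntax-ns#type",
               object = "https://w3id.org/salon#AlignmentSequence",
               objectType = "iri", datatype = NA_character_),
    data.frame(subject = "https://w3id.org/salon#X_s1",
               predicate = "https://w3id.org/salon#organism",
               object = "weird \"name\"\nwith\ttabs \\ backslash",
               objectType = "literal", datatype = NA_character_))
  g <- TripleGraph(rows)
  for (f in c("turtle", "rdfxml", "ntriples", "jsonld"))
    expect_true(sameTripleSet(parseRdf(serializeRdf(g, f), f), g), info = f)
})

test_that("the model reconstructed from RDF equals the original", {
  for (seed in c(3, 8)) {
    aln <- generateAlignment(nSequences = 3, nColumns = 7, nFeatures = 2,
                             seed = seed)
    for (f in c("turtle", "ntriples")) {
      back <- fromRdf(serializeRdf(toRdf(aln), f), f)
      expect_length(back$violations, 0L)
      expect_same_model(back$alignment, aln)
    }
  }
})

test_that("a graph carrying only inverse triples reconstructs the same model", {
  aln <- generateAlignment(nSequences = 2, nColumns = 5, seed = 6)
  g <- toRdf(aln)
  tr <- triples(g)
  ns <- baseNamespace(g)
  forward <- paste0(ns, c("hasSequence", "hasSubAlignment"))
  onlyInverse <- TripleGraph(tr[!tr$predicate %in% forward, , drop = FALSE],
                             ns)
  back <- alignmentFromGraph(onlyInverse)
  expect_same_model(back$alignment, alignmentFromGraph(g)$alignment)
})

test_that("schema violations in a graph are collected, not dropped", {
  aln <- generateAlignment(nSequences = 2, nColumns = 4, seed = 1)
  g <- toRdf(aln)
  tr <- triples(g)
  ns <- baseNamespace(g)
  # delete the rdf:type of one sequence node
  seqIri <- tr$object[tr$predicate == paste0(ns, "hasSequence")][1]
  rdfType <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
  broken <- TripleGraph(tr[!(tr$subject == seqIri & tr$predicate == rdfType), ,
                           drop = FALSE], ns)
  v <- graphSchemaViolations(broken)
  expect_gt(length(v), 0L)
  expect_true(all(vapply(v, ruleId, character(1)) == "schema_assertion"))
  expect_true(any(grepl("no rdf:type", vapply(v, function(x) x@detail,
                                              character(1)))))
})

test_that("alignment scores survive the RDF round-trip with their bounds", {
  aln <- generateAlignment(nSequences = 2, nColumns = 4, seed = 12)
  fn <- ScoreFunction("percent_totally_conserved", "alignment", 0, 100)
  aln@alignmentScores <- list(Score(62.5, fn))
  back <- fromRdf(serializeRdf(toRdf(aln), "jsonld"), "jsonld")$alignment
  expect_length(alignmentScores(back), 1L)
  sc <- alignmentScores(back)[[1]]
  expect_equal(scoreValue(sc), 62.5)
  expect_equal(scoreFunction(sc)@name, "percent_totally_conserved")
  expect_equal(c(scoreFunction(sc)@scoreMin, scoreFunction(sc)@scoreMax),
               c(0, 100))
})

test_that("the SPARQL update export wraps the statements in INSERT DATA", {
  g <- toRdf(generateAlignment(nSequences = 2, nColumns = 3, seed = 4))
  upd <- sparqlUpdate(g)
  expect_match(upd, "^INSERT DATA \\{")
  expect_equal(length(gregexpr(" \\.\n", upd)[[1]]), nrow(triples(g)))
})
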