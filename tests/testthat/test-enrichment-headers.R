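test_that("query builders emit deterministic, keyed, federated SPARQL", {
  q <- buildAccessionQuery("1D2N")
  expect_match(q, "SELECT ")
  expect_match(q, "SERVICE <https://sparql.uniprot.org/sparql>", fixed = TRUE)
  expect_match(q, "VALUES \\?accession \\{ \"1D2N\" \\}")
  expect_identical(q, buildAccessionQuery("1D2N"))
  p <- buildPdbQuery("1AAB")
  for (field in c("db", "uniqueIdentifier", "entryName", "proteinName",
                  "organismName", "geneName", "proteinExistence"))
    expect_match(p, paste0("\\?", field))
  expect_identical(p, buildPdbQuery("1AAB"))
  expect_error(buildAccessionQuery(""), "non-empty")
  expect_error(buildPdbQuery(""), "non-empty")
  # quotes in keys are escaped inside the literal
  injected <- buildAccessionQuery("bad\"} SERVICE <evil>")
  expect_match(injected, "{ \"bad\\\"} SERVICE <evil>\" }", fixed = TRUE)
  custom <- buildAccessionQuery("X1", endpoint = "http://example.org/sparql")
  expect_match(custom, "SERVICE <http://example.org/sparql>", fixed = TRUE)
})

test_that("enrichment links proteins without mutating the alignment", {
  aln <- generateAlignment(nSequences = 2, nColumns = 6, seed = 3)
  before <- modelDigest(aln)
  client <- fixtureEndpointClient(list(
    P00001 = responseRow("P00001"),
    P00002 = responseRow("P00002", entry = "TST2_HUMAN", gene = "TST2")))
  res <- enrichAlignment(aln, client)
  expect_length(res$results, 2L)
  expect_length(res$failures, 0L)
  expect_equal(modelDigest(aln), before)
  tr <- triples(res$graph)
  ns <- baseNamespace(res$graph)
  assoc <- tr[tr$predicate == paste0(ns, "hasAssociationWithProtein"), ,
              drop = FALSE]
  expect_equal(nrow(assoc), 2L)
  expect_setequal(assoc$subject, paste0(ns, c("SYN3_seq1", "SYN3_seq2")))
  # protein nodes are typed and carry their accession
  protein <- paste0(ns, "protein_P00001")
  expect_true(protein %in% assoc$object)
  expect_true(any(tr$subject == protein & tr$objectType == "literal" &
                  tr$object == "P00001"))
  # the enriched graph still passes the schema assertions
  expect_length(graphSchemaViolations(res$graph), 0L)
})

test_that("endpoint failures degrade gracefully per accession", {
  aln <- generateAlignment(nSequences = 2, nColumns = 6, seed = 3)
  failing <- fixtureEndpointClient(failFor = c("P00001", "P00002"))
  res <- enrichAlignment(aln, failing)
  expect_length(res$results, 0L)
  expect_setequal(names(res$failures), c("P00001", "P00002"))
  # graph unchanged relative to the plain mapping
  expect_true(sameTripleSet(res$graph, toRdf(aln)))
  # a client that errors on some keys still enriches the others
  partial <- fixtureEndpointClient(list(P00002 = responseRow("P00002")),
                                   failFor = "P00001")
  res2 <- enrichAlignment(aln, partial)
  expect_length(res2$results, 1L)
  expect_equal(names(res2$failures), "P00001")
})

test_that("ambiguous PDB mappings surface every candidate", {
  rows <- rbind(responseRow("P11111", pe = 2, entry = "AAA_YEAST"),
                responseRow("P00009", pe = 1, entry = "BBB_HUMAN"),
                responseRow("P22222", pe = 1, entry = "CCC_MOUSE"))
  client <- fixtureEndpointClient(list(`1AAB` = rows))
  result <- lookupProtein("1AAB", client, type = "pdb")
  expect_s4_class(result, "EnrichmentResult")
  expect_length(result@ambiguousMatches, 2L)
  # strongest protein-existence evidence wins, ties broken by accession
  expect_equal(result@protein@accessionNumber, "P00009")
  others <- vapply(result@ambiguousMatches,
                   function(r) r@accessionNumber, character(1))
  expect_setequal(others, c("P11111", "P22222"))
  expect_null(lookupProtein("9ZZZ", client, type = "pdb"))
})

test_that("description lines include exactly the populated fields in order", {
  full <- ProteinRecord("P69905", entryName = "HBA_HUMAN",
                        proteinName = "Hemoglobin subunit alpha",
                        organismName = "Homo sapiens", geneName = "HBA1",
                        proteinExistence = 1L, dbTag = "sp")
  expect_equal(uniprotHeader(full),
               paste0(">sp|P69905|HBA_HUMAN Hemoglobin subunit alpha ",
                      "OS=Homo sapiens GN=HBA1 PE=1"))
  noGene <- ProteinRecord("P1", entryName = "E_X", proteinName = "N")
  expect_false(grepl("GN=", uniprotHeader(noGene)))
  expect_equal(ncbiHeader(full),
               ">P69905 Hemoglobin subunit alpha [Homo sapiens]")
  noOrg <- ProteinRecord("P1", proteinName = "thing")
  expect_false(grepl("\\[", ncbiHeader(noOrg)))
  expect_error(ProteinRecord(NA_character_), "non-empty")
})

test_that("generate-then-parse is the identity on populated header fields", {
  set.seed(99)
  for (i in 1:60) {
    rec <- randomProteinRecord()
    # UniProtKB dialect
    up <- parseFasta(paste0(uniprotHeader(rec), "\nMKWV"),
                     "uniprotkb")[[1]]@parsedFields
    expect_equal(up$unique_identifier, rec@accessionNumber)
    expect_equal(up$db, rec@dbTag)
    if (!is.na(rec@proteinName))
      expect_equal(up$protein_name, rec@proteinName)
    if (!is.na(rec@organismName))
      expect_equal(up$organism_name, rec@organismName)
    if (!is.na(rec@geneName)) expect_equal(up$gene_name, rec@geneName)
    if (!is.na(rec@proteinExistence))
      expect_equal(up$protein_existence, rec@proteinExistence)
    # NCBI dialect
    nc <- parseFasta(paste0(ncbiHeader(rec), "\nMKWV"),
                     "ncbi")[[1]]@parsedFields
    expect_equal(nc$accession, rec@accessionNumber)
    if (!is.na(rec@proteinName)) expect_equal(nc$description, rec@proteinName)
    if (!is.na(rec@organismName)) expect_equal(nc$organism, rec@organismName)
  }
})
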