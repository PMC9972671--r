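test_that("MACSIM XML round-trips the model field-for-field", {
  for (seed in c(1, 2, 3)) {
    aln <- generateAlignment(nSequences = 3, nColumns = 12, nFeatures = 2,
                             seed = seed)
    expect_same_model(parseMacsim(writeMacsim(aln)), aln)
  }
  # feature fields are copied verbatim
  xml <- writeMacsim(generateAlignment(nSequences = 2, nColumns = 10,
                                       nFeatures = 1, seed = 4))
  expect_match(xml, "<fitem>")
  expect_match(xml, "<fstart>")
})

test_that("MACSIM parsing maps the published elements", {
  xml <- paste0(
    "<macsim><alignment><aln-name>BB11001</aln-name>",
    "<sequence seq-type=\"Protein\"><seq-name>1aab_</seq-name>",
    "<accession>P12345</accession>",
    "<fitem><ftype>DOMAIN</ftype><fstart>3</fstart><fstop>7</fstop>",
    "<fnote>HMG box</fnote></fitem>",
    "<sequence>MKVLI--AC</sequence></sequence>",
    "<sequence seq-type=\"Protein\"><seq-name>1j46_A</seq-name>",
    "<sequence>MKVLIWQAC</sequence></sequence>",
    "</alignment></macsim>")
  aln <- parseMacsim(xml)
  expect_equal(alignmentId(aln), "BB11001")
  sub <- subAlignments(aln)[[1]]
  expect_equal(subAlignmentName(sub), "BB11001")
  seqs <- alignmentSequences(sub)
  expect_equal(seqIdentifier(seqs[[1]]), "1aab_")
  expect_equal(accessionNumber(seqs[[1]]), "P12345")
  expect_equal(moleculeType(seqs[[1]]), "Protein")
  expect_s4_class(seqs[[1]], "AlignmentSequence")
  f <- features(seqs[[1]])[[1]]
  expect_equal(c(f@fstart, f@fstop), c(3L, 7L))
  expect_equal(f@ftype, "DOMAIN")
  expect_equal(gapCharacter(sub), "-")
})

test_that("MACSIM errors are informative", {
  expect_error(parseMacsim("<macsim><alignment>"), "parse error")
  noName <- paste0("<macsim><alignment><aln-name>x</aln-name>",
                   "<sequence seq-type=\"Protein\">",
                   "<sequence>MK</sequence></sequence>",
                   "</alignment></macsim>")
  expect_error(parseMacsim(noName), "sequence 1 has no <seq-name>")
})

test_that("unknown MACSIM elements survive a read/write round-trip", {
  xml <- paste0(
    "<macsim><alignment><aln-name>x</aln-name>",
    "<sequence seq-type=\"Protein\"><seq-name>s1</seq-name>",
    "<organism>Homo sapiens</organism>",
    "<sequence>MKA</sequence></sequence>",
    "<sequence seq-type=\"Protein\"><seq-name>s2</seq-name>",
    "<sequence>MKC</sequence></sequence>",
    "</alignment></macsim>")
  out <- writeMacsim(parseMacsim(xml))
  expect_match(out, "<organism>Homo sapiens</organism>", fixed = TRUE)
  again <- parseMacsim(out)
  expect_equal(alignmentSequences(subAlignments(again)[[1]])[[1]]@passthrough,
               "<organism>Homo sapiens</organism>")
})

test_that("an empty sub-alignment name is preserved as an empty element", {
  seqs <- list(AlignmentSequence("a", "MK"), AlignmentSequence("b", "ML"))
  aln <- Alignment("X", list(SubAlignment(seqs, name = "")))
  xml <- writeMacsim(aln)
  back <- parseMacsim(xml, alignmentId = "X")
  expect_equal(subAlignmentName(subAlignments(back)[[1]]), "")
})

test_that("UniProtKB description lines parse into the published fields", {
  recs <- parseFasta(paste0(
    ">sp|P69905|HBA_HUMAN Hemoglobin subunit alpha OS=Homo sapiens ",
    "GN=HBA1 PE=1\nMVLSPADKTN"), dialect = "uniprotkb")
  f <- recs[[1]]@parsedFields
  expect_equal(f$db, "sp")
  expect_equal(f$unique_identifier, "P69905")
  expect_equal(f$entry_name, "HBA_HUMAN")
  expect_equal(f$protein_name, "Hemoglobin subunit alpha")
  expect_equal(f$organism_name, "Homo sapiens")
  expect_equal(f$gene_name, "HBA1")
  expect_equal(f$protein_existence, 1L)
  # absent optional fields are absent, never empty strings
  minimal <- parseFasta(">sp|Q1|E_X\nMK", dialect = "uniprotkb")[[1]]
  expect_false("gene_name" %in% names(minimal@parsedFields))
  expect_false("protein_name" %in% names(minimal@parsedFields))
  # unknown modifiers are retained verbatim
  extra <- parseFasta(">sp|Q1|E_X Name OX=9606 SV=2\nMK",
                      dialect = "uniprotkb")[[1]]
  expect_equal(extra@parsedFields$extra_tags, c(OX = "9606", SV = "2"))
})

test_that("NCBI description lines parse accession, description and organism", {
  rec <- parseFasta(">NP_000549.1 hemoglobin subunit alpha [Homo sapiens]\nMV",
                    dialect = "ncbi")[[1]]
  expect_equal(rec@parsedFields$accession, "NP_000549.1")
  expect_equal(rec@parsedFields$description, "hemoglobin subunit alpha")
  expect_equal(rec@parsedFields$organism, "Homo sapiens")
  bare <- parseFasta(">XP_1\nMV", dialect = "ncbi")[[1]]
  expect_equal(names(bare@parsedFields), "accession")
})

test_that("FASTA format and dialect errors are raised", {
  expect_error(parseFasta("ACDE"), "does not start with '>'")
  expect_error(parseFasta(""), "empty input")
  expect_error(parseFasta(">sp-P69905-HBA\nMK", dialect = "uniprotkb"),
               "separators")
})

test_that("FASTA writing wraps residues and round-trips fields", {
  rec <- parseFasta(paste0(">seq1\n", paste(rep("ACDEFGHIKL", 13),
                                            collapse = "")))[[1]]
  out <- writeFasta(list(rec), lineWidth = 60)
  lines <- strsplit(out, "\n")[[1]]
  expect_equal(sum(!startsWith(lines, ">")), 3L)  # ceil(130 / 60)
  expect_equal(lines[1], ">seq1")
  # dialect round-trip identity on parsed fields and residues
  set.seed(21)
  for (i in 1:10) {
    rec <- randomProteinRecord()
    fasta <- paste0(uniprotHeader(rec), "\nMKVLIWQACDE")
    parsed <- parseFasta(fasta, "uniprotkb")
    rewritten <- writeFasta(parsed, "uniprotkb", lineWidth = 5)
    reparsed <- parseFasta(rewritten, "uniprotkb")
    expect_equal(reparsed[[1]]@parsedFields, parsed[[1]]@parsedFields)
    expect_equal(reparsed[[1]]@residues, parsed[[1]]@residues)
  }
})

test_that("no FASTA record is silently dropped", {
  set.seed(3)
  n <- 7
  text <- paste(vapply(seq_len(n), function(i)
    paste0(">rec", i, "\n",
           paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
                 collapse = "")), character(1)), collapse = "\n")
  expect_length(parseFasta(text), n)
})
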