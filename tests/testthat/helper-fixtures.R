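# Shared fixture builders and model comparison helpers.

twentyResidueColumn <- function() paste(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                        collapse = "")

# worked-example fixture: alignment score 95 under a [0, 100] maximization
# function plus one column scoring 1 under a [0, 1] function
fig2Alignment <- function(alignmentScore = 95, columnScore = 1) {
  alnFn <- ScoreFunction("percent_conserved", "alignment", 0, 100)
  colFn <- ScoreFunction("percent_conserved", "column", 0, 1)
  seqs <- list(AlignmentSequence("seqA", "MK"),
               AlignmentSequence("seqB", "MK"))
  sub <- SubAlignment(seqs, name = "demo")
  cols <- buildColumns(sub)
  cols[[1]]@columnScores <- list(Score(columnScore, colFn))
  Alignment("FIG2", subAlignments = list(sub),
            alignmentScores = list(Score(alignmentScore, alnFn)),
            columns = cols)
}

featureDigest <- function(f) {
  list(ftype = f@ftype, fstart = f@fstart, fstop = f@fstop,
       fnote = f@fnote, fscore = f@fscore)
}

sequenceDigest <- function(s) {
  list(identifier = s@identifier, accession = s@accessionNumber,
       residues = s@residues, length = s@length, organism = s@organism,
       keywords = s@keywords, molecule = s@molecule,
       features = lapply(s@features, featureDigest))
}

scoreDigest <- function(sc) {
  fn <- sc@scoreFunction
  list(value = sc@value, fnName = fn@name, kind = fn@kind,
       scoreMin = fn@scoreMin, scoreMax = fn@scoreMax)
}

modelDigest <- function(a) {
  list(
    alignmentId = a@alignmentId,
    subs = lapply(a@subAlignments, function(sub) list(
      name = sub@name, gap = sub@gapCharacter,
      sequences = lapply(sub@sequences, sequenceDigest))),
    scores = lapply(a@alignmentScores, scoreDigest))
}

expect_same_model <- function(a, b) {
  expect_equal(modelDigest(a), modelDigest(b))
}

# random ProteinRecord with optional fields present at random
randomProteinRecord <- function() {
  word <- function(n) paste(sample(c(LETTERS, letters, 0:9), n, replace = TRUE),
                            collapse = "")
  phrase <- function(k) paste(replicate(k, word(sample(3:8, 1))), collapse = " ")
  maybe <- function(x) if (runif(1) < 0.3) NA_character_ else x
  pe <- if (runif(1) < 0.3) NA_integer_ else sample(1:5, 1)
  ProteinRecord(
    accessionNumber = word(6),
    entryName = maybe(paste0(word(4), "_", word(5))),
    proteinName = maybe(phrase(sample(1:4, 1))),
    organismName = maybe(phrase(2)),
    geneName = maybe(word(5)),
    proteinExistence = pe,
    dbTag = sample(c("sp", "tr"), 1))
}

# offline endpoint response rows for one accession
responseRow <- function(accession, pe = 1, entry = "TST1_HUMAN",
                        name = "Test protein", organism = "Homo sapiens",
                        gene = "TST1", db = "sp") {
  data.frame(accession = accession, entry_name = entry, protein_name = name,
             organism_name = organism, gene_name = gene,
             protein_existence = pe, db = db, stringsAsFactors = FALSE)
}
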