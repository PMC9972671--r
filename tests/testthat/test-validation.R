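test_that("score bounds are inclusive and fire at most one rule per score", {
  fn <- ScoreFunction("pc", "alignment", 0, 100)
  expect_length(checkScoreBounds(Score(95, fn)), 0L)
  expect_length(checkScoreBounds(Score(0, fn)), 0L)
  expect_length(checkScoreBounds(Score(100, fn)), 0L)
  over <- checkScoreBounds(Score(101, fn))
  expect_equal(ruleId(over[[1]]), "alignment_score_gt_max")
  under <- checkScoreBounds(Score(-1, fn))
  expect_equal(ruleId(under[[1]]), "alignment_score_lt_min")
  colFn <- ScoreFunction("pc", "column", 0, 1)
  expect_equal(ruleId(checkScoreBounds(Score(2, colFn))[[1]]),
               "column_score_gt_max")
  expect_equal(ruleId(checkScoreBounds(Score(-0.5, colFn))[[1]]),
               "column_score_lt_min")
  # no declared bounds disables the check with a warning
  expect_warning(v <- checkScoreBounds(Score(1e6, ScoreFunction("free", "column"))),
                 "no bounds")
  expect_length(v, 0L)
})

test_that("bound checking matches a brute-force interval oracle", {
  set.seed(17)
  for (i in 1:200) {
    lo <- round(runif(1, -50, 50), 2)
    hi <- lo + round(runif(1, 0, 100), 2)
    v <- round(runif(1, -100, 200), 2)
    kind <- sample(c("alignment", "column"), 1)
    fn <- ScoreFunction("f", kind, lo, hi)
    res <- checkScoreBounds(Score(v, fn))
    if (v > hi) {
      expect_length(res, 1L)
      expect_equal(ruleId(res[[1]]), paste0(kind, "_score_gt_max"))
    } else if (v < lo) {
      expect_length(res, 1L)
      expect_match(ruleId(res[[1]]), "_score_lt_min$")
    } else {
      expect_length(res, 0L)
    }
  }
})

test_that("bound verdicts are invariant under positive rescaling", {
  fn <- ScoreFunction("f", "alignment", 0, 100)
  set.seed(8)
  for (i in 1:30) {
    v <- runif(1, -50, 150)
    k <- runif(1, 0.01, 50)
    base <- length(checkScoreBounds(Score(v, fn)))
    scaled <- length(checkScoreBounds(
      Score(v * k, ScoreFunction("f", "alignment", 0 * k, 100 * k))))
    expect_equal(base, scaled)
  }
})

test_that("cardinality checks implement the published minimums", {
  seqs2 <- list(AlignmentSequence("a", "MK"), AlignmentSequence("b", "ML"))
  ok <- Alignment("X", list(SubAlignment(seqs2)))
  expect_length(checkCardinality(ok), 0L)
  one <- Alignment("X", list(SubAlignment(seqs2[1])))
  v <- checkCardinality(one)
  expect_length(v, 1L)
  expect_equal(ruleId(v[[1]]), "subalignment_min_sequences")
  none <- Alignment("X")
  expect_equal(ruleId(checkCardinality(none)[[1]]),
               "alignment_min_subalignments")
})

test_that("the worked example validates as correct and perturbs as incorrect", {
  report <- validateAlignment(fig2Alignment())
  expect_equal(verdict(report), "correct")
  expect_length(violations(report), 0L)
  bad <- validateAlignment(fig2Alignment(alignmentScore = -1))
  expect_equal(verdict(bad), "incorrect")
  expect_equal(vapply(violations(bad), ruleId, character(1)),
               "alignment_score_lt_min")
  badCol <- validateAlignment(fig2Alignment(columnScore = 1.5))
  expect_equal(vapply(violations(badCol), ruleId, character(1)),
               "column_score_gt_max")
})

test_that("reliability flags columns without flipping the verdict", {
  aln <- fig2Alignment()
  guidance <- ReliabilityMeasure("GUIDANCE", 0.5, "below_cutoff",
                                 scoreMin = 0, scoreMax = 1)
  gFn <- ScoreFunction("GUIDANCE", "column", 0, 1)
  aln@columns[[1]]@columnScores <-
    c(aln@columns[[1]]@columnScores, list(Score(0.9, gFn)))
  aln@columns[[2]]@columnScores <- list(Score(0.2, gFn))
  report <- validateAlignment(aln, measures = list(guidance))
  expect_equal(verdict(report), "correct")
  expect_equal(unreliableColumns(report), 2L)
  rules <- vapply(violations(report), ruleId, character(1))
  expect_true("unreliable_column" %in% rules)
  # direct check interface
  v <- checkReliability(aln, guidance)
  expect_length(v, 1L)
  expect_match(v[[1]]@subject, "column 2")
  # a column missing the measure's score errors naming the column
  aln@columns[[2]]@columnScores <- list()
  expect_error(checkReliability(aln, guidance), "column 2 has no score")
})

test_that("validate is pure and deterministic", {
  aln <- fig2Alignment(alignmentScore = 120)
  r1 <- validateAlignment(aln)
  r2 <- validateAlignment(aln)
  expect_equal(reportAsJson(r1), reportAsJson(r2))
  expect_equal(verdict(r1), "incorrect")
})

test_that("validation reports serialize to JSON with the rule vocabulary", {
  report <- validateAlignment(fig2Alignment(alignmentScore = 101))
  json <- jsonlite::fromJSON(reportAsJson(report), simplifyVector = FALSE)
  expect_equal(json$verdict, "incorrect")
  expect_equal(json$violations[[1]]$rule_id, "alignment_score_gt_max")
})

test_that("the exported SWRL rule texts cover the published rule set", {
  rules <- swrlRuleTexts()
  expect_setequal(names(rules),
                  c("correctness", "column_score_gt_max",
                    "column_score_lt_min", "alignment_score_gt_max",
                    "alignment_score_lt_min", "unreliable_column"))
  expect_true(all(grepl("->", rules)))
  expect_match(rules["correctness"], "swrlb:lessThanOrEqual")
})
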