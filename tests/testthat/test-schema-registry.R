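test_that("built-in registry matches the published object property table", {
  reg <- builtinSchema()
  op <- objectProperties(reg)
  expect_equal(nrow(op), 14L)
  expect_equal(sum(op$isInverse), 4L)
  # row-for-row: property -> c(domain, range, inverse)
  expected <- list(
    hasConstructionMethod     = c("SubAlignment", "ConstructionMethod", NA),
    hasAlignmentScore         = c("Alignment", "AlignmentScore", NA),
    hasAlignmentScoreFunction = c("AlignmentScore", "AlignmentScoreFunction", NA),
    hasColumn                 = c("Alignment", "AlignmentColumn", "isColumnOf"),
    hasColumnScore            = c("AlignmentColumn", "ColumnScore", NA),
    hasColumnScoreFunction    = c("ColumnScore", "ColumnScoreFunction", NA),
    hasSubAlignment           = c("Alignment", "SubAlignment", "isSubalignmentOf"),
    hasFeature                = c("AlignmentSequence", "Feature", "isFeatureOf"),
    hasSequence               = c("SubAlignment", "AlignmentSequence", "isSequenceOf"),
    hasAssociationWithProtein = c("SequenceAlignment", "Protein", NA))
  for (nm in names(expected)) {
    row <- lookupProperty(reg, nm)
    expect_equal(unname(c(row$domain, row$range, row$inverseOf)),
                 unname(expected[[nm]]), info = nm)
  }
})

test_that("inverse property pairs round-trip", {
  reg <- builtinSchema()
  op <- objectProperties(reg)
  withInv <- op[!is.na(op$inverseOf), , drop = FALSE]
  expect_equal(nrow(withInv), 8L)  # 4 pairs, both directions declared
  for (i in seq_len(nrow(withInv))) {
    back <- lookupProperty(reg, withInv$inverseOf[i])
    expect_equal(back$inverseOf, withInv$name[i])
    expect_equal(back$domain, withInv$range[i])
    expect_equal(back$range, withInv$domain[i])
  }
})

test_that("data property datatypes follow the vocabulary", {
  reg <- builtinSchema()
  types <- c(identifier = "string", accessionNumber = "string",
             organism = "string", column = "string",
             atSequenceIndex = "integer", columnWeight = "integer",
             length = "integer",
             consensusCharacter = "short", gapCharacter = "short",
             score = "decimal", scoreMax = "decimal", scoreMin = "decimal",
             scoreCutoff = "decimal", FScore = "decimal")
  for (nm in names(types)) {
    def <- lookupProperty(reg, nm)
    expect_false(is.null(def), info = nm)
    expect_equal(def$datatype, unname(types[nm]), info = nm)
  }
})

test_that("class hierarchy resolves subclasses to their parents", {
  reg <- builtinSchema()
  expect_equal(classParents(reg, "ProteinAlignmentSequence"),
               "AlignmentSequence")
  expect_equal(classParents(reg, "DNAAlignmentSequence"),
               "AlignmentSequence")
  expect_equal(classParents(reg, "StochasticApproach"), "ConstructionMethod")
  expect_equal(classParents(reg, "Alignment"), character())
  cls <- schemaClasses(reg)
  expect_equal(sum(cls$topLevel), 11L)
})

test_that("assertions are checked against domain, range and datatype", {
  reg <- builtinSchema()
  expect_true(checkAssertion(reg, "SubAlignment", "hasSequence",
                             "AlignmentSequence")$ok)
  # subclasses of the declared range are accepted
  expect_true(checkAssertion(reg, "SubAlignment", "hasSequence",
                             "ProteinAlignmentSequence")$ok)
  bad <- checkAssertion(reg, "Alignment", "hasSequence", "AlignmentSequence")
  expect_false(bad$ok)
  expect_equal(bad$kind, "domain")
  expect_true(checkAssertion(reg, "AlignmentColumn", "atSequenceIndex",
                             "integer")$ok)
  wrongType <- checkAssertion(reg, "AlignmentColumn", "atSequenceIndex",
                              "decimal")
  expect_equal(wrongType$kind, "datatype")
  unknown <- checkAssertion(reg, "Alignment", "noSuchProperty", "string")
  expect_equal(unknown$kind, "unknown-property")
})

test_that("assertion checking is total over random known-property triples", {
  reg <- builtinSchema()
  classes <- schemaClasses(reg)$name
  props <- c(objectProperties(reg)$name, dataProperties(reg)$name)
  kinds <- c(classes, "string", "integer", "decimal", "short")
  set.seed(11)
  for (i in 1:200) {
    res <- checkAssertion(reg, sample(classes, 1), sample(props, 1),
                          sample(kinds, 1))
    expect_true(is.list(res) && is.logical(res$ok))
    if (!res$ok) expect_true(res$kind %in%
      c("domain", "range", "datatype", "unknown-property"))
  }
})

test_that("the alias domain admits protein associations from sequences", {
  reg <- builtinSchema()
  expect_true(checkAssertion(reg, "AlignmentSequence",
                             "hasAssociationWithProtein", "Protein")$ok)
  expect_true(checkAssertion(reg, "Alignment",
                             "hasAssociationWithProtein", "Protein")$ok)
  expect_false(checkAssertion(reg, "Feature",
                              "hasAssociationWithProtein", "Protein")$ok)
})

test_that("the schema summary covers every registered entity", {
  reg <- builtinSchema()
  summ <- schemaSummary(reg)
  expect_setequal(unique(summ$entity),
                  c("class", "objectProperty", "dataProperty",
                    "cardinalityRule"))
  expect_equal(sum(summ$entity == "objectProperty"), 14L)
  expect_true(all(schemaClasses(reg)$name %in%
                  summ$name[summ$entity == "class"]))
})
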