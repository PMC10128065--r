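rulesFile <- system.file("extdata", "example_pathway_rules.yaml",
                         package = "beeprofiler")

test_that("rule parsing builds the expected expression trees", {
  leaf <- parseStepExpression("K00001")
  expect_identical(leaf, list(op = "KO", ko = "K00001"))

  tree <- parseStepExpression("(K00001 AND K00002) OR K00003")
  expect_identical(tree$op, "ANY")
  expect_length(tree$children, 2L)
  expect_identical(tree$children[[1L]]$op, "ALL")
  expect_identical(tree$children[[2L]]$ko, "K00003")

  # AND binds tighter than OR
  flat <- parseStepExpression("K00001 AND K00002 OR K00003")
  expect_identical(flat$op, "ANY")
  expect_identical(flat$children[[1L]]$op, "ALL")

  expect_error(parseStepExpression("K1 OR K00002"), "invalid KO")
  expect_error(parseStepExpression("K00001 AND"), "unexpected end")
  expect_error(parseStepExpression("(K00001 OR K00002"), "parentheses")
  expect_error(parseStepExpression(""), "empty")
})

test_that("rule files are validated: ids, categories, step lists", {
  rules <- parseRules(rulesFile)
  expect_gt(length(rules), 10L)
  expect_s4_class(rules[[1L]], "PathwayRule")
  expect_false(anyDuplicated(names(rules)) > 0L)

  dup <- tempfile(fileext = ".yaml")
  writeLines(c("- pathway: p1", "  category: energy/carbon",
               "  steps: [K00001]",
               "- pathway: p1", "  category: energy/carbon",
               "  steps: [K00002]"), dup)
  expect_error(parseRules(dup), "duplicate pathway id")

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("- pathway: p1", "  category: energy/carbon",
               "  steps: ['K00001 FOO K00002']"), bad)
  expect_error(parseRules(bad), "p1.*step 1", ignore.case = TRUE)

  empty <- tempfile(fileext = ".yaml")
  writeLines(c("- pathway: p1", "  category: energy/carbon",
               "  steps: []"), empty)
  expect_error(parseRules(empty), "empty step list")
})

test_that("step evaluation follows boolean semantics and matches a naive oracle", {
  expect_true(evaluateStep(parseStepExpression("K00001"), "K00001"))
  expect_false(evaluateStep(parseStepExpression("K00001"), "K00002"))
  expect_false(evaluateStep(parseStepExpression("K00001 AND K00002"), "K00001"))
  expect_true(evaluateStep(parseStepExpression("K00001 OR (K00002 AND K00003)"),
                           c("K00002", "K00003")))

  # 200 random (rule, KO-set) pairs against text-substitution evaluation
  rules <- parseRules(rulesFile)
  pool <- unique(unlist(regmatches(
    unlist(lapply(rules, function(r) r@stepText)),
    gregexpr("K[0-9]{5}", unlist(lapply(rules, function(r) r@stepText))))))
  set.seed(101)
  for (i in seq_len(200L)) {
    rule <- rules[[sample.int(length(rules), 1L)]]
    kos <- randomKoSet(sample.int(length(pool), 1L), pool)
    got <- pathwayCompleteness(rule, kos)
    expect_equal(got$completeness, oracleCompleteness(rule, kos))
    expect_identical(got$nTotal, length(rule@steps))
  }
})

test_that("completeness is an exact rational and the matrix round-trips", {
  rule <- new("PathwayRule", pathwayId = "p", category = "energy/carbon",
              steps = lapply(sprintf("K%05d", 1:4), parseStepExpression),
              stepText = sprintf("K%05d", 1:4))
  got <- pathwayCompleteness(rule, sprintf("K%05d", 1:3))
  expect_identical(got$completeness, 0.75)
  expect_identical(got$nPresent, 3L)
  expect_equal(pathwayCompleteness(rule, character(0L))$completeness, 0)

  # serialized float equals k/n to 12 decimals
  rule7 <- new("PathwayRule", pathwayId = "p7", category = "energy/carbon",
               steps = lapply(sprintf("K%05d", 1:7), parseStepExpression),
               stepText = sprintf("K%05d", 1:7))
  v <- pathwayCompleteness(rule7, sprintf("K%05d", 1:3))
  expect_equal(as.numeric(sprintf("%.12f", v$completeness)), 3 / 7,
               tolerance = 1e-12)

  rules <- simulateRules(6L, c(3L, 4L, 5L, 2L, 6L, 4L), seed = 11)
  planted <- matrix(c(1, 0.75, 0.4, 0.5, 0.5, 0.25,
                      0, 0.25, 1, 1, 1 / 6, 0.75), 2L, 6L, byrow = TRUE)
  ann <- simulateAnnotations(rules, planted, seed = 12)
  cm <- completenessMatrix(rules, ann)
  expect_equal(unname(completeness(cm)), planted)
  expect_identical(dimnames(completeness(cm)),
                   list(names(ann), names(rules)))

  # all KOs of all rules -> row of 1; empty genome -> row of 0
  pool <- unique(unlist(lapply(rules, function(r)
    regmatches(r@stepText, gregexpr("K[0-9]{5}", r@stepText)))))
  full <- GenomeAnnotation("full", ko = stats::setNames(
    as.list(pool), paste0("g", seq_along(pool))))
  none <- GenomeAnnotation("none")
  cm2 <- completenessMatrix(rules, list(full, none))
  expect_true(all(completeness(cm2)["full", ] == 1))
  expect_true(all(completeness(cm2)["none", ] == 0))
})

test_that("completeness is monotone under KO addition and order-invariant", {
  rules <- parseRules(rulesFile)
  pool <- unique(unlist(lapply(rules, function(r)
    regmatches(r@stepText, gregexpr("K[0-9]{5}", r@stepText)))))
  set.seed(77)
  for (i in seq_len(25L)) {
    kos <- randomKoSet(sample.int(length(pool) - 5L, 1L), pool)
    more <- union(kos, randomKoSet(5L, pool))
    before <- vapply(rules, function(r)
      pathwayCompleteness(r, kos)$completeness, numeric(1L))
    after <- vapply(rules, function(r)
      pathwayCompleteness(r, more)$completeness, numeric(1L))
    expect_true(all(after >= before))
    # permutation invariance of the KO set
    shuffled <- vapply(rules, function(r)
      pathwayCompleteness(r, sample(kos))$completeness, numeric(1L))
    expect_identical(before, shuffled)
  }

  # gene order never changes matrix output
  g1 <- GenomeAnnotation("g", ko = list(a = "K00844", b = "K01810",
                                        c = "K00850"))
  g2 <- GenomeAnnotation("g", ko = list(c = "K00850", a = "K00844",
                                        b = "K01810"))
  expect_identical(completeness(completenessMatrix(rules, list(g1))),
                   completeness(completenessMatrix(rules, list(g2))))
})

test_that("CAZyme counting matches the naive oracle and validates labels", {
  g <- GenomeAnnotation("g1", cazymes = list(g1 = "GH13", g2 = "GH13",
                                             g3 = "PL1"))
  cc <- countCazymes(list(g))
  expect_identical(cazymeCounts(cc)["g1", "GH13"], 2L)
  expect_identical(cazymeCounts(cc)["g1", "PL1"], 1L)
  expect_identical(unname(ghTotal(cc)), 2L)
  expect_identical(unname(plTotal(cc)), 1L)

  # a gene in k families contributes 1 to each
  gm <- GenomeAnnotation("gm", cazymes = list(x = c("GH5", "CBM48")))
  ccm <- countCazymes(list(gm))
  expect_identical(cazymeCounts(ccm)["gm", "GH5"], 1L)
  expect_identical(cazymeCounts(ccm)["gm", "CBM48"], 1L)

  empty <- GenomeAnnotation("empty")
  cc2 <- countCazymes(list(g, empty))
  expect_true(all(cazymeCounts(cc2)["empty", ] == 0L))
  expect_identical(ghTotal(cc2)[["empty"]], 0L)

  expect_error(GenomeAnnotation("bad", cazymes = list(g1 = "XYZ9")),
               "malformed CAZyme")

  # random assignment tables vs naive per-gene counting
  set.seed(5)
  fams <- c(paste0("GH", 1:6), paste0("PL", 1:3), "GT2", "CE4", "CBM50")
  for (rep in seq_len(10L)) {
    nGenes <- sample.int(30L, 1L)
    assign <- lapply(seq_len(nGenes), function(i)
      sample(fams, sample.int(3L, 1L)))
    names(assign) <- paste0("gene", seq_len(nGenes))
    g <- GenomeAnnotation("r", cazymes = assign)
    cc <- countCazymes(list(g))
    naive <- table(unlist(assign, use.names = FALSE))
    for (f in names(naive))
      expect_identical(cazymeCounts(cc)["r", f], as.integer(naive[[f]]))
    expect_identical(unname(ghTotal(cc)),
                     as.integer(sum(naive[grepl("^GH", names(naive))])))
  }
})

test_that("categorical completeness tables map to {1, 0.5, 0}", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tpathway\tcall",
               "g1\tlysine\tcomplete", "g1\tvaline\tpartial",
               "g2\tlysine\tabsent", "g2\tvaline\tComplete"), f)
  m <- readCategoricalCompleteness(f)
  expect_equal(m["g1", "lysine"], 1)
  expect_equal(m["g1", "valine"], 0.5)
  expect_equal(m["g2", "lysine"], 0)
  expect_equal(m["g2", "valine"], 1)

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("genome_id\tpathway\tcall", "g1\tlysine\tmaybe"), bad)
  expect_error(readCategoricalCompleteness(bad), "unknown call")
})
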