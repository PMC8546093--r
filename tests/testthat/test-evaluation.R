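mkGraph <- function(nodes, ...) {
  e <- list(...)
  edges <- if (length(e))
    data.frame(parent = vapply(e, `[`, "", 1), child = vapply(e, `[`, "", 2))
  else data.frame(parent = character(), child = character())
  causalGraph(nodes, edges)
}

test_that("stability applies the half-support and 30% orientation rules", {
  nodes <- c("a", "b")
  fwd <- mkGraph(nodes, c("a", "b"))
  rev <- mkGraph(nodes, c("b", "a"))
  empty <- mkGraph(nodes)
  # adjacency in 499 of 1000 graphs -> excluded
  graphs <- c(rep(list(fwd), 499), rep(list(empty), 501))
  st <- orientationStability(graphs)
  expect_identical(nrow(stabilityTable(st)), 0L)
  expect_true(is.na(ambiguousPct(st)))
  # in all graphs, single orientation -> supported, not ambiguous
  st2 <- orientationStability(rep(list(fwd), 10))
  tab2 <- stabilityTable(st2)
  expect_identical(tab2$support, 1)
  expect_false(tab2$ambiguous)
  expect_identical(ambiguousPct(st2), 0)
  # 600 of 1000, 350 forward / 250 reverse -> 0.583/0.417, ambiguous
  graphs3 <- c(rep(list(fwd), 350), rep(list(rev), 250),
               rep(list(empty), 400))
  st3 <- orientationStability(graphs3)
  tab3 <- stabilityTable(st3)
  expect_identical(tab3$support, 0.6)
  expect_equal(tab3$forward_frac, 350 / 600, tolerance = 1e-12)
  expect_equal(tab3$reverse_frac, 250 / 600, tolerance = 1e-12)
  expect_true(tab3$ambiguous)
  expect_identical(ambiguousPct(st3), 100)
})

test_that("precision counts unsupported and contradicted edges", {
  ev <- evidenceBase(
    associative = data.frame(node_a = c("a", "b", "c"),
                             node_b = c("b", "c", "d")),
    causalPositive = data.frame(from = c("a", "b"), to = c("b", "c")),
    causalNegative = data.frame(from = "c", to = "d", context = ""))
  # all edges causal-positive (and associative) -> precision 1
  expect_identical(evidencePrecision(mkGraph(letters[1:4], c("a", "b"),
                                             c("b", "c")), ev), 1)
  # 4 edges: one pair without associative evidence (a-d), one orientation
  # contradicted by a context-free negative (c -> d) -> precision 0.5
  g4 <- mkGraph(letters[1:4], c("a", "b"), c("b", "c"), c("a", "d"),
                c("c", "d"))
  expect_identical(evidencePrecision(g4, ev), 0.5)
  # lone edge associated but negated -> precision 0
  expect_identical(evidencePrecision(mkGraph(letters[1:4], c("c", "d")), ev),
                   0)
  # empty graph -> undefined
  expect_true(is.na(evidencePrecision(mkGraph(letters[1:4]), ev)))
})

test_that("causal recall honours paths, aliases and context vetoes", {
  aliases <- data.frame(
    evidence_name = c("blood pressure", "blood pressure", "stroke"),
    event_code = c("sbp", "dbp", "stroke"))
  ev <- evidenceBase(
    causalPositive = data.frame(from = "blood pressure", to = "stroke"),
    aliases = aliases)
  g <- mkGraph(c("sbp", "dbp", "cevd", "stroke"),
               c("sbp", "cevd"), c("cevd", "stroke"))
  # the path sbp -> cevd -> stroke satisfies blood pressure -> stroke
  expect_identical(causalRecall(g, ev), 1)
  # restricting to direct edges only defeats the path clause
  expect_identical(causalRecall(g, ev, maxPathLen = 1), 0)
  # a direct edge satisfies regardless of other paths
  gd <- mkGraph(c("sbp", "dbp", "cevd", "stroke"), c("dbp", "stroke"))
  expect_identical(causalRecall(gd, ev), 1)
  # context veto: "in patients with x, a does not cause b"
  ev2 <- evidenceBase(
    causalPositive = data.frame(from = c("a", "p", "q"),
                                to = c("b", "b", "b")),
    causalNegative = data.frame(from = "a", to = "b", context = "x"))
  g2 <- mkGraph(c("a", "x", "b", "p", "q"),
                c("a", "x"), c("x", "b"), c("p", "b"))
  # a->x->b vetoed; p->b direct; q->b absent: recall = 1/3 by hand count
  expect_equal(causalRecall(g2, ev2), 1 / 3, tolerance = 1e-12)
  # the context-tagged negative must not veto other relationships
  ev3 <- evidenceBase(causalPositive = data.frame(from = "p", to = "b"),
                      causalNegative = data.frame(from = "a", to = "b",
                                                  context = "x"))
  g3 <- mkGraph(c("p", "x", "b"), c("p", "x"), c("x", "b"))
  expect_identical(causalRecall(g3, ev3), 1)
})

test_that("unmappable evidence nodes are skipped with unchanged denominator", {
  ev <- evidenceBase(causalPositive = data.frame(from = c("a", "ghost"),
                                                 to = c("b", "b")))
  g <- mkGraph(c("a", "b"), c("a", "b"))
  expect_message(r <- causalRecall(g, ev), "maps to no graph node")
  expect_identical(r, 0.5)
})

test_that("associative recall uses skeleton connectivity", {
  g <- mkGraph(letters[1:6], c("a", "b"), c("c", "b"), c("d", "e"))
  ev <- evidenceBase(associative = data.frame(
    node_a = c("a", "a", "d", "a", "b"),
    node_b = c("b", "c", "e", "d", "c")))
  # connected: a-b direct, a-c via b (orientation-blind), d-e direct,
  # b-c via a; not connected: a-d -> 4/5
  expect_equal(associativeRecall(g, ev), 0.8, tolerance = 1e-12)
  # different components are never explained
  ev2 <- evidenceBase(associative = data.frame(node_a = "a", node_b = "f"))
  expect_identical(associativeRecall(g, ev2), 0)
})

test_that("recall and precision react correctly to adding edges", {
  ev <- evidenceBase(
    associative = data.frame(node_a = c("a", "b"), node_b = c("b", "c")),
    causalPositive = data.frame(from = c("a", "b"), to = c("b", "c")))
  g1 <- mkGraph(letters[1:3], c("a", "b"))
  g2 <- mkGraph(letters[1:3], c("a", "b"), c("b", "c"))
  expect_gte(causalRecall(g2, ev), causalRecall(g1, ev))
  expect_gte(associativeRecall(g2, ev), associativeRecall(g1, ev))
  # adding an incorrect edge lowers precision
  g3 <- mkGraph(letters[1:3], c("a", "b"), c("a", "c"))
  expect_lt(evidencePrecision(g3, ev), evidencePrecision(g1, ev))
})

test_that("site comparison pools edges and counts concordance", {
  nodes <- letters[1:5]
  gA <- mkGraph(nodes, c("a", "b"), c("b", "c"), c("c", "d"), c("d", "e"),
                c("a", "e"))
  gB <- mkGraph(nodes, c("a", "b"), c("b", "c"), c("c", "d"))
  # identical pooled sets -> 100% concordant
  cc <- compareSites(rep(list(gA), 4), rep(list(gA), 6))
  expect_identical(attr(cc, "concordance_pct"), 100)
  # 3 of 5 union edges shared -> 60%
  cc2 <- compareSites(rep(list(gA), 10), rep(list(gB), 10))
  expect_identical(attr(cc2, "n_union"), 5L)
  expect_identical(attr(cc2, "n_concordant"), 3L)
  expect_identical(attr(cc2, "concordance_pct"), 60)
  # strong support at one site, absent at the other -> discordant row
  gEmpty <- mkGraph(nodes)
  siteA <- c(rep(list(mkGraph(nodes, c("a", "b"))), 177),
             rep(list(gEmpty), 23))
  siteB <- c(rep(list(mkGraph(nodes, c("a", "b"))), 0),
             rep(list(gEmpty), 200))
  cc3 <- compareSites(siteA, siteB)
  expect_equal(cc3$support_a_pct, 88.5, tolerance = 1e-12)
  expect_equal(cc3$support_b_pct, 0, tolerance = 1e-12)
  expect_false(cc3$concordant)
  # symmetry: swapping sites transposes without changing the counts
  cc4 <- compareSites(rep(list(gB), 10), rep(list(gA), 10))
  expect_identical(attr(cc4, "n_concordant"), attr(cc2, "n_concordant"))
  expect_identical(attr(cc4, "n_union"), attr(cc2, "n_union"))
  expect_equal(cc4$support_a_pct, cc2$support_b_pct)
})

test_that("evidence files and reports round-trip", {
  evFile <- tempfile(fileext = ".csv")
  writeLines(c("type,node_a,node_b,context",
               "assoc,a,b,",
               "causal_pos,a,b,",
               "causal_neg,a,c,x"), evFile)
  alFile <- tempfile(fileext = ".csv")
  writeLines(c("evidence_name,event_code", "a,a1", "a,a2"), alFile)
  ev <- readEvidence(evFile, alFile)
  expect_identical(nrow(ev@associative), 1L)
  expect_identical(ev@causalNegative$context, "x")
  expect_identical(sort(ev@aliases$event_code), c("a1", "a2"))

  st <- orientationStability(rep(list(mkGraph(c("a", "b"), c("a", "b"))), 5))
  f <- tempfile(fileext = ".tsv")
  exportStability(st, f)
  expect_equal(read.delim(f)$support, 1)
  f2 <- tempfile(fileext = ".tsv")
  exportConcordance(compareSites(list(mkGraph(c("a", "b"), c("a", "b"))),
                                 list(mkGraph(c("a", "b"), c("a", "b")))),
                    f2)
  expect_identical(read.delim(f2)$concordant, TRUE)
  f3 <- tempfile(fileext = ".json")
  exportMetrics(list(precision = 0.5), f3)
  expect_identical(jsonlite::read_json(f3)$precision, 0.5)
})
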