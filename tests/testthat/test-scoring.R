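test_that("risk set applies both exclusion predicates", {
  # 6-patient toy: p1 has v at w1; p2 unobserved before w1; p3 unobserved
  # after w2; p4-p6 eligible
  x1 <- cbind(v = c(1, 0, 0, 0, 0, 0), u = rep(0, 6))
  x2 <- cbind(v = c(1, 0, 1, 0, 1, 0), u = rep(0, 6))
  rownames(x1) <- rownames(x2) <- sprintf("p%d", 1:6)
  panel <- toyPanel(x1, x2, obs1 = c(TRUE, FALSE, rep(TRUE, 4)),
                    obs2 = c(TRUE, TRUE, FALSE, rep(TRUE, 3)))
  expect_identical(riskSet(panel, "v"), c("p4", "p5", "p6"))
  # everyone has the event -> empty; nobody has it, all observed -> full
  full <- toyPanel(x1 * 0 + 1, x2 * 0 + 1)
  expect_identical(riskSet(full, "v"), character())
  none <- toyPanel(x1 * 0, x2 * 0)
  expect_identical(riskSet(none, "v"), sprintf("p%d", 1:6))
  expect_error(riskSet(panel, "nope"), "unknown event")
})

test_that("intercept-only fit has the closed-form MLE and log-likelihood", {
  for (km in list(c(3L, 10L), c(7L, 19L), c(120L, 400L))) {
    k <- km[1]; m <- km[2]
    x1 <- matrix(0L, m, 1, dimnames = list(sprintf("p%d", 1:m), "v"))
    x2 <- x1; x2[seq_len(k), 1] <- 1L
    mod <- fitNodeModel(toyPanel(x1, x2), "v")
    expect_equal(unname(mod@coefficients["(Intercept)"]), qlogis(k / m),
                 tolerance = 1e-9)
    expect_equal(mod@logLik, k * log(k / m) + (m - k) * log(1 - k / m),
                 tolerance = 1e-9)
    expect_identical(mod@m, m)
    expect_true(mod@converged)
  }
})

test_that("single binary parent recovers the 2x2 log odds ratio", {
  # risk-set table: parent=1: 30 of 80 incident; parent=0: 10 of 120
  n <- 200
  par <- c(rep(1L, 80), rep(0L, 120))
  y <- c(rep(1L, 30), rep(0L, 50), rep(1L, 10), rep(0L, 110))
  x1 <- cbind(v = rep(0L, n), u = par)
  x2 <- cbind(v = y, u = par)
  rownames(x1) <- rownames(x2) <- sprintf("p%03d", 1:n)
  mod <- fitNodeModel(toyPanel(x1, x2), "v", parents = "u")
  lor <- log((30 / 50) / (10 / 110))
  expect_equal(unname(mod@coefficients["u"]), lor, tolerance = 1e-6)
  expect_equal(unname(mod@coefficients["(Intercept)"]), qlogis(10 / 120),
               tolerance = 1e-6)
})

test_that("patients positive at the first cross section are excluded", {
  x1 <- cbind(v = c(1L, 1L, 0L, 0L, 0L, 0L))
  x2 <- cbind(v = c(1L, 1L, 1L, 0L, 1L, 0L))
  rownames(x1) <- rownames(x2) <- sprintf("p%d", 1:6)
  mod <- fitNodeModel(toyPanel(x1, x2), "v")
  expect_identical(mod@m, 4L)  # only the x1 = 0 patients
  expect_equal(unname(mod@coefficients["(Intercept)"]), qlogis(0.5),
               tolerance = 1e-9)
})

test_that("constant outcome and separation trigger recorded fallbacks", {
  # constant outcome: nobody becomes incident
  x1 <- cbind(v = rep(0L, 20), u = rep(c(0L, 1L), 10))
  x2 <- x1
  rownames(x1) <- rownames(x2) <- sprintf("p%d", 1:20)
  mod <- fitNodeModel(toyPanel(x1, x2), "v", parents = "u")
  expect_identical(mod@method, "degenerate")
  expect_false(mod@converged)
  expect_identical(unname(mod@coefficients["u"]), 0)
  # perfect separation: incident iff parent present
  x2b <- cbind(v = x1[, "u"], u = x1[, "u"])
  modSep <- fitNodeModel(toyPanel(x1, x2b), "v", parents = "u")
  expect_identical(modSep@method, "ridge")
  expect_false(modSep@converged)
  expect_true(all(is.finite(modSep@coefficients)))
})

test_that("transition coefficients are recovered at scale", {
  beta <- log(3)
  nodes <- c("a", "b")
  m <- groundTruthModel(nodes, data.frame(parent = "a", child = "b"),
                        c(a = qlogis(0.3), b = qlogis(0.1)), NULL,
                        c(a = qlogis(0.05), b = qlogis(0.05)),
                        data.frame(parent = "a", child = "b", beta = beta))
  panel <- simulatePanel(m, 20000, seed = 42)
  mod <- fitNodeModel(panel, "b", parents = "a")
  # standard error from the observed information of the independent glm route
  rs <- riskSet(panel, "b")
  df <- data.frame(y = as.numeric(x2Matrix(panel)["b", rs]),
                   a = as.numeric(x1Matrix(panel)["a", rs]))
  se <- sqrt(diag(vcov(glm(y ~ a, binomial(), df))))[["a"]]
  expect_lt(abs(mod@coefficients[["a"]] - beta), 3 * se)
})

test_that("graph score matches the closed form and the glm oracle", {
  panel <- randomPanel(4, 300, seed = 21)
  nodes <- eventCodes(panel)
  g0 <- graphScore(panel, causalGraph(nodes))
  s0 <- graphScoreOf(g0)
  expect_identical(s0@nEdges, 0L)
  expect_equal(s0@bic, -2 * s0@logLik, tolerance = 1e-12)
  for (v in nodes)
    expect_equal(s0@nodeLogLik[[v]], oracleNodeLogLik(panel, v, character()),
                 tolerance = 1e-7)
  # single-edge graph: BIC = -2 * (hand-assembled node terms) + log(n)
  e <- data.frame(parent = nodes[1], child = nodes[2])
  g1 <- graphScore(panel, causalGraph(nodes, e))
  s1 <- graphScoreOf(g1)
  expect_equal(s1@bic, oracleBIC(panel, e), tolerance = 1e-6)
  # adding an edge never decreases the child's fitted log-likelihood
  expect_gte(s1@nodeLogLik[[nodes[2]]] + 1e-9, s0@nodeLogLik[[nodes[2]]])
  # decomposability: only the child term changed
  others <- setdiff(nodes, nodes[2])
  expect_equal(s1@nodeLogLik[others], s0@nodeLogLik[others],
               tolerance = 1e-12)
})

test_that("scores are invariant to node and patient ordering and caching", {
  panel <- randomPanel(4, 250, seed = 31)
  nodes <- eventCodes(panel)
  e <- data.frame(parent = nodes[c(1, 3)], child = nodes[c(2, 4)])
  cache <- new.env(parent = emptyenv())
  cold <- graphScoreOf(graphScore(panel, causalGraph(nodes, e),
                                  cache = cache))
  warm <- graphScoreOf(graphScore(panel, causalGraph(nodes, e),
                                  cache = cache))
  expect_identical(cold@bic, warm@bic)
  expect_identical(cold@nodeLogLik, warm@nodeLogLik)
  # permute patients and nodes
  pPerm <- sample(patientIds(panel))
  panel2 <- panel[rev(nodes), pPerm]
  perm <- graphScoreOf(graphScore(panel2, causalGraph(rev(nodes), e)))
  expect_equal(perm@bic, cold@bic, tolerance = 1e-9)
  expect_equal(perm@nodeLogLik[nodes], cold@nodeLogLik[nodes],
               tolerance = 1e-9)
})

test_that("nodes with empty risk sets contribute zero and reject parents", {
  x1 <- cbind(v = rep(1L, 8), u = rep(0L, 8))
  x2 <- cbind(v = rep(1L, 8), u = rep(c(0L, 1L), 4))
  rownames(x1) <- rownames(x2) <- sprintf("p%d", 1:8)
  panel <- toyPanel(x1, x2)
  s <- graphScoreOf(graphScore(panel, causalGraph(c("v", "u"))))
  expect_identical(s@nodeLogLik[["v"]], 0)
  expect_error(
    graphScore(panel, causalGraph(c("v", "u"),
                                  data.frame(parent = "u", child = "v"))),
    "empty risk set")
})

test_that("score report exports audit JSON", {
  panel <- randomPanel(3, 100, seed = 4)
  g <- graphScore(panel, causalGraph(eventCodes(panel)))
  f <- tempfile(fileext = ".json")
  exportScoreReport(g, f)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$bic, graphScoreOf(g)@bic, tolerance = 1e-9)
  expect_identical(rep$n_edges, 0L)
})
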