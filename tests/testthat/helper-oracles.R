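# Independent oracles and small fixtures shared across the suite.

# brute-force upper-tail sum of Binomial(m, 1/2): P(X >= k)
oracleBinomTail <- function(k, m) {
  if (k > m) return(0)
  sum(choose(m, seq.int(k, m)) * 0.5^m)
}

# two-sided exact discordant-pair p-value, majority direction
oracleMcNemarP <- function(nf, nr) {
  m <- nf + nr
  min(1, 2 * oracleBinomTail(max(nf, nr), m))
}

# node log-likelihood via stats::glm on a data.frame -- an assembly of the
# likelihood independent of the package's glm.fit/closed-form path
oracleNodeLogLik <- function(panel, v, parents) {
  rs <- riskSet(panel, v)
  df <- data.frame(y = as.numeric(x2Matrix(panel)[v, rs]))
  for (p in parents) df[[p]] <- as.numeric(x1Matrix(panel)[p, rs])
  f <- if (length(parents))
    stats::as.formula(paste("y ~", paste(sprintf("`%s`", parents),
                                         collapse = "+")))
  else y ~ 1
  fit <- stats::glm(f, binomial(), df,
                    control = glm.control(epsilon = 1e-10, maxit = 200))
  as.numeric(stats::logLik(fit))
}

# BIC of an edge set via the glm oracle
oracleBIC <- function(panel, edges) {
  n <- sum(observedBoth(panel))
  ll <- 0
  for (v in eventCodes(panel)) {
    if (!length(riskSet(panel, v))) next
    pa <- as.character(edges$parent[edges$child == v])
    ll <- ll + oracleNodeLogLik(panel, v, pa)
  }
  -2 * ll + log(n) * nrow(edges)
}

# exhaustive minimum-BIC subset of candidate edges (acyclic subsets only)
oracleExhaustiveSearch <- function(panel, cand) {
  nodes <- eventCodes(panel)
  best <- NULL
  bestBic <- Inf
  nc <- nrow(cand)
  for (mask in 0:(2^nc - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(nc) - 1L)))
    edges <- cand[sel, , drop = FALSE]
    ig <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                        vertices = nodes)
    if (!igraph::is_dag(ig)) next
    bic <- oracleBIC(panel, edges)
    if (bic < bestBic - 1e-9) {
      bestBic <- bic
      best <- edges
    }
  }
  list(edges = best, bic = bestBic)
}

# pairwise-comparison structural Hamming distance
oracleSHD <- function(ehat, etrue, nodes) {
  shd <- 0L
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    a <- nodes[i]; b <- nodes[j]
    hab <- any(ehat$parent == a & ehat$child == b)
    hba <- any(ehat$parent == b & ehat$child == a)
    tab <- any(etrue$parent == a & etrue$child == b)
    tba <- any(etrue$parent == b & etrue$child == a)
    hAdj <- hab || hba
    tAdj <- tab || tba
    if (hAdj != tAdj) shd <- shd + 1L
    else if (hAdj && tAdj && (hab != tab)) shd <- shd + 1L
  }
  shd
}

# hand-specified panel: statuses given as patient x event matrices
toyPanel <- function(x1, x2, obs1 = NULL, obs2 = NULL) {
  if (is.null(obs1)) obs1 <- rep(TRUE, nrow(x1))
  if (is.null(obs2)) obs2 <- rep(TRUE, nrow(x1))
  EventPanel(t(x1), t(x2), observedBeforeW1 = obs1, observedAfterW2 = obs2)
}

mcWindows <- function() {
  studyWindows("2003-01-01", "2004-12-31", "2006-01-01", "2007-12-31")
}

# random small panel for property checks
randomPanel <- function(nNodes, n, seed, beta = log(3)) {
  simulatePanel(randomGroundTruth(nNodes = nNodes, beta = beta, seed = seed),
                n, seed = seed + 1000L)
}
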