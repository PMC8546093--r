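#' Precedence-constrained greedy DAG search
#'
#' Constructs a causal graph by forward greedy search: starting from the
#' empty graph, each iteration evaluates the BIC change of adding every
#' ordered pair from the precedence constraint set that is not yet an edge,
#' keeps the graph acyclic, and whose child has a non-empty risk set; the
#' edge with the largest BIC decrease is added (ties broken
#' lexicographically by child then parent, for determinism). The search
#' stops when no candidate strictly decreases the BIC. Because candidate
#' edges come only from the constraint set, every returned edge carries its
#' precedence orientation — the mechanism that eliminates ambiguously
#' oriented edges.
#'
#' Since the BIC is decomposable, adding edge (p, c) changes only the child
#' term: `deltaBIC = -2 * (logLik(c | parents + p) - logLik(c | parents)) +
#' log(n)`. Node fits are memoised by (node, parent set).
#'
#' @param panel An [EventPanel-class].
#' @param constraints A [PrecedenceSet-class] over the panel's events (an
#'   empty set yields the empty graph). A cyclic constraint set is tolerated:
#'   acyclicity is enforced at each addition.
#' @param prune Also run a greedy backward sweep after the forward phase,
#'   deleting single edges while deletion lowers the BIC (off by default:
#'   the canonical procedure is forward-only).
#' @return A scored [CausalGraph-class]; `graphSteps()` holds the accepted
#'   additions with their BIC deltas.
#' @export
greedySearch <- function(panel, constraints, prune = FALSE) {
  stopifnot(is(panel, "EventPanel"), is(constraints, "PrecedenceSet"))
  nodes <- eventCodes(panel)
  cand <- precedencePairs(constraints)[, c("earlier", "later")]
  names(cand) <- c("parent", "child")
  if (nrow(cand) && !all(c(cand$parent, cand$child) %in% nodes))
    stop("constraint events missing from the panel", call. = FALSE)
  # deterministic candidate order: lexicographic by (child, parent)
  cand <- cand[order(cand$child, cand$parent), , drop = FALSE]

  n <- sum(observedBoth(panel))
  logn <- log(n)
  cache <- new.env(parent = emptyenv())

  riskEmpty <- stats::setNames(
    vapply(nodes, function(v) length(riskSet(panel, v)) == 0L, logical(1)),
    nodes)

  curLL <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in nodes)
    if (!riskEmpty[v]) curLL[v] <- .nodeTerm(panel, v, character(), cache)@logLik

  parents <- stats::setNames(vector("list", length(nodes)), nodes)
  edges <- data.frame(parent = character(), child = character())
  bic <- -2 * sum(curLL)
  steps <- list()

  if (nrow(cand)) repeat {
    inG <- .edgeKey(cand$parent, cand$child) %in%
      .edgeKey(edges$parent, edges$child)
    best <- NULL
    bestDelta <- 0
    adj <- .adjList(edges)
    for (r in which(!inG)) {
      p <- cand$parent[r]; cc <- cand$child[r]
      if (riskEmpty[cc]) next
      if (.reachable(adj, cc, p)) next  # would create a cycle
      newLL <- .nodeTerm(panel, cc, c(parents[[cc]], p), cache)@logLik
      delta <- -2 * (newLL - curLL[cc]) + logn
      if (delta < bestDelta - 1e-12) {
        bestDelta <- delta
        best <- list(parent = p, child = cc, ll = newLL)
      }
    }
    if (is.null(best)) break
    parents[[best$child]] <- c(parents[[best$child]], best$parent)
    curLL[best$child] <- best$ll
    edges <- rbind(edges,
                   data.frame(parent = best$parent, child = best$child))
    bic <- bic + bestDelta
    steps[[length(steps) + 1L]] <-
      data.frame(parent = best$parent, child = best$child,
                 delta_bic = bestDelta, bic = bic)
  }

  if (prune && nrow(edges)) repeat {
    best <- NULL
    bestDelta <- 0
    for (r in seq_len(nrow(edges))) {
      cc <- edges$child[r]
      newLL <- .nodeTerm(panel, cc,
                         setdiff(parents[[cc]], edges$parent[r]),
                         cache)@logLik
      delta <- -2 * (newLL - curLL[cc]) - logn
      if (delta < bestDelta - 1e-12) {
        bestDelta <- delta
        best <- list(row = r, child = cc, ll = newLL, delta = delta)
      }
    }
    if (is.null(best)) break
    cc <- best$child
    parents[[cc]] <- setdiff(parents[[cc]], edges$parent[best$row])
    curLL[cc] <- best$ll
    bic <- bic + best$delta
    edges <- edges[-best$row, , drop = FALSE]
    if (!nrow(edges)) break
  }

  rownames(edges) <- NULL
  g <- causalGraph(nodes, edges)
  g <- graphScore(panel, g, cache = cache)
  g@steps <- if (length(steps)) do.call(rbind, steps) else g@steps
  g
}

#' Full discovery pipeline on a panel
#'
#' Convenience wrapper: [computePrecedence()] followed by [greedySearch()].
#'
#' @inheritParams computePrecedence
#' @inheritParams greedySearch
#' @return A scored [CausalGraph-class].
#' @export
discoverGraph <- function(panel, alpha = 0.05, minDiscordant = 0L,
                          prune = FALSE) {
  greedySearch(panel, computePrecedence(panel, alpha, minDiscordant),
               prune = prune)
}

#' Bootstrap replication of the discovery pipeline
#'
#' Resamples patients with replacement, recomputes the precedence constraint
#' set on each replica (so reported stability reflects the variability of
#' the whole method, not only of the search), reruns the greedy search, and
#' returns the replica graphs. Events that vanish from a replica (no patient
#' has the event by window 2) are dropped from that replica's vocabulary
#' with a message. Deterministic given `seed`; per-replica substream seeds
#' are recorded in the `replica_seeds` attribute.
#'
#' @param panel An [EventPanel-class] for the cohort (inclusion criteria
#'   already applied; panel construction is per-patient, so resampling panel
#'   columns is equivalent to resampling the cohort and rebuilding).
#' @param B Number of bootstrap replicas.
#' @param seed Integer seed.
#' @param alpha,minDiscordant Passed to [computePrecedence()].
#' @param prune Passed to [greedySearch()].
#' @param resample Diagnostic flag; `FALSE` runs each replica on the
#'   original panel (so `B = 1` reproduces a direct [discoverGraph()] run).
#' @return List of `B` [CausalGraph-class] objects with attribute
#'   `replica_seeds`.
#' @export
bootstrapGraphs <- function(panel, B, seed, alpha = 0.05,
                            minDiscordant = 0L, prune = FALSE,
                            resample = TRUE) {
  stopifnot(is(panel, "EventPanel"), B >= 1L)
  set.seed(as.integer(seed))
  replicaSeeds <- sample.int(.Machine$integer.max - 1L, B)
  graphs <- vector("list", B)
  for (b in seq_len(B)) {
    set.seed(replicaSeeds[b])
    idx <- if (resample) sample.int(ncol(panel), replace = TRUE)
           else seq_len(ncol(panel))
    sub <- panel[, idx]
    colnames(sub) <- make.unique(colnames(sub))
    gone <- rowSums(x2Matrix(sub)) == 0L
    if (any(gone)) {
      message(sprintf("replica %d: dropping %d vanished event(s): %s", b,
                      sum(gone),
                      paste(rownames(sub)[gone], collapse = ", ")))
      sub <- sub[!gone, ]
    }
    graphs[[b]] <- greedySearch(
      sub, computePrecedence(sub, alpha, minDiscordant), prune = prune)
  }
  attr(graphs, "replica_seeds") <- replicaSeeds
  graphs
}
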