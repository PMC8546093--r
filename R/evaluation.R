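#' Construct an evidence base
#'
#' @param associative `data.frame(node_a, node_b)` of unordered associative
#'   pairs (evidence vocabulary).
#' @param causalPositive `data.frame(from, to)` of ordered pairs with trial
#'   evidence of causation.
#' @param causalNegative `data.frame(from, to, context)` of ordered pairs
#'   with trial evidence of no causation; `context = ""` for unconditional
#'   negatives, otherwise the evidence name X of "in patients with X, `from`
#'   does not cause `to`".
#' @param aliases `data.frame(evidence_name, event_code)` mapping evidence
#'   names onto panel event codes (one row per mapping; a name may map to
#'   several codes). An empty table means evidence names are event codes.
#' @return An [EvidenceBase-class].
#' @export
evidenceBase <- function(associative = data.frame(node_a = character(),
                                                  node_b = character()),
                         causalPositive = data.frame(from = character(),
                                                     to = character()),
                         causalNegative = data.frame(from = character(),
                                                     to = character(),
                                                     context = character()),
                         aliases = data.frame(evidence_name = character(),
                                              event_code = character())) {
  chr <- function(d) {
    d <- as.data.frame(d)
    d[] <- lapply(d, as.character)
    d
  }
  causalNegative <- chr(causalNegative)
  if (!"context" %in% names(causalNegative)) causalNegative$context <- ""
  causalNegative$context[is.na(causalNegative$context)] <- ""
  new("EvidenceBase", associative = chr(associative),
      causalPositive = chr(causalPositive),
      causalNegative = causalNegative, aliases = chr(aliases))
}

#' Read an evidence file and alias table
#'
#' The evidence file is delimited text with header
#' `type,node_a,node_b,context`, where `type` is one of `assoc`,
#' `causal_pos`, `causal_neg`; `context` is blank except for
#' context-tagged causal negatives. The alias file has header
#' `evidence_name,event_code`.
#'
#' @param file Evidence file path.
#' @param aliasFile Optional alias file path.
#' @param sep Field separator.
#' @return An [EvidenceBase-class].
#' @export
readEvidence <- function(file, aliasFile = NULL, sep = ",") {
  ev <- utils::read.table(file, header = TRUE, sep = sep,
                          colClasses = "character", fill = TRUE)
  need <- c("type", "node_a", "node_b")
  if (!all(need %in% names(ev)))
    stop("evidence file needs columns type, node_a, node_b[, context]",
         call. = FALSE)
  if (!"context" %in% names(ev)) ev$context <- ""
  ev$context[is.na(ev$context)] <- ""
  bad <- setdiff(unique(ev$type), c("assoc", "causal_pos", "causal_neg"))
  if (length(bad))
    stop(sprintf("unknown evidence type(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  al <- if (is.null(aliasFile))
    data.frame(evidence_name = character(), event_code = character())
  else utils::read.table(aliasFile, header = TRUE, sep = sep,
                         colClasses = "character")
  a <- ev[ev$type == "assoc", c("node_a", "node_b")]
  cp <- ev[ev$type == "causal_pos", c("node_a", "node_b")]
  names(cp) <- c("from", "to")
  cn <- ev[ev$type == "causal_neg", c("node_a", "node_b", "context")]
  names(cn) <- c("from", "to", "context")
  evidenceBase(a, cp, cn, al)
}

# evidence name -> event codes; the name itself is always included so that
# evidence phrased directly in event codes needs no alias row
.aliasCodes <- function(evidence, name) {
  al <- evidence@aliases
  unique(c(al$event_code[al$evidence_name == name], name))
}

# event code -> evidence names citing it (identity always included)
.namesForCode <- function(evidence, code) {
  al <- evidence@aliases
  unique(c(al$evidence_name[al$event_code == code], code))
}

.unorderedKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Evidence-based precision of a discovered graph
#'
#' An edge is *incorrect* when there is no associative evidence of a
#' relationship between its two events, or when causal evidence specifically
#' indicates the lack of a causal relationship in that orientation
#' (context-free negatives are applied unconditionally; context-tagged
#' negatives only veto paths, see [causalRecall()]). Precision is one minus
#' the proportion of incorrect edges among the discovered edges.
#'
#' @param graph A non-empty [CausalGraph-class].
#' @param evidence An [EvidenceBase-class].
#' @return Precision in \[0, 1\]; `NA` for an empty graph.
#' @export
evidencePrecision <- function(graph, evidence) {
  stopifnot(is(graph, "CausalGraph"), is(evidence, "EvidenceBase"))
  e <- graphEdges(graph)
  if (!nrow(e)) return(NA_real_)
  assocKeys <- .unorderedKey(evidence@associative$node_a,
                             evidence@associative$node_b)
  negUncond <- evidence@causalNegative[evidence@causalNegative$context == "", ,
                                       drop = FALSE]
  negKeys <- paste(negUncond$from, negUncond$to, sep = "\r")
  incorrect <- vapply(seq_len(nrow(e)), function(r) {
    pNames <- .namesForCode(evidence, e$parent[r])
    cNames <- .namesForCode(evidence, e$child[r])
    combos <- expand.grid(p = pNames, c = cNames,
                          stringsAsFactors = FALSE)
    associated <- any(.unorderedKey(combos$p, combos$c) %in% assocKeys)
    negated <- any(paste(combos$p, combos$c, sep = "\r") %in% negKeys)
    !associated || negated
  }, logical(1))
  1 - mean(incorrect)
}

# reachability from any of `fromCodes` to any of `toCodes` along directed
# paths of length <= maxLen whose intermediate nodes avoid `vetoCodes`
.pathSatisfied <- function(graph, fromCodes, toCodes, vetoCodes,
                           maxPathLen = Inf) {
  e <- graphEdges(graph)
  direct <- any(e$parent %in% fromCodes & e$child %in% toCodes)
  if (direct) return(TRUE)
  if (maxPathLen < 2) return(FALSE)
  ig <- asIgraph(graph)
  for (a in intersect(fromCodes, graphNodes(graph))) {
    for (b in intersect(toCodes, graphNodes(graph))) {
      drop <- setdiff(intersect(vetoCodes, graphNodes(graph)), c(a, b))
      g2 <- igraph::delete_vertices(ig, drop)
      d <- igraph::distances(g2, v = a, to = b, mode = "out")[1L, 1L]
      if (is.finite(d) && d <= maxPathLen) return(TRUE)
    }
  }
  FALSE
}

#' Causal recall of a discovered graph
#'
#' A known causal relationship from A to B counts as discovered when the
#' graph has a node mapping to A, a node mapping to B, and either a direct
#' edge A to B, or a directed path from A to B whose every intermediate node
#' X is not cited by a context-tagged negative "in patients with X, A does
#' not cause B". Evidence names are mapped to event codes through the alias
#' table (so evidence about "blood pressure" can be satisfied through either
#' the systolic or diastolic node, e.g. by a path sbp to cevd to stroke).
#' Relationships whose endpoints map to no graph node are logged and counted
#' as not discovered (the denominator is unchanged).
#'
#' @param graph A [CausalGraph-class].
#' @param evidence An [EvidenceBase-class] with non-empty `causalPositive`.
#' @param maxPathLen Maximum admissible path length in edges (default
#'   unlimited; `1` restricts to direct edges).
#' @return Recall in \[0, 1\].
#' @export
causalRecall <- function(graph, evidence, maxPathLen = Inf) {
  stopifnot(is(graph, "CausalGraph"), is(evidence, "EvidenceBase"))
  pos <- evidence@causalPositive
  if (!nrow(pos)) stop("no causal-positive evidence", call. = FALSE)
  neg <- evidence@causalNegative
  nodes <- graphNodes(graph)
  hit <- vapply(seq_len(nrow(pos)), function(r) {
    fromCodes <- intersect(.aliasCodes(evidence, pos$from[r]), nodes)
    toCodes <- intersect(.aliasCodes(evidence, pos$to[r]), nodes)
    if (!length(fromCodes) || !length(toCodes)) {
      message(sprintf("causal evidence %s -> %s maps to no graph node; skipped",
                      pos$from[r], pos$to[r]))
      return(FALSE)
    }
    ctx <- neg$context[neg$from == pos$from[r] & neg$to == pos$to[r] &
                         neg$context != ""]
    vetoCodes <- unique(unlist(lapply(ctx, .aliasCodes,
                                      evidence = evidence)))
    if (is.null(vetoCodes)) vetoCodes <- character()
    .pathSatisfied(graph, fromCodes, toCodes, vetoCodes, maxPathLen)
  }, logical(1))
  mean(hit)
}

#' Associative recall of a discovered graph
#'
#' A known associative relationship between A and B is explained when nodes
#' mapping to A and B are connected by a path in the orientation-blind
#' skeleton of the graph.
#'
#' @param graph A [CausalGraph-class].
#' @param evidence An [EvidenceBase-class] with non-empty `associative`.
#' @return Recall in \[0, 1\].
#' @export
associativeRecall <- function(graph, evidence) {
  stopifnot(is(graph, "CausalGraph"), is(evidence, "EvidenceBase"))
  assoc <- evidence@associative
  if (!nrow(assoc)) stop("no associative evidence", call. = FALSE)
  nodes <- graphNodes(graph)
  ig <- igraph::as_undirected(asIgraph(graph))
  comp <- igraph::components(ig)$membership
  hit <- vapply(seq_len(nrow(assoc)), function(r) {
    aCodes <- intersect(.aliasCodes(evidence, assoc$node_a[r]), nodes)
    bCodes <- intersect(.aliasCodes(evidence, assoc$node_b[r]), nodes)
    if (!length(aCodes) || !length(bCodes)) {
      message(sprintf("associative evidence %s -- %s maps to no graph node; skipped",
                      assoc$node_a[r], assoc$node_b[r]))
      return(FALSE)
    }
    any(outer(comp[aCodes], comp[bCodes], `==`))
  }, logical(1))
  mean(hit)
}

#' Bootstrap orientation stability
#'
#' Summarises the edges of a list of bootstrap graphs orientation-blind: an
#' adjacency is reported when present (in either orientation) in at least
#' `supportThreshold` of the graphs, and flagged *ambiguous* when both
#' orientations each appear in at least `orientationThreshold` of the graphs
#' containing the adjacency.
#'
#' @param graphs List of [CausalGraph-class] (at least 2).
#' @param supportThreshold Minimum support fraction for an adjacency to be
#'   reported (default 0.5).
#' @param orientationThreshold Minimum fraction of each orientation for the
#'   ambiguity flag (default 0.3).
#' @return A [StabilityReport-class].
#' @export
orientationStability <- function(graphs, supportThreshold = 0.5,
                                 orientationThreshold = 0.3) {
  stopifnot(length(graphs) >= 2L,
            all(vapply(graphs, is, logical(1), "CausalGraph")))
  B <- length(graphs)
  tallies <- new.env(parent = emptyenv())
  for (g in graphs) {
    e <- graphEdges(g)
    if (!nrow(e)) next
    a <- pmin(e$parent, e$child)
    b <- pmax(e$parent, e$child)
    fwd <- e$parent == a
    for (r in seq_len(nrow(e))) {
      key <- paste(a[r], b[r], sep = "\r")
      cur <- tallies[[key]]
      if (is.null(cur)) cur <- c(fwd = 0L, rev = 0L)
      if (fwd[r]) cur["fwd"] <- cur["fwd"] + 1L else cur["rev"] <- cur["rev"] + 1L
      tallies[[key]] <- cur
    }
  }
  keys <- ls(tallies)
  rows <- lapply(keys, function(key) {
    cur <- tallies[[key]]
    nm <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    nSupp <- sum(cur)
    data.frame(node_a = nm[1L], node_b = nm[2L],
               support = nSupp / B,
               forward_frac = cur[["fwd"]] / nSupp,
               reverse_frac = cur[["rev"]] / nSupp)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node_a = character(), node_b = character(),
               support = numeric(), forward_frac = numeric(),
               reverse_frac = numeric())
  tab <- tab[tab$support >= supportThreshold, , drop = FALSE]
  tab$ambiguous <- tab$forward_frac >= orientationThreshold &
    tab$reverse_frac >= orientationThreshold
  tab <- tab[order(-tab$support, tab$node_a, tab$node_b), , drop = FALSE]
  rownames(tab) <- NULL
  new("StabilityReport", table = tab,
      ambiguousPct = if (nrow(tab)) 100 * mean(tab$ambiguous) else NA_real_,
      nGraphs = as.integer(B), supportThreshold = supportThreshold,
      orientationThreshold = orientationThreshold)
}

.edgeSupport <- function(graphs) {
  counts <- new.env(parent = emptyenv())
  for (g in graphs) {
    e <- graphEdges(g)
    for (key in .edgeKey(e$parent, e$child)) {
      cur <- counts[[key]]
      counts[[key]] <- if (is.null(cur)) 1L else cur + 1L
    }
  }
  keys <- ls(counts)
  stats::setNames(vapply(keys, function(k) counts[[k]], integer(1)) /
                    length(graphs), keys)
}

#' Cross-cohort edge concordance
#'
#' Pools the bootstrap graphs of two cohorts into per-site directed edge
#' sets (edges with support at or above `supportThreshold`), and compares
#' them: the output lists every edge in the union with its support
#' percentage at each site and a concordance flag. Summary counts (union
#' size, coinciding and differing edges, concordance percentage) are
#' attached as attributes.
#'
#' @param graphsA,graphsB Non-empty lists of [CausalGraph-class] from the
#'   two cohorts.
#' @param supportThreshold Pooling cutoff on the support fraction (default
#'   0.5, matching the stability inclusion rule).
#' @return `data.frame(parent, child, support_a_pct, support_b_pct, in_a,
#'   in_b, concordant)` sorted with discordant edges first, with attributes
#'   `n_union`, `n_concordant`, `n_discordant`, `concordance_pct`.
#' @export
compareSites <- function(graphsA, graphsB, supportThreshold = 0.5) {
  stopifnot(length(graphsA) >= 1L, length(graphsB) >= 1L)
  vocabA <- unique(unlist(lapply(graphsA, graphNodes)))
  vocabB <- unique(unlist(lapply(graphsB, graphNodes)))
  unshared <- c(setdiff(vocabA, vocabB), setdiff(vocabB, vocabA))
  if (length(unshared))
    message(sprintf("events not shared between sites: %s",
                    paste(unshared, collapse = ", ")))
  sa <- .edgeSupport(graphsA)
  sb <- .edgeSupport(graphsB)
  pooledA <- names(sa)[sa >= supportThreshold]
  pooledB <- names(sb)[sb >= supportThreshold]
  union <- sort(unique(c(pooledA, pooledB)))
  pc <- do.call(rbind, strsplit(union, "\r", fixed = TRUE))
  tab <- data.frame(
    parent = if (length(union)) pc[, 1L] else character(),
    child = if (length(union)) pc[, 2L] else character(),
    support_a_pct = 100 * unname(ifelse(is.na(sa[union]), 0, sa[union])),
    support_b_pct = 100 * unname(ifelse(is.na(sb[union]), 0, sb[union])),
    in_a = union %in% pooledA,
    in_b = union %in% pooledB)
  tab$concordant <- tab$in_a & tab$in_b
  tab <- tab[order(tab$concordant, tab$parent, tab$child), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_union") <- nrow(tab)
  attr(tab, "n_concordant") <- sum(tab$concordant)
  attr(tab, "n_discordant") <- sum(!tab$concordant)
  attr(tab, "concordance_pct") <-
    if (nrow(tab)) 100 * mean(tab$concordant) else NA_real_
  tab
}

#' Export evaluation artefacts
#'
#' `exportStability()` writes the stability table as TSV;
#' `exportConcordance()` writes the [compareSites()] table as TSV (edge,
#' per-site discovery percentages, concordance flag); `exportMetrics()`
#' writes a JSON object of named metric values.
#'
#' @param report A [StabilityReport-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
exportStability <- function(report, file) {
  utils::write.table(stabilityTable(report), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname exportStability
#' @param concordance Output of [compareSites()].
#' @export
exportConcordance <- function(concordance, file) {
  utils::write.table(concordance, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname exportStability
#' @param metrics Named list of metric values.
#' @export
exportMetrics <- function(metrics, file) {
  jsonlite::write_json(metrics, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
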