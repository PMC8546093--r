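expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

# adjacency-list DFS reachability: is `to` reachable from `from`?
.reachable <- function(adj, from, to) {
  if (from == to) return(TRUE)
  seen <- character()
  stack <- from
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    nxt <- adj[[cur]]
    if (is.null(nxt)) next
    if (to %in% nxt) return(TRUE)
    new <- setdiff(nxt, seen)
    seen <- c(seen, new)
    stack <- c(stack, new)
  }
  FALSE
}

.adjList <- function(edges) {
  if (!nrow(edges)) return(list())
  split(as.character(edges$child), factor(edges$parent))
}

.hasCycle <- function(nodes, edges) {
  # Kahn's algorithm; TRUE when a directed cycle exists
  if (!nrow(edges)) return(FALSE)
  indeg <- table(factor(edges$child, levels = nodes))
  adj <- .adjList(edges)
  queue <- nodes[indeg == 0L]
  removed <- 0L
  indeg <- as.list(indeg)
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    removed <- removed + 1L
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  removed < length(nodes)
}

.edgeKey <- function(parent, child) paste(parent, child, sep = "\r")

#' Convert a causal graph to an igraph object
#'
#' @param graph A [CausalGraph-class].
#' @return An [igraph::igraph] directed graph over the same nodes.
#' @export
asIgraph <- function(graph) {
  igraph::graph_from_data_frame(graphEdges(graph), directed = TRUE,
                                vertices = graphNodes(graph))
}

.assertScalarProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stop(sprintf("'%s' must be a scalar in (0,1)", name), call. = FALSE)
}
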