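#' Accessors for EventPanel objects
#'
#' `x1Matrix()` and `x2Matrix()` return the binary status matrices (events in
#' rows, patients in columns) at the first and second cross section;
#' `incidentMatrix()` returns `x2 & !x1` (events newly present in window 2);
#' `eventCodes()` and `patientIds()` return the dimnames; `observedBoth()`
#' returns the logical vector of patients observed at both cross sections —
#' the BIC sample.
#'
#' @param x An [EventPanel-class].
#' @return A matrix, character vector or logical vector as described.
#' @name x1Matrix
#' @aliases x2Matrix incidentMatrix eventCodes patientIds observedBoth
NULL

#' @rdname x1Matrix
#' @export
setMethod("x1Matrix", "EventPanel", function(x)
  SummarizedExperiment::assay(x, "x1"))

#' @rdname x1Matrix
#' @export
setMethod("x2Matrix", "EventPanel", function(x)
  SummarizedExperiment::assay(x, "x2"))

#' @rdname x1Matrix
#' @export
setMethod("incidentMatrix", "EventPanel", function(x) {
  m <- SummarizedExperiment::assay(x, "x2") -
    SummarizedExperiment::assay(x, "x1")
  storage.mode(m) <- "integer"
  m
})

#' @rdname x1Matrix
#' @export
setMethod("eventCodes", "EventPanel", function(x) rownames(x))

#' @rdname x1Matrix
#' @export
setMethod("patientIds", "EventPanel", function(x) colnames(x))

#' @rdname x1Matrix
#' @export
setMethod("observedBoth", "EventPanel", function(x) {
  cd <- SummarizedExperiment::colData(x)
  as.logical(cd$observed_before_w1 & cd$observed_after_w2)
})

setMethod("show", "EventPanel", function(object) {
  x1 <- x1Matrix(object)
  inc <- incidentMatrix(object)
  cat(sprintf("EventPanel: %d events x %d patients\n",
              nrow(object), ncol(object)))
  cat(sprintf("  pre-existing cells: %d, incident cells: %d\n",
              sum(x1), sum(inc)))
  cat(sprintf("  patients observed at both cross sections: %d\n",
              sum(observedBoth(object))))
})

#' Accessors for CausalGraph objects
#'
#' `graphNodes()` and `graphEdges()` return the node vector and the
#' `parent`/`child` edge table; `numEdges()` the edge count;
#' `graphScoreOf()` the attached [ScoreComponents-class] (or `NULL`);
#' `graphSteps()` the greedy-search trace; `nodeModels()` the fitted
#' per-node transition models.
#'
#' @param x A [CausalGraph-class].
#' @return See the individual descriptions.
#' @name graphNodes
#' @aliases graphEdges numEdges graphScoreOf graphSteps nodeModels
NULL

#' @rdname graphNodes
#' @export
setMethod("graphNodes", "CausalGraph", function(x) x@nodes)

#' @rdname graphNodes
#' @export
setMethod("graphEdges", "CausalGraph", function(x) x@edges)

#' @rdname graphNodes
#' @export
setMethod("numEdges", "CausalGraph", function(x) nrow(x@edges))

#' @rdname graphNodes
#' @export
setMethod("graphScoreOf", "CausalGraph", function(x) x@score)

#' @rdname graphNodes
#' @export
setMethod("graphSteps", "CausalGraph", function(x) x@steps)

#' @rdname graphNodes
#' @export
setMethod("nodeModels", "CausalGraph", function(x) x@models)

setMethod("show", "CausalGraph", function(object) {
  cat(sprintf("CausalGraph: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
  if (!is.null(object@score))
    cat(sprintf("  BIC %.4f (logLik %.4f, n = %d)\n",
                object@score@bic, object@score@logLik, object@score@n))
  if (nrow(object@edges)) {
    shown <- utils::head(object@edges, 10L)
    cat(paste0("  ", shown$parent, " -> ", shown$child, collapse = "\n"),
        "\n")
    if (nrow(object@edges) > 10L)
      cat(sprintf("  ... and %d more\n", nrow(object@edges) - 10L))
  }
})

#' Extract the pair table of a PrecedenceSet
#'
#' @param x A [PrecedenceSet-class].
#' @return `data.frame` with columns `earlier`, `later`, `n_forward`,
#'   `n_reverse`, `p_value`, sorted by p-value.
#' @name precedencePairs
NULL

#' @rdname precedencePairs
#' @export
setMethod("precedencePairs", "PrecedenceSet", function(x) x@pairs)

#' @export
setMethod("length", "PrecedenceSet", function(x) nrow(x@pairs))

setMethod("show", "PrecedenceSet", function(object) {
  cat(sprintf("PrecedenceSet: %d ordered pairs over %d events (alpha = %g)\n",
              nrow(object@pairs), length(object@events), object@alpha))
  if (nrow(object@pairs)) print(utils::head(object@pairs, 5L))
})

setMethod("show", "NodeTransitionModel", function(object) {
  cat(sprintf("NodeTransitionModel for '%s' (%d parents, m = %d, %s)\n",
              object@node, length(object@parents), object@m, object@method))
  print(object@coefficients)
})

setMethod("show", "ScoreComponents", function(object) {
  cat(sprintf("ScoreComponents: BIC %.4f = -2 * %.4f + log(%d) * %d\n",
              object@bic, object@logLik, object@n, object@nEdges))
})

#' Accessors for StabilityReport objects
#'
#' `stabilityTable()` returns the per-adjacency table; `ambiguousPct()` the
#' percentage of reported adjacencies with ambiguous orientation.
#'
#' @param x A [StabilityReport-class].
#' @name stabilityTable
NULL

#' @rdname stabilityTable
#' @export
setMethod("stabilityTable", "StabilityReport", function(x) x@table)

#' @rdname stabilityTable
#' @export
setMethod("ambiguousPct", "StabilityReport", function(x) x@ambiguousPct)

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf(
    "StabilityReport over %d graphs: %d adjacencies at support >= %.2f\n",
    object@nGraphs, nrow(object@table), object@supportThreshold))
  cat(sprintf("  ambiguously oriented: %s%%\n",
              format(object@ambiguousPct)))
})

#' True edge set of a ground-truth model
#'
#' @param x A [GroundTruthModel-class].
#' @return `data.frame(parent, child)`.
#' @name trueEdges
NULL

#' @rdname trueEdges
#' @export
setMethod("trueEdges", "GroundTruthModel", function(x) x@edges)

setMethod("show", "GroundTruthModel", function(object) {
  cat(sprintf("GroundTruthModel: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
  cat(sprintf("  anchorProb %.2f, lagMeanDays %.1f, reversalProb %.2f\n",
              object@anchorProb, object@lagMeanDays, object@reversalProb))
})

setMethod("show", "EvidenceBase", function(object) {
  cat(sprintf(
    "EvidenceBase: %d associative, %d causal-positive, %d causal-negative\n",
    nrow(object@associative), nrow(object@causalPositive),
    nrow(object@causalNegative)))
  cat(sprintf("  %d alias mappings\n", nrow(object@aliases)))
})

setMethod("show", "StudyWindows", function(object) {
  cat(sprintf("StudyWindows: [%s, %s] and [%s, %s]\n",
              object@w1Start, object@w1End, object@w2Start, object@w2End))
})
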