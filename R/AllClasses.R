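#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
NULL

#' Two-window study design
#'
#' Holds the four calendar dates delimiting the two observation windows of a
#' two-cross-section study. Window 1 closes at `w1End` (the first cross
#' section); window 2 closes at `w2End` (the second cross section). A gap
#' between the windows is allowed.
#'
#' @slot w1Start,w1End,w2Start,w2End `Date` scalars with
#'   `w1Start < w1End <= w2Start < w2End`.
#' @export
setClass("StudyWindows",
         representation(w1Start = "Date", w1End = "Date",
                        w2Start = "Date", w2End = "Date"))

setValidity("StudyWindows", function(object) {
  d <- c(object@w1Start, object@w1End, object@w2Start, object@w2End)
  if (anyNA(d)) return("window dates must not be NA")
  if (!(object@w1Start < object@w1End)) return("w1Start must precede w1End")
  if (!(object@w1End <= object@w2Start)) return("w1End must not exceed w2Start")
  if (!(object@w2Start < object@w2End)) return("w2Start must precede w2End")
  TRUE
})

#' Construct a two-window study design
#'
#' @param w1Start,w1End,w2Start,w2End Calendar dates (`Date` or ISO-8601
#'   strings) satisfying `w1Start < w1End <= w2Start < w2End`.
#' @return A [StudyWindows-class] object.
#' @examples
#' studyWindows("2003-01-01", "2004-12-31", "2006-01-01", "2007-12-31")
#' @export
studyWindows <- function(w1Start, w1End, w2Start, w2End) {
  new("StudyWindows",
      w1Start = as.Date(w1Start), w1End = as.Date(w1End),
      w2Start = as.Date(w2Start), w2End = as.Date(w2End))
}

#' Two-cross-section event status panel
#'
#' An `EventPanel` stores, for every patient (column) and disease-related
#' event (row), the binary status at two cross sections: assay `"x1"` is 1
#' when the event is pre-existing (first record on or before the end of
#' window 1) and assay `"x2"` is 1 when the event is present by the end of
#' window 2. Pre-existing events persist, so `x1 <= x2` holds cell-wise; an
#' event is *incident* when `x2 = 1` and `x1 = 0`. Per-patient observation
#' flags (`observed_before_w1`, `observed_after_w2` in `colData`) record
#' whether the patient was under observation outside each window, which
#' defines the risk sets used by the transition models.
#'
#' @seealso [EventPanel()], [buildEventPanel()], [x1Matrix()],
#'   [incidentMatrix()], [riskSet()]
#' @export
setClass("EventPanel", contains = "SummarizedExperiment")

setValidity("EventPanel", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("x1", "x2") %in% an))
    return("assays 'x1' and 'x2' are required")
  x1 <- SummarizedExperiment::assay(object, "x1")
  x2 <- SummarizedExperiment::assay(object, "x2")
  if (!all(x1 %in% c(0L, 1L)) || !all(x2 %in% c(0L, 1L)))
    return("assay values must be binary 0/1")
  if (any(x1 > x2))
    return("persistence violated: x1 = 1 requires x2 = 1")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("observed_before_w1", "observed_after_w2") %in% colnames(cd)))
    return("colData must contain observed_before_w1 and observed_after_w2")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    return("event (row) and patient (column) names are required")
  TRUE
})

#' Construct an EventPanel from status matrices
#'
#' @param x1,x2 Binary integer matrices (events in rows, patients in columns,
#'   both with dimnames) of pre-existing and window-2 statuses; `x1 <= x2`
#'   must hold cell-wise.
#' @param observedBeforeW1,observedAfterW2 Logical vectors, one entry per
#'   patient, flagging observation before window 1 and after window 2.
#'   Default `TRUE` for all patients (a cohort passing the inclusion criteria
#'   is observed at both ends by construction).
#' @return An [EventPanel-class].
#' @examples
#' x1 <- matrix(c(1L, 0L, 0L, 0L), 2, 2,
#'              dimnames = list(c("htn", "dm"), c("p1", "p2")))
#' x2 <- matrix(c(1L, 1L, 0L, 0L), 2, 2, dimnames = dimnames(x1))
#' EventPanel(x1, x2)
#' @export
EventPanel <- function(x1, x2,
                       observedBeforeW1 = rep(TRUE, ncol(x1)),
                       observedAfterW2 = rep(TRUE, ncol(x1))) {
  storage.mode(x1) <- "integer"
  storage.mode(x2) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(x1 = x1, x2 = x2),
    colData = S4Vectors::DataFrame(
      observed_before_w1 = as.logical(observedBeforeW1),
      observed_after_w2 = as.logical(observedAfterW2),
      row.names = colnames(x1)))
  new("EventPanel", se)
}

#' Set of temporal precedence constraints
#'
#' The constraint set of ordered event pairs with statistically clear
#' temporal precedence, as established by one-sided exact binomial tests on
#' discordant pre-existing/incident counts. Only these ordered pairs are
#' admissible edges for the constrained graph search.
#'
#' @slot pairs A `data.frame` with columns `earlier`, `later`, `n_forward`,
#'   `n_reverse`, `p_value`, one row per admitted ordered pair, sorted by
#'   p-value.
#' @slot alpha Significance level used by the test.
#' @slot events Event vocabulary over which pairs were tested.
#' @seealso [computePrecedence()]
#' @export
setClass("PrecedenceSet",
         representation(pairs = "data.frame", alpha = "numeric",
                        events = "character"))

setValidity("PrecedenceSet", function(object) {
  p <- object@pairs
  need <- c("earlier", "later", "n_forward", "n_reverse", "p_value")
  if (!all(need %in% names(p)))
    return("pairs must have columns earlier, later, n_forward, n_reverse, p_value")
  if (nrow(p)) {
    if (any(p$n_forward < 0) || any(p$n_reverse < 0))
      return("discordant counts must be non-negative")
    if (any(p$p_value < 0 | p$p_value > 1)) return("p_value outside [0,1]")
    key <- apply(cbind(pmin(p$earlier, p$later), pmax(p$earlier, p$later)),
                 1L, paste, collapse = "\r")
    if (anyDuplicated(key))
      return("at most one orientation per unordered pair is allowed")
  }
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    return("alpha must be a scalar in (0,1)")
  TRUE
})

#' Per-node logistic transition model
#'
#' Logistic regression of a node's window-2 status on the window-1 statuses
#' of its parents, fitted over the node's risk set (patients without the
#' event at the first cross section and observed at both cross sections).
#'
#' @slot node Event code of the modelled node.
#' @slot parents Event codes of the regressor parents.
#' @slot coefficients Named numeric: `"(Intercept)"` followed by one
#'   log-odds coefficient per parent.
#' @slot logLik Maximised binomial log-likelihood over the risk set.
#' @slot m Risk-set size.
#' @slot converged Whether the plain IRLS fit converged without fallback.
#' @slot method `"mle"`, `"ridge"` (separation fallback) or `"degenerate"`
#'   (constant outcome).
#' @seealso [fitNodeModel()]
#' @export
setClass("NodeTransitionModel",
         representation(node = "character", parents = "character",
                        coefficients = "numeric", logLik = "numeric",
                        m = "integer", converged = "logical",
                        method = "character"))

#' Decomposed BIC score of a causal graph
#'
#' @slot nodeLogLik Named numeric, per-node transition log-likelihood.
#' @slot logLik Total log-likelihood (sum of node terms).
#' @slot n Number of patients observed at both cross sections (the BIC
#'   sample size).
#' @slot nEdges Number of edges in the scored graph.
#' @slot bic `-2 * logLik + log(n) * nEdges`.
#' @seealso [graphScore()]
#' @export
setClass("ScoreComponents",
         representation(nodeLogLik = "numeric", logLik = "numeric",
                        n = "integer", nEdges = "integer", bic = "numeric"))

setValidity("ScoreComponents", function(object) {
  if (abs(object@logLik - sum(object@nodeLogLik)) >
      1e-8 * max(1, abs(object@logLik)))
    return("logLik must equal the sum of node terms")
  expected <- -2 * object@logLik + log(object@n) * object@nEdges
  if (abs(object@bic - expected) > 1e-8 * max(1, abs(expected)))
    return("bic must equal -2*logLik + log(n)*nEdges")
  TRUE
})

#' Causal graph over disease-related events
#'
#' A directed acyclic graph whose nodes are event codes and whose edges point
#' from a pre-existing (parent) event to an incident (child) event. When
#' produced by [greedySearch()] every edge belongs to the precedence
#' constraint set with its constraint orientation, each node carries its
#' fitted [NodeTransitionModel-class], and `score` holds the decomposed BIC.
#'
#' @slot nodes Character vector of event codes.
#' @slot edges `data.frame` with columns `parent`, `child`.
#' @slot models Named list of [NodeTransitionModel-class] (possibly empty
#'   until fitted).
#' @slot score A [ScoreComponents-class], or `NULL` until scored.
#' @slot steps `data.frame` trace of accepted greedy steps (`parent`,
#'   `child`, `delta_bic`, `bic`), empty for hand-built graphs.
#' @seealso [causalGraph()], [greedySearch()], [graphScore()]
#' @export
setClass("CausalGraph",
         representation(nodes = "character", edges = "data.frame",
                        models = "list", score = "ANY", steps = "data.frame"))

setValidity("CausalGraph", function(object) {
  e <- object@edges
  if (!all(c("parent", "child") %in% names(e)))
    return("edges must have columns parent, child")
  if (nrow(e)) {
    if (!all(c(e$parent, e$child) %in% object@nodes))
      return("edge endpoints must be graph nodes")
    if (any(e$parent == e$child)) return("self-loops are not allowed")
    if (anyDuplicated(paste(e$parent, e$child, sep = "\r")))
      return("duplicate edges are not allowed")
    if (.hasCycle(object@nodes, e)) return("graph must be acyclic")
  }
  TRUE
})

#' Construct a causal graph
#'
#' @param nodes Character vector of event codes.
#' @param edges `data.frame` with columns `parent` and `child` (zero rows for
#'   an empty graph).
#' @return A [CausalGraph-class] with no fitted models.
#' @examples
#' causalGraph(c("a", "b"), data.frame(parent = "a", child = "b"))
#' @export
causalGraph <- function(nodes, edges = data.frame(parent = character(),
                                                  child = character())) {
  edges <- as.data.frame(edges)[, c("parent", "child")]
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  new("CausalGraph", nodes = as.character(nodes), edges = edges,
      models = list(), score = NULL,
      steps = data.frame(parent = character(), child = character(),
                         delta_bic = numeric(), bic = numeric()))
}

#' Curated evidence base for graph evaluation
#'
#' Holds clinical evidence against which a discovered graph is judged:
#' unordered associative pairs (observational evidence of a relationship),
#' ordered causal-positive pairs (trial evidence that the cause raises the
#' effect), and ordered causal-negative pairs, each optionally tagged with a
#' context event ("in patients with X, A does not cause B"). Evidence is
#' phrased in its own vocabulary; `aliases` maps each evidence name to one or
#' more panel event codes (e.g. "blood pressure" to both `sbp` and `dbp`).
#'
#' @slot associative `data.frame(node_a, node_b)`, unordered.
#' @slot causalPositive `data.frame(from, to)`, ordered.
#' @slot causalNegative `data.frame(from, to, context)`, ordered; `context`
#'   is `""` for an unconditional negative.
#' @slot aliases `data.frame(evidence_name, event_code)`, one row per
#'   mapping.
#' @seealso [evidenceBase()], [readEvidence()], [evidencePrecision()],
#'   [causalRecall()], [associativeRecall()]
#' @export
setClass("EvidenceBase",
         representation(associative = "data.frame",
                        causalPositive = "data.frame",
                        causalNegative = "data.frame",
                        aliases = "data.frame"))

setValidity("EvidenceBase", function(object) {
  if (!all(c("node_a", "node_b") %in% names(object@associative)))
    return("associative needs columns node_a, node_b")
  if (!all(c("from", "to") %in% names(object@causalPositive)))
    return("causalPositive needs columns from, to")
  if (!all(c("from", "to", "context") %in% names(object@causalNegative)))
    return("causalNegative needs columns from, to, context")
  if (!all(c("evidence_name", "event_code") %in% names(object@aliases)))
    return("aliases needs columns evidence_name, event_code")
  pos <- paste(object@causalPositive$from, object@causalPositive$to,
               sep = "\r")
  negUncond <- object@causalNegative[object@causalNegative$context == "", ]
  neg <- paste(negUncond$from, negUncond$to, sep = "\r")
  if (length(intersect(pos, neg)))
    return("a pair cannot be both causal-positive and unconditionally causal-negative")
  TRUE
})

#' Bootstrap orientation-stability report
#'
#' Summarises a list of bootstrap graphs: each orientation-blind adjacency
#' present in at least `supportThreshold` of the graphs is reported with its
#' support and the fraction of supporting graphs carrying each orientation.
#' An adjacency is *ambiguous* when both orientations appear in at least
#' `orientationThreshold` of the graphs containing it.
#'
#' @slot table `data.frame` with one row per reported adjacency: `node_a`,
#'   `node_b` (lexicographic), `support`, `forward_frac` (a to b),
#'   `reverse_frac`, `ambiguous`.
#' @slot ambiguousPct Percentage of reported adjacencies that are ambiguous
#'   (`NA` when no adjacency clears the support threshold).
#' @slot nGraphs Number of graphs summarised.
#' @slot supportThreshold,orientationThreshold The thresholds applied.
#' @seealso [orientationStability()]
#' @export
setClass("StabilityReport",
         representation(table = "data.frame", ambiguousPct = "numeric",
                        nGraphs = "integer", supportThreshold = "numeric",
                        orientationThreshold = "numeric"))

#' Ground-truth generative model for synthetic cohorts
#'
#' Defines the data-generating process used by [simulatePanel()] and
#' [simulateRawEvents()]: a DAG over event codes, per-node logistic models
#' for the window-1 cross section (applied by ancestral sampling), per-node
#' logistic transition models for incidence in window 2 given the window-1
#' parent statuses (pre-existing events persist deterministically), the
#' probability that a patient has observation-anchor records at both ends of
#' the study, and timestamp-noise parameters (mean exponential documentation
#' lag in days; probability of shuffling record dates within a
#' patient-window).
#'
#' @slot nodes Character vector of event codes.
#' @slot edges `data.frame(parent, child)`, acyclic.
#' @slot w1Intercepts,transIntercepts Named numeric, log-odds intercepts per
#'   node for the window-1 and transition models.
#' @slot w1Coefs,transCoefs `data.frame(parent, child, beta)` log-odds
#'   coefficients; rows must correspond to edges.
#' @slot anchorProb Probability of an anchor record at each end of the study.
#' @slot lagMeanDays Mean of the exponential documentation lag (0 = none).
#' @slot reversalProb Probability that a patient-window's record dates are
#'   permuted among its events.
#' @seealso [groundTruthModel()], [defaultGroundTruth()]
#' @export
setClass("GroundTruthModel",
         representation(nodes = "character", edges = "data.frame",
                        w1Intercepts = "numeric", w1Coefs = "data.frame",
                        transIntercepts = "numeric", transCoefs = "data.frame",
                        anchorProb = "numeric", lagMeanDays = "numeric",
                        reversalProb = "numeric"))

setValidity("GroundTruthModel", function(object) {
  e <- object@edges
  if (nrow(e) && !all(c(e$parent, e$child) %in% object@nodes))
    return("edge endpoints must be nodes")
  if (nrow(e) && .hasCycle(object@nodes, e)) return("edges must form a DAG")
  for (nm in c("w1Intercepts", "transIntercepts")) {
    v <- slot(object, nm)
    if (!all(object@nodes %in% names(v)))
      return(sprintf("%s must name every node", nm))
    if (any(!is.finite(v))) return(sprintf("%s must be finite", nm))
  }
  for (nm in c("w1Coefs", "transCoefs")) {
    cf <- slot(object, nm)
    if (!all(c("parent", "child", "beta") %in% names(cf)))
      return(sprintf("%s needs columns parent, child, beta", nm))
    if (any(!is.finite(cf$beta)))
      return(sprintf("%s coefficients must be finite", nm))
    if (nrow(cf)) {
      key <- paste(cf$parent, cf$child, sep = "\r")
      ekey <- paste(e$parent, e$child, sep = "\r")
      if (!all(key %in% ekey))
        return(sprintf("%s rows must correspond to model edges", nm))
    }
  }
  if (object@anchorProb < 0 || object@anchorProb > 1)
    return("anchorProb must lie in [0,1]")
  if (object@lagMeanDays < 0) return("lagMeanDays must be non-negative")
  if (object@reversalProb < 0 || object@reversalProb > 1)
    return("reversalProb must lie in [0,1]")
  TRUE
})
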