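#' Construct a ground-truth generative model
#'
#' @param nodes Character vector of event codes.
#' @param edges `data.frame(parent, child)`, acyclic.
#' @param w1Intercepts,transIntercepts Named numeric log-odds intercepts per
#'   node: `w1Intercepts` drives the window-1 cross section (ancestral
#'   sampling over the DAG), `transIntercepts` the incidence transition.
#' @param w1Coefs,transCoefs `data.frame(parent, child, beta)`: log-odds
#'   effect of the parent's window-1 status on the child. Edges missing from
#'   a table get coefficient 0 in that model.
#' @param anchorProb Probability that a patient has an observation-anchor
#'   record before window 1 (and, independently, after window 2).
#' @param lagMeanDays Mean of the exponential documentation lag added to
#'   onset dates by [simulateRawEvents()] (0 disables the lag).
#' @param reversalProb Probability that the record dates of a patient-window
#'   are randomly permuted among its events (timestamp-order noise).
#' @return A [GroundTruthModel-class].
#' @export
groundTruthModel <- function(nodes, edges, w1Intercepts, w1Coefs = NULL,
                             transIntercepts, transCoefs = NULL,
                             anchorProb = 1, lagMeanDays = 0,
                             reversalProb = 0) {
  edges <- as.data.frame(edges)
  fixCoefs <- function(cf) {
    if (is.null(cf))
      return(data.frame(parent = character(), child = character(),
                        beta = numeric()))
    cf <- as.data.frame(cf)
    cf$parent <- as.character(cf$parent)
    cf$child <- as.character(cf$child)
    cf$beta <- as.numeric(cf$beta)
    cf
  }
  new("GroundTruthModel", nodes = as.character(nodes),
      edges = data.frame(parent = as.character(edges$parent),
                         child = as.character(edges$child)),
      w1Intercepts = w1Intercepts[nodes], w1Coefs = fixCoefs(w1Coefs),
      transIntercepts = transIntercepts[nodes],
      transCoefs = fixCoefs(transCoefs),
      anchorProb = anchorProb, lagMeanDays = lagMeanDays,
      reversalProb = reversalProb)
}

#' Default ten-node comorbidity ground truth
#'
#' A chronic-disease progression model in the style of a type-2 diabetes
#' comorbidity network: obesity drives hypertension, hyperlipidemia and
#' pre-diabetes; pre-diabetes drives diabetes; hypertension, hyperlipidemia
#' and diabetes drive coronary artery disease; hypertension and diabetes
#' drive chronic renal failure; coronary artery disease drives myocardial
#' infarction, which drives heart failure; hypertension drives
#' cerebrovascular disease. Ten nodes, twelve edges. Window-1 marginal
#' prevalences fall in roughly 0.05-0.3 and all causal effects are strong
#' (odds ratios of 3-4 in both the cross-sectional and the transition
#' models), the regime in which structure recovery is expected to be
#' near-perfect at a few thousand patients.
#'
#' @param anchorProb,lagMeanDays,reversalProb Observation/noise settings,
#'   see [groundTruthModel()].
#' @return A [GroundTruthModel-class].
#' @export
defaultGroundTruth <- function(anchorProb = 1, lagMeanDays = 0,
                               reversalProb = 0) {
  nodes <- c("ob", "htn", "hld", "predm", "dm", "cad", "mi", "chf", "crf",
             "cevd")
  edges <- data.frame(
    parent = c("ob", "ob", "ob", "predm", "htn", "hld", "dm", "htn", "dm",
               "cad", "mi", "htn"),
    child = c("htn", "hld", "predm", "dm", "cad", "cad", "cad", "crf",
              "crf", "mi", "chf", "cevd"))
  b3 <- log(3)
  b4 <- log(4)
  w1Int <- c(ob = logit(0.30), htn = logit(0.12), hld = logit(0.15),
             predm = logit(0.06), dm = logit(0.04), cad = logit(0.04),
             mi = logit(0.03), chf = logit(0.03), crf = logit(0.03),
             cevd = logit(0.04))
  w1Coefs <- data.frame(edges, beta = b3)
  trInt <- c(ob = logit(0.06), htn = logit(0.06), hld = logit(0.06),
             predm = logit(0.05), dm = logit(0.04), cad = logit(0.04),
             mi = logit(0.03), chf = logit(0.03), crf = logit(0.03),
             cevd = logit(0.03))
  trCoefs <- data.frame(edges, beta = b4)
  groundTruthModel(nodes, edges, w1Int, w1Coefs, trInt, trCoefs,
                   anchorProb = anchorProb, lagMeanDays = lagMeanDays,
                   reversalProb = reversalProb)
}

#' Random sparse ground truth for small test instances
#'
#' Draws a random DAG (edges oriented along a random topological order with
#' probability `edgeProb`), window-1 prevalences uniform in `prevRange`,
#' transition baselines uniform in `baseIncRange` and all causal log-odds
#' coefficients equal to `beta`.
#'
#' @param nNodes Number of events.
#' @param edgeProb Probability of each forward pair being an edge.
#' @param beta Log-odds effect size for both models.
#' @param prevRange,baseIncRange Ranges for window-1 prevalence and baseline
#'   incidence.
#' @param seed Integer seed.
#' @return A [GroundTruthModel-class].
#' @export
randomGroundTruth <- function(nNodes = 6L, edgeProb = 0.3, beta = log(3),
                              prevRange = c(0.1, 0.3),
                              baseIncRange = c(0.04, 0.1), seed = 1L) {
  set.seed(as.integer(seed))
  nodes <- sprintf("v%02d", seq_len(nNodes))
  ord <- sample(nodes)
  pairs <- utils::combn(seq_len(nNodes), 2L)
  sel <- stats::runif(ncol(pairs)) < edgeProb
  edges <- data.frame(parent = ord[pairs[1L, sel]],
                      child = ord[pairs[2L, sel]])
  w1Int <- stats::setNames(logit(stats::runif(nNodes, prevRange[1L],
                                              prevRange[2L])), nodes)
  trInt <- stats::setNames(logit(stats::runif(nNodes, baseIncRange[1L],
                                              baseIncRange[2L])), nodes)
  groundTruthModel(nodes, edges, w1Int,
                   if (nrow(edges)) data.frame(edges, beta = beta) else NULL,
                   trInt,
                   if (nrow(edges)) data.frame(edges, beta = beta) else NULL)
}

.coefMatrix <- function(model, which = c("w1", "trans")) {
  which <- match.arg(which)
  cf <- if (which == "w1") model@w1Coefs else model@transCoefs
  k <- length(model@nodes)
  B <- matrix(0, k, k, dimnames = list(model@nodes, model@nodes))
  if (nrow(cf)) B[cbind(cf$parent, cf$child)] <- cf$beta
  B
}

.topoOrder <- function(nodes, edges) {
  if (!nrow(edges)) return(nodes)
  ig <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                      vertices = nodes)
  names(igraph::topo_sort(ig, mode = "out"))
}

#' Simulate an event panel from a ground-truth model
#'
#' Window-1 statuses are drawn by ancestral sampling over the DAG (each node
#' is Bernoulli with log-odds equal to its window-1 intercept plus the sum
#' of parent coefficients over the already-sampled parent statuses).
#' Window-2 statuses follow the transition model: a pre-existing event
#' persists deterministically, an absent one becomes incident with
#' probability `expit(intercept + sum(beta * x1(parent)))`. Observation
#' flags are Bernoulli with the model's `anchorProb` at each end.
#'
#' @param model A [GroundTruthModel-class].
#' @param n Number of patients.
#' @param seed Integer seed; output is deterministic given
#'   `(model, n, seed)`.
#' @return An [EventPanel-class] with the generating model stored in
#'   `metadata(panel)$truth`.
#' @export
simulatePanel <- function(model, n, seed) {
  stopifnot(is(model, "GroundTruthModel"), n >= 1L)
  set.seed(as.integer(seed))
  nodes <- model@nodes
  Bw1 <- .coefMatrix(model, "w1")
  Btr <- .coefMatrix(model, "trans")

  X1 <- matrix(0L, nrow = n, ncol = length(nodes),
               dimnames = list(sprintf("p%0*d", nchar(as.character(n)),
                                       seq_len(n)), nodes))
  for (v in .topoOrder(nodes, model@edges)) {
    eta <- model@w1Intercepts[v] + drop(X1 %*% Bw1[, v])
    X1[, v] <- stats::rbinom(n, 1L, expit(eta))
  }
  X2 <- X1
  for (v in nodes) {
    eta <- model@transIntercepts[v] + drop(X1 %*% Btr[, v])
    inc <- stats::rbinom(n, 1L, expit(eta))
    X2[, v] <- as.integer(X1[, v] == 1L | inc == 1L)
  }
  obs1 <- stats::runif(n) < model@anchorProb
  obs2 <- stats::runif(n) < model@anchorProb
  panel <- EventPanel(t(X1), t(X2), observedBeforeW1 = obs1,
                      observedAfterW2 = obs2)
  S4Vectors::metadata(panel)$truth <- model
  panel
}

#' Simulate raw time-stamped tables from a ground-truth model
#'
#' Converts a simulated truth panel into dated records the way an EHR would
#' hold them: each pre-existing event gets an onset date uniform in window 1,
#' each incident event an onset date uniform in window 2; an exponential
#' documentation lag (mean `lagMeanDays`) is added; with probability
#' `reversalProb` the dates of a patient's events within the same window are
#' permuted (onset-order noise that the two-window transformation should be
#' immune to). Anchor measurement records (`anchor_code`) are emitted before
#' window 1 and after window 2 with probability `anchorProb` each, and a
#' demographics table with adult ages is generated. Records whose lag pushes
#' them across their window boundary are counted in the `n_crossings`
#' attribute so transformation error can be bounded.
#'
#' @param model A [GroundTruthModel-class].
#' @param windows A [StudyWindows-class].
#' @param n Number of patients.
#' @param seed Integer seed.
#' @param anchorCode Measurement code used for anchor records.
#' @return List with `events` (raw event table), `measurements`,
#'   `demographics`, `truth` (the truth [EventPanel-class], observation
#'   flags matching the emitted anchors), `model`, and attribute-like field
#'   `n_crossings`.
#' @export
simulateRawEvents <- function(model, windows, n, seed,
                              anchorCode = "bp_measurement") {
  stopifnot(is(model, "GroundTruthModel"), is(windows, "StudyWindows"))
  panel <- simulatePanel(model, n, seed)  # consumes the seed stream first
  pats <- patientIds(panel)
  X1 <- t(x1Matrix(panel))
  Inc <- t(incidentMatrix(panel))

  w1Days <- as.integer(windows@w1End - windows@w1Start)
  w2Days <- as.integer(windows@w2End - windows@w2Start)

  recs <- list()
  crossings <- 0L
  for (v in eventCodes(panel)) {
    pre <- pats[X1[, v] == 1L]
    inc <- pats[Inc[, v] == 1L]
    if (length(pre)) {
      onset <- windows@w1Start +
        sample.int(w1Days + 1L, length(pre), replace = TRUE) - 1L
      lag <- if (model@lagMeanDays > 0)
        round(stats::rexp(length(pre), 1 / model@lagMeanDays)) else 0
      dated <- onset + lag
      crossings <- crossings + sum(dated > windows@w1End)
      recs[[length(recs) + 1L]] <-
        data.frame(patient_id = pre, event_code = v, date = dated,
                   window = 1L)
    }
    if (length(inc)) {
      onset <- windows@w2Start +
        sample.int(w2Days + 1L, length(inc), replace = TRUE) - 1L
      lag <- if (model@lagMeanDays > 0)
        round(stats::rexp(length(inc), 1 / model@lagMeanDays)) else 0
      dated <- onset + lag
      crossings <- crossings + sum(dated > windows@w2End)
      recs[[length(recs) + 1L]] <-
        data.frame(patient_id = inc, event_code = v, date = dated,
                   window = 2L)
    }
  }
  events <- if (length(recs)) do.call(rbind, recs) else
    data.frame(patient_id = character(), event_code = character(),
               date = as.Date(character()), window = integer())

  if (model@reversalProb > 0 && nrow(events)) {
    grp <- paste(events$patient_id, events$window, sep = "\r")
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (length(idx) >= 2L && stats::runif(1L) < model@reversalProb)
        events$date[idx] <- events$date[sample(idx)]
    }
  }
  events$window <- NULL
  rownames(events) <- NULL

  obs1 <- SummarizedExperiment::colData(panel)$observed_before_w1
  obs2 <- SummarizedExperiment::colData(panel)$observed_after_w2
  meas <- rbind(
    if (any(obs1)) data.frame(patient_id = pats[obs1],
                              measurement_code = anchorCode,
                              value = round(stats::rnorm(sum(obs1), 125, 15), 1),
                              date = windows@w1Start - 30L),
    if (any(obs2)) data.frame(patient_id = pats[obs2],
                              measurement_code = anchorCode,
                              value = round(stats::rnorm(sum(obs2), 125, 15), 1),
                              date = windows@w2End + 30L))
  if (is.null(meas))
    meas <- data.frame(patient_id = character(),
                       measurement_code = character(), value = numeric(),
                       date = as.Date(character()))

  demo <- data.frame(
    patient_id = pats,
    birthdate = windows@w1End -
      round(stats::runif(n, 30, 80) * 365.25),
    sex = sample(c("F", "M"), n, replace = TRUE))

  list(events = events, measurements = meas, demographics = demo,
       truth = panel, model = model, n_crossings = crossings)
}

#' Structure-recovery metrics
#'
#' Directed-edge precision and recall of an estimated graph against the true
#' edge set, and the structural Hamming distance (missing adjacencies +
#' extra adjacencies + misoriented edges, each counted once).
#'
#' @param gHat A [CausalGraph-class] or `data.frame(parent, child)`.
#' @param gTrue A [GroundTruthModel-class], [CausalGraph-class] or
#'   `data.frame(parent, child)`.
#' @return Named list: `edge_precision`, `edge_recall`, `shd` (precision of
#'   an empty estimate is `NA`).
#' @export
structureMetrics <- function(gHat, gTrue) {
  edgesOf <- function(g) {
    if (is(g, "CausalGraph")) return(graphEdges(g))
    if (is(g, "GroundTruthModel")) return(trueEdges(g))
    as.data.frame(g)[, c("parent", "child")]
  }
  eh <- edgesOf(gHat)
  et <- edgesOf(gTrue)
  kh <- .edgeKey(eh$parent, eh$child)
  kt <- .edgeKey(et$parent, et$child)
  ah <- .unorderedKey(eh$parent, eh$child)
  at <- .unorderedKey(et$parent, et$child)
  misoriented <- sum(ah %in% at & !(kh %in% kt))
  missing <- sum(!(at %in% ah))
  extra <- sum(!(ah %in% at))
  list(edge_precision = if (length(kh)) mean(kh %in% kt) else NA_real_,
       edge_recall = if (length(kt)) mean(kt %in% kh) else NA_real_,
       shd = missing + extra + misoriented)
}
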