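#' Risk set of an event
#'
#' The fitting population for a node's transition model: patients without the
#' event at the first cross section (for the others the probability of
#' presence at the second cross section is 1) that are under observation at
#' both cross sections.
#'
#' @param panel An [EventPanel-class].
#' @param v Event code.
#' @return Character vector of patient ids.
#' @export
riskSet <- function(panel, v) {
  stopifnot(is(panel, "EventPanel"))
  if (!v %in% eventCodes(panel))
    stop(sprintf("unknown event '%s'", v), call. = FALSE)
  sel <- x1Matrix(panel)[v, ] == 0L & observedBoth(panel)
  patientIds(panel)[sel]
}

# Plain IRLS logistic fit via glm.fit with separation detection; returns
# list(coef, logLik, converged, method). X has no intercept column.
.fitLogistic <- function(y, X, ridgeLambda = 1e-4) {
  m <- length(y)
  k <- ncol(X)
  cn <- colnames(X)

  intOnly <- function(method) {
    kk <- sum(y)
    p <- min(max(kk / m, 0.5 / m), 1 - 0.5 / m)
    ll <- kk * log(p) + (m - kk) * log1p(-p)
    coef <- c("(Intercept)" = logit(p),
              stats::setNames(rep(0, k), cn))
    list(coef = coef, logLik = ll, converged = TRUE, method = method)
  }

  constY <- all(y == y[1L])
  if (k == 0L || constY) {
    out <- intOnly(if (constY) "degenerate" else "mle")
    out$converged <- !constY
    return(out)
  }

  # drop regressors constant on the risk set; their coefficients are not
  # identifiable and are reported as 0
  keep <- apply(X, 2L, function(col) length(unique(col)) > 1L)
  Xi <- cbind(`(Intercept)` = 1, X[, keep, drop = FALSE])

  sepWarn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xi, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })

  coef <- fit$coefficients
  degenerateFit <- anyNA(coef)
  separated <- sepWarn || !fit$converged || any(abs(coef[-1L]) > 15,
                                                na.rm = TRUE)
  method <- "mle"
  converged <- fit$converged && !separated && !degenerateFit

  if (separated || degenerateFit) {
    rf <- .ridgeLogistic(y, Xi, lambda = ridgeLambda)
    coef <- rf$coef
    mu <- expit(drop(Xi %*% coef))
    method <- "ridge"
    converged <- FALSE
  } else {
    mu <- fit$fitted.values
  }
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))

  full <- stats::setNames(rep(0, k + 1L), c("(Intercept)", cn))
  full[names(coef)] <- coef
  list(coef = full, logLik = ll, converged = converged, method = method)
}

# Newton iterations for the L2-penalised logistic log-likelihood
# ll(beta) - lambda/2 * sum(beta[-1]^2); stabilises separated fits.
.ridgeLogistic <- function(y, Xi, lambda = 1e-4, maxit = 100L, tol = 1e-8) {
  k <- ncol(Xi)
  beta <- numeric(k)
  pen <- c(0, rep(lambda, k - 1L))
  obj <- -Inf
  for (it in seq_len(maxit)) {
    eta <- drop(Xi %*% beta)
    mu <- expit(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    newObj <- sum(y * log(mu) + (1 - y) * log1p(-mu)) -
      sum(pen * beta^2) / 2
    grad <- drop(crossprod(Xi, y - mu)) - pen * beta
    W <- mu * (1 - mu)
    H <- crossprod(Xi, Xi * W) + diag(pen + 1e-10, k)
    step <- solve(H, grad)
    beta <- beta + step
    if (abs(newObj - obj) <= tol * (abs(newObj) + tol)) break
    obj <- newObj
  }
  list(coef = stats::setNames(beta, colnames(Xi)))
}

#' Fit a node's logistic transition model
#'
#' Maximum-likelihood logistic regression of the node's window-2 status on
#' the window-1 statuses of its parents, over the node's risk set. An
#' intercept is always included. Patients already positive at the first
#' cross section contribute probability 1 (log-likelihood 0) and are
#' excluded from fitting. A constant outcome falls back to a degenerate
#' intercept-only model at the empirical proportion clipped away from 0 and
#' 1; (quasi-)separation triggers a ridge-stabilised refit with a small
#' fixed L2 penalty (`lambda = 1e-4` on the parent coefficients, not the
#' intercept). The `converged` slot is `FALSE` whenever a fallback was used.
#'
#' @param panel An [EventPanel-class].
#' @param v Event code of the node.
#' @param parents Character vector of parent event codes (may be empty).
#' @return A [NodeTransitionModel-class].
#' @export
fitNodeModel <- function(panel, v, parents = character()) {
  stopifnot(is(panel, "EventPanel"))
  parents <- as.character(parents)
  if (v %in% parents) stop("a node cannot be its own parent", call. = FALSE)
  if (!all(parents %in% eventCodes(panel)))
    stop("unknown parent event code", call. = FALSE)
  rs <- riskSet(panel, v)
  if (!length(rs)) stop(sprintf("empty risk set for '%s'", v), call. = FALSE)

  y <- x2Matrix(panel)[v, rs]
  X <- t(x1Matrix(panel)[parents, rs, drop = FALSE])
  colnames(X) <- parents
  fit <- .fitLogistic(as.numeric(y), X)
  new("NodeTransitionModel", node = v, parents = parents,
      coefficients = fit$coef, logLik = fit$logLik, m = length(rs),
      converged = fit$converged, method = fit$method)
}

.parentsOf <- function(edges, v) {
  as.character(edges$parent[edges$child == v])
}

.cacheKey <- function(v, parents)
  paste0(v, "|", paste(sort(parents), collapse = ","))

# fetch-or-fit a node term; cache maps .cacheKey -> NodeTransitionModel
.nodeTerm <- function(panel, v, parents, cache) {
  key <- .cacheKey(v, parents)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  mod <- fitNodeModel(panel, v, parents)
  if (!is.null(cache)) cache[[key]] <- mod
  mod
}

#' Score a causal graph by the transition BIC
#'
#' The graph log-likelihood is the sum over nodes of the fitted transition
#' log-likelihood of the node given its parents (the window-1 cross-section
#' term is a constant for a fixed transition graph and is dropped). The
#' score is `BIC = -2 * logLik + log(n) * |G|`, where `n` is the number of
#' patients observed at both cross sections and `|G|` is the number of
#' edges — the penalty counts edges, not parameters, and intercepts are
#' unpenalised. Nodes with an empty risk set contribute 0 to the
#' log-likelihood (such nodes cannot receive parents).
#'
#' @param panel An [EventPanel-class].
#' @param graph A [CausalGraph-class] (acyclic, nodes in the panel).
#' @param cache Optional environment used to memoise node terms keyed by
#'   (node, parent set); pass the same environment across calls to reuse
#'   fits.
#' @return A [CausalGraph-class] identical to `graph` but carrying fitted
#'   `nodeModels()` and a [ScoreComponents-class] in `graphScoreOf()`.
#' @export
graphScore <- function(panel, graph, cache = NULL) {
  stopifnot(is(panel, "EventPanel"), is(graph, "CausalGraph"))
  if (!all(graphNodes(graph) %in% eventCodes(panel)))
    stop("graph nodes must exist in the panel", call. = FALSE)

  nodes <- graphNodes(graph)
  edges <- graphEdges(graph)
  models <- vector("list", length(nodes))
  names(models) <- nodes
  nodeLL <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    pa <- .parentsOf(edges, v)
    rs <- riskSet(panel, v)
    if (!length(rs)) {
      if (length(pa))
        stop(sprintf("node '%s' has an empty risk set and cannot have parents",
                     v), call. = FALSE)
      nodeLL[v] <- 0
      next
    }
    mod <- .nodeTerm(panel, v, pa, cache)
    models[[v]] <- mod
    nodeLL[v] <- mod@logLik
  }
  n <- sum(observedBoth(panel))
  ll <- sum(nodeLL)
  score <- new("ScoreComponents", nodeLogLik = nodeLL, logLik = ll,
               n = as.integer(n), nEdges = nrow(edges),
               bic = -2 * ll + log(n) * nrow(edges))
  graph@models <- models[!vapply(models, is.null, logical(1))]
  graph@score <- score
  graph
}

#' Write a score audit report
#'
#' Structured JSON with the per-node log-likelihood terms, totals, sample
#' size and edge count of a scored graph.
#'
#' @param graph A scored [CausalGraph-class] (see [graphScore()]).
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
exportScoreReport <- function(graph, file) {
  sc <- graphScoreOf(graph)
  if (is.null(sc)) stop("graph has not been scored", call. = FALSE)
  rep <- list(n = sc@n, n_edges = sc@nEdges, log_lik = sc@logLik,
              bic = sc@bic, node_log_lik = as.list(sc@nodeLogLik),
              node_methods = lapply(nodeModels(graph), function(m) m@method))
  jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
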