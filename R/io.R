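#' Export a causal graph
#'
#' Writes the edge list as `parent<TAB>child` text (`format = "tsv"`), or a
#' GraphML / DOT rendering via [igraph::write_graph()].
#'
#' @param graph A [CausalGraph-class].
#' @param file Output path.
#' @param format One of `"tsv"`, `"graphml"`, `"dot"`.
#' @return `file`, invisibly.
#' @export
exportGraph <- function(graph, file, format = c("tsv", "graphml", "dot")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(graphEdges(graph), file, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    igraph::write_graph(asIgraph(graph), file, format = format)
  }
  invisible(file)
}

#' Export bootstrap edge frequencies
#'
#' One row per directed edge observed in any replica:
#' `parent,child,support_fraction`.
#'
#' @param graphs List of [CausalGraph-class] from [bootstrapGraphs()].
#' @param file Output path.
#' @param sep Field separator.
#' @return `file`, invisibly.
#' @export
exportEdgeFrequencies <- function(graphs, file, sep = ",") {
  supp <- .edgeSupport(graphs)
  keys <- names(supp)
  pc <- if (length(keys)) do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
        else matrix(character(), 0L, 2L)
  out <- data.frame(parent = pc[, 1L][seq_along(keys)],
                    child = pc[, 2L][seq_along(keys)],
                    support_fraction = unname(supp))
  out <- out[order(-out$support_fraction, out$parent, out$child), ,
             drop = FALSE]
  utils::write.table(out, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a study configuration file
#'
#' YAML with fields `windows` (`w1_start`, `w1_end`, `w2_start`, `w2_end`),
#' `anchor_codes`, optional `vocabulary`, optional `cutoffs` (per
#' measurement code, a list of bands with `event_code`, `lower`, `upper`;
#' `upper: .inf` or absent for unbounded), optional `strict` (default
#' `FALSE`), optional `alpha` (default 0.05), optional `min_discordant`
#' (default 0).
#'
#' @param file Path to the YAML configuration.
#' @return List with elements `windows` ([StudyWindows-class]),
#'   `anchor_codes`, `vocabulary`, `cutoffs`, `strict`, `alpha`,
#'   `min_discordant`.
#' @export
readStudyConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  w <- cfg$windows
  if (is.null(w)) stop("config is missing 'windows'", call. = FALSE)
  windows <- studyWindows(w$w1_start, w$w1_end, w$w2_start, w$w2_end)
  cutoffs <- cfg$cutoffs
  if (!is.null(cutoffs)) {
    cutoffs <- lapply(cutoffs, function(bands) lapply(bands, function(b) {
      if (is.null(b$upper)) b$upper <- Inf
      b$lower <- as.numeric(b$lower)
      b$upper <- as.numeric(b$upper)
      b
    }))
    .validateCutoffs(cutoffs)
  }
  list(windows = windows,
       anchor_codes = as.character(cfg$anchor_codes),
       vocabulary = if (is.null(cfg$vocabulary)) NULL
                    else as.character(cfg$vocabulary),
       cutoffs = cutoffs,
       strict = isTRUE(cfg$strict),
       alpha = if (is.null(cfg$alpha)) 0.05 else as.numeric(cfg$alpha),
       min_discordant = if (is.null(cfg$min_discordant)) 0L
                        else as.integer(cfg$min_discordant))
}

#' Run the discovery pipeline from raw tables
#'
#' End-to-end driver used by the command-line interface: categorizes
#' measurements, applies the inclusion criteria (anchor records are the
#' measurement occasions plus any anchor-coded events), builds the panel,
#' extracts precedence constraints and runs the greedy search.
#'
#' @param events Raw event table (see [readEventTable()]).
#' @param measurements Optional measurement table.
#' @param demographics Demographics table.
#' @param config A configuration list from [readStudyConfig()].
#' @return List with `panel`, `constraints`, `graph`, `cohort`.
#' @export
runDiscovery <- function(events, measurements = NULL, demographics, config) {
  raw <- .asEventTable(events)
  anchorRows <- raw[0L, ]
  if (!is.null(measurements) && nrow(measurements)) {
    anchorRows <- measurementEvents(measurements)
    if (!is.null(config$cutoffs))
      raw <- rbind(raw, categorizeMeasurements(measurements, config$cutoffs))
  }
  cohort <- applyInclusionCriteria(rbind(raw, anchorRows), demographics,
                                   config$windows, config$anchor_codes)
  if (!length(cohort)) stop("no patient satisfies the inclusion criteria",
                            call. = FALSE)
  panel <- buildEventPanel(raw, config$windows, cohort,
                           vocabulary = config$vocabulary,
                           strict = config$strict)
  constraints <- computePrecedence(panel, alpha = config$alpha,
                                   minDiscordant = config$min_discordant)
  graph <- greedySearch(panel, constraints)
  list(panel = panel, constraints = constraints, graph = graph,
       cohort = cohort)
}
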