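#' Extract temporal precedence constraints from an event panel
#'
#' For every unordered pair of events \{A, B\}, patients carrying both events
#' by the second cross section are classified by which event came first at
#' window resolution: `n_forward` counts patients with A pre-existing and B
#' incident, `n_reverse` counts the converse. Patients with both events
#' pre-existing or both incident are concordant at window resolution and
#' carry no ordering information. "A precedes B" is declared when the exact
#' two-sided binomial (McNemar-style) test of the discordant split against
#' proportion 1/2 rejects at `alpha` and A leads the majority of discordant
#' patients; the reported `p_value` is the two-sided exact p (twice the
#' majority-direction tail sum, capped at 1). Testing two-sided at `alpha`
#' and orienting by the majority keeps the per-pair type-I rate at `alpha`
#' (two one-sided tests at `alpha` each would admit null pairs at nearly
#' twice the nominal rate). At most one orientation per pair can be
#' admitted. Pairs whose events always co-occur in the same window (no
#' discordant patients) are never admitted: they have no clear precedence.
#'
#' The resulting constraint set fixes the only admissible edges — and their
#' orientations — for [greedySearch()].
#'
#' @param panel An [EventPanel-class].
#' @param alpha Per-pair significance level (default 0.05); rejection uses
#'   `p <= alpha` on the two-sided exact p. No multiplicity correction is
#'   applied: the constraint set is deliberately permissive, and
#'   over-inclusion is later filtered by the BIC search.
#' @param minDiscordant Minimum number of discordant patients required before
#'   a pair is tested (default 0, i.e. off).
#' @return A [PrecedenceSet-class] sorted by p-value.
#' @export
computePrecedence <- function(panel, alpha = 0.05, minDiscordant = 0L) {
  stopifnot(is(panel, "EventPanel"))
  if (ncol(panel) == 0L) stop("empty panel", call. = FALSE)
  .assertScalarProb(alpha, "alpha")

  X1 <- t(x1Matrix(panel))      # patients x events
  Inc <- t(incidentMatrix(panel))
  ev <- eventCodes(panel)
  # n_forward[A, B] = #patients with A pre-existing and B incident; the
  # restriction to patients having both events by window 2 is implied because
  # x1(A) = 1 forces x2(A) = 1 and incident(B) forces x2(B) = 1.
  NF <- crossprod(X1, Inc)

  rows <- list()
  k <- 0L
  for (i in seq_along(ev)[-length(ev)]) {
    for (j in seq.int(i + 1L, length(ev))) {
      nf <- NF[i, j]
      nr <- NF[j, i]
      m <- nf + nr
      if (m == 0L || m < minDiscordant) next
      if (nf >= nr) {
        tail <- stats::pbinom(nf - 1L, m, 0.5, lower.tail = FALSE)
        earlier <- ev[i]; later <- ev[j]
        cf <- nf; cr <- nr
      } else {
        tail <- stats::pbinom(nr - 1L, m, 0.5, lower.tail = FALSE)
        earlier <- ev[j]; later <- ev[i]
        cf <- nr; cr <- nf
      }
      p <- min(1, 2 * tail)
      if (p <= alpha && cf > cr) {
        k <- k + 1L
        rows[[k]] <- data.frame(earlier = earlier, later = later,
                                n_forward = as.integer(cf),
                                n_reverse = as.integer(cr), p_value = p)
      }
    }
  }
  pairs <- if (k) do.call(rbind, rows) else
    data.frame(earlier = character(), later = character(),
               n_forward = integer(), n_reverse = integer(),
               p_value = numeric())
  pairs <- pairs[order(pairs$p_value, pairs$earlier, pairs$later), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  new("PrecedenceSet", pairs = pairs, alpha = alpha, events = ev)
}

#' Export a precedence set as delimited text
#'
#' Columns `earlier,later,n_forward,n_reverse,p_value`, sorted by p-value.
#'
#' @param pset A [PrecedenceSet-class].
#' @param file Output path.
#' @param sep Field separator.
#' @return `file`, invisibly.
#' @export
exportPrecedence <- function(pset, file, sep = ",") {
  stopifnot(is(pset, "PrecedenceSet"))
  utils::write.table(precedencePairs(pset), file, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
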