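#' @importFrom data.table as.data.table setnames :=
NULL

.asEventTable <- function(raw) {
  raw <- as.data.frame(raw)
  need <- c("patient_id", "event_code", "date")
  if (!all(need %in% names(raw)))
    stop("event table needs columns patient_id, event_code, date",
         call. = FALSE)
  raw$patient_id <- as.character(raw$patient_id)
  raw$event_code <- as.character(raw$event_code)
  raw$date <- as.Date(raw$date)
  if (nrow(raw)) {
    if (anyNA(raw$date)) stop("unparseable date in event table", call. = FALSE)
    if (anyNA(raw$patient_id) || anyNA(raw$event_code) ||
        any(raw$patient_id == "") || any(raw$event_code == ""))
      stop("missing patient_id or event_code in event table", call. = FALSE)
  }
  raw[, need]
}

#' Read the delimited input tables
#'
#' Readers for the three long-format inputs: raw events
#' (`patient_id,event_code,date`), numeric measurements
#' (`patient_id,measurement_code,value,date`) and demographics
#' (`patient_id,birthdate,sex`). Dates are ISO-8601.
#'
#' @param file Path to a delimited text file with a header.
#' @param sep Field separator.
#' @return A `data.frame` with typed columns.
#' @export
readEventTable <- function(file, sep = ",") {
  .asEventTable(utils::read.table(file, header = TRUE, sep = sep,
                                  colClasses = "character"))
}

#' @rdname readEventTable
#' @export
readMeasurementTable <- function(file, sep = ",") {
  m <- utils::read.table(file, header = TRUE, sep = sep,
                         colClasses = "character")
  need <- c("patient_id", "measurement_code", "value", "date")
  if (!all(need %in% names(m)))
    stop("measurement table needs columns patient_id, measurement_code, value, date",
         call. = FALSE)
  m$value <- as.numeric(m$value)
  m$date <- as.Date(m$date)
  if (any(!is.finite(m$value))) stop("non-finite measurement value",
                                     call. = FALSE)
  m[, need]
}

#' @rdname readEventTable
#' @export
readDemographics <- function(file, sep = ",") {
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         colClasses = "character")
  need <- c("patient_id", "birthdate", "sex")
  if (!all(need %in% names(d)))
    stop("demographics table needs columns patient_id, birthdate, sex",
         call. = FALSE)
  d$birthdate <- as.Date(d$birthdate)
  d[, need]
}

#' Apply the cohort inclusion criteria
#'
#' Selects patients that are demonstrably under observation across the whole
#' study: at least one anchor-coded record dated strictly before the start of
#' window 1 AND at least one dated strictly after the end of window 2 (the
#' default configuration uses blood-pressure measurements as anchors), aged
#' 18 or over at the end of window 1, with non-missing sex and birthdate.
#'
#' @param raw A raw event table (`patient_id`, `event_code`, `date`); anchor
#'   records may come from [measurementEvents()].
#' @param demographics `data.frame(patient_id, birthdate, sex)`.
#' @param windows A [StudyWindows-class].
#' @param anchorCodes Character vector of event codes that count as
#'   observation anchors.
#' @return Character vector of included patient ids (sorted). Patients in
#'   `raw` with no demographics row are excluded with a warning.
#' @export
applyInclusionCriteria <- function(raw, demographics, windows, anchorCodes) {
  raw <- .asEventTable(raw)
  demographics <- as.data.frame(demographics)
  demographics$patient_id <- as.character(demographics$patient_id)
  demographics$birthdate <- as.Date(demographics$birthdate)
  stopifnot(is(windows, "StudyWindows"))
  if (!nrow(raw)) return(character())

  pats <- unique(raw$patient_id)
  miss <- setdiff(pats, demographics$patient_id)
  if (length(miss))
    warning(sprintf("%d patient(s) without demographics excluded: %s",
                    length(miss),
                    paste(utils::head(miss, 5L), collapse = ", ")),
            call. = FALSE)

  anch <- raw[raw$event_code %in% anchorCodes, , drop = FALSE]
  before <- unique(anch$patient_id[anch$date < windows@w1Start])
  after <- unique(anch$patient_id[anch$date > windows@w2End])

  d <- demographics[match(pats, demographics$patient_id), , drop = FALSE]
  ageOk <- !is.na(d$birthdate) &
    (as.numeric(windows@w1End - d$birthdate) / 365.25) >= 18
  sexOk <- !is.na(d$sex) & d$sex != ""
  keep <- pats %in% before & pats %in% after &
    !(pats %in% miss) & ageOk & sexOk
  sort(pats[keep])
}

#' Categorize numeric measurements into threshold events
#'
#' Turns each measurement row whose value falls into a configured band into
#' an event row carrying the measurement date. Bands use closed lower and
#' open upper bounds, so a value equal to the cutoff fires the "at or above
#' cutoff" event (e.g. guideline bands such as "SBP >= 140" or
#' "BMI >= 25 and < 30").
#'
#' @param measurements `data.frame(patient_id, measurement_code, value,
#'   date)`.
#' @param cutoffs Named list: one entry per measurement code, each a list of
#'   bands `list(event_code =, lower =, upper =)` (`upper` may be `Inf`).
#'   Bands within a code must be disjoint.
#' @return A raw event table; rows whose value matches no band emit nothing.
#' @examples
#' m <- data.frame(patient_id = "p1", measurement_code = "sbp",
#'                 value = 142, date = "2003-05-01")
#' co <- list(sbp = list(list(event_code = "sbp_high", lower = 140,
#'                            upper = Inf)))
#' categorizeMeasurements(m, co)
#' @export
categorizeMeasurements <- function(measurements, cutoffs) {
  m <- as.data.frame(measurements)
  m$patient_id <- as.character(m$patient_id)
  m$measurement_code <- as.character(m$measurement_code)
  m$value <- as.numeric(m$value)
  m$date <- as.Date(m$date)
  .validateCutoffs(cutoffs)
  out <- vector("list", length(cutoffs))
  for (i in seq_along(cutoffs)) {
    code <- names(cutoffs)[i]
    rows <- m[m$measurement_code == code, , drop = FALSE]
    if (!nrow(rows)) next
    hits <- lapply(cutoffs[[i]], function(band) {
      sel <- rows$value >= band$lower & rows$value < band$upper
      if (!any(sel)) return(NULL)
      data.frame(patient_id = rows$patient_id[sel],
                 event_code = band$event_code,
                 date = rows$date[sel])
    })
    out[[i]] <- do.call(rbind, hits)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(patient_id = character(), event_code = character(),
                      date = as.Date(character()))
  rownames(res) <- NULL
  res
}

.validateCutoffs <- function(cutoffs) {
  if (!is.list(cutoffs) || (length(cutoffs) && is.null(names(cutoffs))))
    stop("cutoffs must be a named list keyed by measurement code",
         call. = FALSE)
  for (code in names(cutoffs)) {
    bands <- cutoffs[[code]]
    for (b in bands)
      if (!all(c("event_code", "lower", "upper") %in% names(b)) ||
          b$lower >= b$upper)
        stop(sprintf("malformed band for measurement '%s'", code),
             call. = FALSE)
    if (length(bands) > 1L) {
      lo <- vapply(bands, `[[`, numeric(1), "lower")
      hi <- vapply(bands, `[[`, numeric(1), "upper")
      o <- order(lo)
      if (any(hi[o][-length(o)] > lo[o][-1L]))
        stop(sprintf("overlapping bands for measurement '%s'", code),
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Presence events for measurement records
#'
#' Reduces a measurement table to presence rows (`patient_id`,
#' `measurement_code` as the event code, `date`) so that measurement
#' occasions can serve as observation anchors in
#' [applyInclusionCriteria()], irrespective of the measured value.
#'
#' @param measurements `data.frame(patient_id, measurement_code, value,
#'   date)`.
#' @return A raw event table.
#' @export
measurementEvents <- function(measurements) {
  m <- as.data.frame(measurements)
  data.frame(patient_id = as.character(m$patient_id),
             event_code = as.character(m$measurement_code),
             date = as.Date(m$date))
}

#' Build the two-cross-section event panel
#'
#' Collapses time-stamped records into per-patient binary statuses at the two
#' cross sections: `x1 = 1` when any record of the event is dated on or
#' before the end of window 1 (pre-existing), `x2 = 1` when any record is
#' dated on or before the end of window 2. Records first occurring in the
#' gap between the windows count as incident for window 2, and records after
#' the end of window 2 are ignored, so `x1 <= x2` holds by construction.
#' Within-window record order is irrelevant — only the earliest date per
#' patient-event matters — which is what makes the panel robust to noisy
#' documentation timestamps.
#'
#' @param raw A raw event table.
#' @param windows A [StudyWindows-class].
#' @param cohort Character vector of patient ids to keep (typically from
#'   [applyInclusionCriteria()]); patients with no event rows appear as
#'   all-zero columns.
#' @param vocabulary Optional character vector fixing the event set; records
#'   with codes outside it are dropped with a warning, or abort when
#'   `strict = TRUE`. Default: all codes seen in `raw`.
#' @param strict Abort on unknown event codes instead of dropping them.
#' @param observedBeforeW1,observedAfterW2 Optional named logical vectors
#'   overriding the per-patient observation flags (default: all `TRUE`,
#'   appropriate for a cohort selected by anchor records).
#' @return An [EventPanel-class].
#' @export
buildEventPanel <- function(raw, windows, cohort, vocabulary = NULL,
                            strict = FALSE,
                            observedBeforeW1 = NULL, observedAfterW2 = NULL) {
  raw <- .asEventTable(raw)
  stopifnot(is(windows, "StudyWindows"))
  cohort <- sort(unique(as.character(cohort)))
  if (!length(cohort)) stop("empty cohort", call. = FALSE)

  raw <- raw[raw$patient_id %in% cohort, , drop = FALSE]
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(raw$event_code))
  } else {
    unknown <- setdiff(unique(raw$event_code), vocabulary)
    if (length(unknown)) {
      msg <- sprintf("%d event code(s) outside the vocabulary: %s",
                     length(unknown),
                     paste(utils::head(unknown, 5L), collapse = ", "))
      if (strict) stop(msg, call. = FALSE)
      warning(paste(msg, "- dropped"), call. = FALSE)
      raw <- raw[raw$event_code %in% vocabulary, , drop = FALSE]
    }
  }
  if (!length(vocabulary)) stop("empty event vocabulary", call. = FALSE)

  dt <- data.table::as.data.table(raw)
  first <- dt[, list(first_date = min(date)),
              by = c("patient_id", "event_code")]

  x1 <- matrix(0L, nrow = length(vocabulary), ncol = length(cohort),
               dimnames = list(vocabulary, cohort))
  x2 <- x1
  ri <- match(first$event_code, vocabulary)
  ci <- match(first$patient_id, cohort)
  x1[cbind(ri, ci)] <- as.integer(first$first_date <= windows@w1End)
  x2[cbind(ri, ci)] <- as.integer(first$first_date <= windows@w2End)

  obs1 <- rep(TRUE, length(cohort))
  obs2 <- rep(TRUE, length(cohort))
  if (!is.null(observedBeforeW1)) obs1 <- unname(observedBeforeW1[cohort])
  if (!is.null(observedAfterW2)) obs2 <- unname(observedAfterW2[cohort])
  EventPanel(x1, x2, observedBeforeW1 = obs1, observedAfterW2 = obs2)
}

#' Summarise an event panel
#'
#' Per-event window-1 prevalence (mean of `x1`) and window-2 incidence rate
#' (share of incident patients among those at risk, i.e. with `x1 = 0`).
#'
#' @param panel An [EventPanel-class].
#' @return `data.frame(event, prevalence_w1, incidence_w2, n_at_risk)`;
#'   `incidence_w2` is `NA` for events with an empty risk set.
#' @export
summarizePanel <- function(panel) {
  stopifnot(is(panel, "EventPanel"), ncol(panel) > 0L)
  x1 <- x1Matrix(panel)
  inc <- incidentMatrix(panel)
  atRisk <- ncol(panel) - rowSums(x1)
  data.frame(event = rownames(x1),
             prevalence_w1 = rowSums(x1) / ncol(panel),
             incidence_w2 = ifelse(atRisk > 0L, rowSums(inc) / atRisk, NA_real_),
             n_at_risk = as.integer(atRisk),
             row.names = NULL)
}

#' Export an event panel as wide delimited text
#'
#' One row per patient, columns `<event>__x1` and `<event>__x2`, plus the
#' observation flags.
#'
#' @param panel An [EventPanel-class].
#' @param file Output path.
#' @param sep Field separator.
#' @return `file`, invisibly.
#' @export
exportPanel <- function(panel, file, sep = ",") {
  x1 <- t(x1Matrix(panel))
  x2 <- t(x2Matrix(panel))
  colnames(x1) <- paste0(colnames(x1), "__x1")
  colnames(x2) <- paste0(colnames(x2), "__x2")
  out <- data.frame(patient_id = patientIds(panel), x1, x2,
                    observed_before_w1 =
                      as.integer(SummarizedExperiment::colData(panel)$observed_before_w1),
                    observed_after_w2 =
                      as.integer(SummarizedExperiment::colData(panel)$observed_after_w2),
                    check.names = FALSE)
  utils::write.table(out, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}
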