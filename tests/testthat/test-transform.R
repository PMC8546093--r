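w <- mcWindows()

demo5 <- data.frame(
  patient_id = c("p1", "p2", "p3", "p4", "p5"),
  birthdate = c("1960-01-01", "1960-01-01", "1990-06-01", "1960-01-01",
                "1960-01-01"),
  sex = c("F", "M", "F", "", "M"))

anchors5 <- function() {
  # p1: fully eligible; p2: no anchor after window 2; p3: under 18 at w1 end;
  # p4: sex missing; p5: no anchor before window 1
  data.frame(
    patient_id = c("p1", "p1", "p2", "p3", "p3", "p4", "p4", "p5"),
    event_code = "bp",
    date = c("2002-03-01", "2008-02-01", "2002-03-01", "2002-03-01",
             "2008-02-01", "2002-03-01", "2008-02-01", "2008-02-01"))
}

test_that("inclusion criteria implement each predicate", {
  expect_identical(
    applyInclusionCriteria(data.frame(patient_id = character(),
                                      event_code = character(),
                                      date = as.Date(character())),
                           demo5, w, "bp"),
    character())
  expect_identical(applyInclusionCriteria(anchors5(), demo5, w, "bp"), "p1")
  # age 40, anchors in 2002 and 2008, sex known -> included
  one <- data.frame(patient_id = "q1", event_code = "bp",
                    date = c("2002-06-01", "2008-06-01"))
  d <- data.frame(patient_id = "q1", birthdate = "1964-01-01", sex = "M")
  expect_identical(applyInclusionCriteria(one, d, w, "bp"), "q1")
  # missing demographics row excludes with a warning, not an abort
  expect_warning(
    res <- applyInclusionCriteria(one, demo5, w, "bp"),
    "without demographics")
  expect_identical(res, character())
})

test_that("measurement categorization fires closed-lower-bound bands", {
  co <- list(
    sbp = list(list(event_code = "sbp_ge_140", lower = 140, upper = Inf)),
    bmi = list(list(event_code = "bmi_25_30", lower = 25, upper = 30),
               list(event_code = "bmi_ge_30", lower = 30, upper = Inf)))
  m <- data.frame(patient_id = c("p1", "p1", "p2", "p2"),
                  measurement_code = c("sbp", "sbp", "bmi", "bmi"),
                  value = c(142, 139.9, 27, 30),
                  date = "2003-05-01")
  out <- categorizeMeasurements(m, co)
  expect_setequal(out$event_code[out$patient_id == "p1"], "sbp_ge_140")
  expect_identical(sort(out$event_code[out$patient_id == "p2"]),
                   c("bmi_25_30", "bmi_ge_30"))
  # exactly the lower band fires at 27, the upper at exactly 30
  expect_identical(out$event_code[out$patient_id == "p2" &
                                    out$event_code == "bmi_25_30"],
                   "bmi_25_30")
  expect_identical(out$date, rep(as.Date("2003-05-01"), 3))
  bad <- list(bmi = list(list(event_code = "a", lower = 25, upper = 31),
                         list(event_code = "b", lower = 30, upper = Inf)))
  expect_error(categorizeMeasurements(m, bad), "overlapping")
})

test_that("panel statuses follow the two-boundary definitions", {
  raw <- data.frame(
    patient_id = c("p1", "p2", "p3"),
    event_code = "dm",
    date = c("2003-06-01",   # inside window 1 -> pre-existing
             "2006-06-01",   # first in window 2 -> incident
             "2005-06-01"))  # gap only -> incident for window 2
  panel <- buildEventPanel(raw, w, c("p1", "p2", "p3"))
  expect_identical(as.vector(x1Matrix(panel)["dm", ]), c(1L, 0L, 0L))
  expect_identical(as.vector(x2Matrix(panel)["dm", ]), c(1L, 1L, 1L))
  expect_identical(as.vector(incidentMatrix(panel)["dm", ]), c(0L, 1L, 1L))
  # hand-built 3-patient, 2-event panel
  raw2 <- rbind(raw, data.frame(patient_id = c("p1", "p3"),
                                event_code = "htn",
                                date = c("2006-02-01", "2002-01-15")))
  panel2 <- buildEventPanel(raw2, w, c("p1", "p2", "p3"))
  expect_identical(x1Matrix(panel2),
                   matrix(c(1L, 0L, 0L, 0L, 0L, 1L), 2, 3, byrow = TRUE,
                          dimnames = list(c("dm", "htn"),
                                          c("p1", "p2", "p3"))))
  expect_identical(x2Matrix(panel2),
                   matrix(c(1L, 1L, 1L, 1L, 0L, 1L), 2, 3, byrow = TRUE,
                          dimnames = list(c("dm", "htn"),
                                          c("p1", "p2", "p3"))))
})

test_that("records after window 2 are ignored and cohort filtering applies", {
  raw <- data.frame(patient_id = c("p1", "p2"), event_code = "dm",
                    date = c("2008-06-01", "2003-06-01"))
  panel <- buildEventPanel(raw, w, c("p1", "p2"))
  expect_identical(as.vector(x2Matrix(panel)[, "p1"]), 0L)
  panel2 <- buildEventPanel(raw, w, "p2")
  expect_identical(patientIds(panel2), "p2")
})

test_that("unknown event codes drop with warning or abort in strict mode", {
  raw <- data.frame(patient_id = "p1", event_code = c("dm", "zzz"),
                    date = "2003-06-01")
  expect_warning(panel <- buildEventPanel(raw, w, "p1", vocabulary = "dm"),
                 "outside the vocabulary")
  expect_identical(eventCodes(panel), "dm")
  expect_error(buildEventPanel(raw, w, "p1", vocabulary = "dm",
                               strict = TRUE),
               "outside the vocabulary")
})

test_that("panel is idempotent in duplicate records and persistent", {
  for (seed in 1:5) {
    set.seed(seed)
    raw <- data.frame(
      patient_id = sample(sprintf("p%d", 1:6), 40, replace = TRUE),
      event_code = sample(c("a", "b", "c"), 40, replace = TRUE),
      date = as.Date("2002-01-01") + sample.int(2500, 40, replace = TRUE))
    cohort <- sprintf("p%d", 1:6)
    panel <- buildEventPanel(raw, w, cohort)
    expect_true(all(x1Matrix(panel) <= x2Matrix(panel)))
    dup <- rbind(raw, raw[sample.int(nrow(raw), 10), ])
    panel2 <- buildEventPanel(dup, w, cohort)
    expect_identical(x1Matrix(panel), x1Matrix(panel2))
    expect_identical(x2Matrix(panel), x2Matrix(panel2))
    # shrinking w1_end only moves statuses from pre-existing toward incident
    w2 <- studyWindows("2003-01-01", "2004-06-30", "2006-01-01", "2007-12-31")
    panel3 <- buildEventPanel(raw, w2, cohort)
    expect_true(all(x1Matrix(panel3) <= x1Matrix(panel)))
    expect_identical(x2Matrix(panel3), x2Matrix(panel))
  }
})

test_that("panel summary reports prevalence and at-risk incidence", {
  # 10 patients, 2 pre-existing, 2 of the remaining 8 incident
  x1 <- matrix(c(rep(1, 2), rep(0, 8)), ncol = 1,
               dimnames = list(sprintf("p%d", 1:10), "e"))
  x2 <- x1; x2[3:4] <- 1
  s <- summarizePanel(toyPanel(x1, x2))
  expect_equal(s$prevalence_w1, 0.2)
  expect_equal(s$incidence_w2, 0.25)
  # empty risk set -> undefined marker, not zero
  sFull <- summarizePanel(toyPanel(x1 * 0 + 1, x2 * 0 + 1))
  expect_true(is.na(sFull$incidence_w2))
  expect_equal(sFull$prevalence_w1, 1)
})

test_that("summary incidence matches the generating rate at scale", {
  nodes <- "e"
  m <- groundTruthModel(nodes,
                        data.frame(parent = character(), child = character()),
                        c(e = qlogis(0.2)), NULL, c(e = qlogis(0.1)), NULL)
  panel <- simulatePanel(m, 4000, seed = 3)
  s <- summarizePanel(panel)
  se <- sqrt(0.1 * 0.9 / s$n_at_risk)
  expect_lt(abs(s$incidence_w2 - 0.1), 3 * se)
})

test_that("panel export writes the wide layout", {
  panel <- randomPanel(3, 20, seed = 2)
  f <- tempfile(fileext = ".csv")
  exportPanel(panel, f)
  back <- read.csv(f, check.names = FALSE)
  expect_identical(nrow(back), ncol(panel))
  ev <- eventCodes(panel)[1]
  expect_identical(back[[paste0(ev, "__x1")]],
                   as.integer(x1Matrix(panel)[ev, ]))
  expect_identical(back[[paste0(ev, "__x2")]],
                   as.integer(x2Matrix(panel)[ev, ]))
})
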