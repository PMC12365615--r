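tmz <- drug_synonyms("temozolomide", c("temodar", "temodal"))

# three reports: a PS-target case with 3 PTs, a concomitant-only exposure,
# and an unexposed report
make_small_reports <- function() {
  structure(
    list(
      reports = tibble::tibble(
        report_id = c("1", "2", "3"),
        case_id = c("c1", "c2", "c3"),
        receipt_date = as.Date("2023-01-01") + 0:2,
        sex = c("male", "female", "unknown"),
        age_years = c(55, 30, NA),
        reporter_occupation = c("MD", NA, "PH"),
        reporter_country = c("US", "JP", NA),
        event_date = as.Date(c("2023-01-07", NA, NA)),
        therapy_start_date = as.Date(c("2023-01-01", NA, NA))
      ),
      drugs = tibble::tibble(
        report_id = c("1", "2", "3"),
        drug_name = c("TEMODAR", "temozolomide", "aspirin"),
        role = c("PS", "C", "PS"),
        sequence = 1L
      ),
      events = tibble::tibble(
        report_id = c("1", "1", "1", "2", "3"),
        pt = c("nausea", "rash", "fatigue", "nausea", "rash")
      ),
      outcomes = tibble::tibble(
        report_id = c("1", "1", "2"), outcome = c("HO", "DE", "OT")
      ),
      dropped = integer()
    ),
    class = "faers_reports"
  )
}

test_that("only a primary-suspect synonym match makes a case", {
  cohort <- flag_cases(make_small_reports(), tmz)
  expect_equal(
    cohort$reports$is_case[match(c("1", "2", "3"), cohort$reports$report_id)],
    c(TRUE, FALSE, FALSE)
  )
  # 3 PTs on report 1 give 3 units
  expect_equal(sum(cohort$units$report_id == "1"), 3)
})

test_that("case flagging ignores report order and duplicate PT rows", {
  reports <- make_small_reports()
  reports$events <- dplyr::bind_rows(reports$events, reports$events[1, ])
  shuffled <- reports
  ord <- c(3, 1, 2)
  shuffled$reports <- shuffled$reports[ord, ]
  a <- flag_cases(reports, tmz)
  b <- flag_cases(shuffled, tmz)
  expect_equal(nrow(a$units), 5) # duplicate (report, pt) collapses
  expect_setequal(
    a$reports$report_id[a$reports$is_case],
    b$reports$report_id[b$reports$is_case]
  )
})

test_that("demographic levels sum to the case-report denominator", {
  cohort <- flag_cases(make_small_reports(), tmz)
  dem <- summarize_demographics(cohort)
  for (cat in unique(dem$category)) {
    block <- dem[dem$category == cat, ]
    expect_equal(sum(block$count), 1) # one case report
    expect_equal(sum(block$percentage), 100)
  }
  expect_equal(dem$percentage[dem$category == "sex" & dem$level == "male"], 100)
})

test_that("all-unknown sex lands entirely in the unknown level", {
  cohort <- make_cohort(tibble::tibble(report_id = c("1", "2"), sex = "unknown"))
  dem <- summarize_demographics(cohort)
  sex <- dem[dem$category == "sex", ]
  expect_equal(sex$percentage[sex$level == "unknown"], 100)
  expect_equal(sex$count[sex$level == "unknown"], 2)
})

test_that("the worst outcome wins and reports without outcomes leave the denominator", {
  cohort <- flag_cases(make_small_reports(), tmz)
  oc <- summarize_outcomes(cohort)
  # report 1 has HO and DE: counted once, as DE; report 2 is not a case
  expect_equal(oc$count[oc$level == "DE"], 1)
  expect_equal(oc$count[oc$level == "HO"], 0)
  expect_equal(sum(oc$count), 1)
})

test_that("an outcome-free cohort summarises without division", {
  cohort <- make_cohort(tibble::tibble(report_id = "1"))
  oc <- summarize_outcomes(cohort)
  expect_equal(sum(oc$count), 0)
  expect_true(all(is.na(oc$percentage)))
})

test_that("time-to-onset bins are half-open and partial dates are unknown", {
  start <- as.Date("2023-01-01")
  cohort <- make_cohort(tibble::tibble(
    report_id = as.character(1:6),
    therapy_start_date = c(start, start, start, start, start, as.Date(NA)),
    event_date = c(
      start + 6, start + 28, start + 2, start - 1, as.Date(NA), as.Date(NA)
    )
  ))
  tto <- summarize_tto(cohort)
  expect_equal(tto$count[tto$level == "<7"], 2) # 6 days and 2 days
  expect_equal(tto$count[tto$level == "28-60"], 1) # day 28 enters the higher bin
  expect_equal(tto$count[tto$level == "unknown"], 2) # negative + one-sided
  # report 6 has no dates at all: absent from the tabulation
  expect_equal(sum(tto$count), 5)
})

test_that("co-reporting fractions count any-role co-medication", {
  units <- tibble::tibble(
    report_id = as.character(1:5),
    pt = c("pjp", "pjp", "pjp", "other", "pjp"),
    is_case = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  drugs <- tibble::tibble(
    report_id = c("1", "2", "4", "5"),
    drug_name = c("dexamethasone", "DEXAMETHASONE ", "dexamethasone", "dexamethasone"),
    role = c("C", "SS", "C", "C"),
    sequence = 2L
  )
  cohort <- make_cohort(
    tibble::tibble(report_id = as.character(1:5), is_case = units$is_case),
    units = units, drugs = drugs
  )
  dex <- drug_synonyms("dexamethasone")
  out <- co_reported_fraction(cohort, "pjp", dex)
  expect_equal(out$n_cases_with_pt, 3) # report 5 has the PT but is not a case
  expect_equal(out$n_with_co_drug, 2)
  expect_equal(out$percentage, 66.7)

  absent <- co_reported_fraction(cohort, "no_such_pt", dex)
  expect_equal(absent$n_cases_with_pt, 0)
  expect_true(is.na(absent$percentage))

  never <- co_reported_fraction(cohort, "pjp", drug_synonyms("warfarin"))
  expect_equal(never$percentage, 0)
})
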