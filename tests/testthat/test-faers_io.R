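test_that("a quarter parses with fields mapped and preserved", {
  dir <- withr::local_tempdir()
  files <- write_tiny_quarter(dir)
  bundle <- read_faers_quarter(files, quarter_label = "2023Q1")
  expect_s3_class(bundle, "faers_bundle")
  expect_equal(nrow(bundle$demo), 2)
  expect_equal(bundle$demo$sex, c("M", "F"))
  expect_equal(bundle$reac$primaryid, c("101", "101", "102"))
  # empty trailing field becomes missing
  expect_true(is.na(bundle$demo$event_dt[2]))

  reports <- assemble_reports(bundle)
  r101 <- dplyr::filter(reports$reports, report_id == "101")
  expect_equal(r101$sex, "male")
  expect_equal(r101$age_years, 55)
  expect_equal(r101$receipt_date, as.Date("2023-01-01"))
})

test_that("a header without the report-ID column is a format error", {
  dir <- withr::local_tempdir()
  bad <- write_faers_file(dir, "demo.txt", "caseid$fda_dt", "9001$20230101")
  expect_error(
    read_faers_quarter(c(demo = bad)),
    "no report-ID column",
    ignore.case = TRUE
  )
})

test_that("column aliases absorb header drift", {
  dir <- withr::local_tempdir()
  old_style <- write_faers_file(
    dir, "demo.txt", "isr$case$fda_dt", "7$70$20100101"
  )
  bundle <- read_faers_quarter(c(demo = old_style))
  expect_equal(bundle$demo$primaryid, "7")
  expect_equal(bundle$demo$caseid, "70")
})

test_that("partial dates resolve to the first day of the period", {
  expect_equal(parse_faers_date("20230215"), as.Date("2023-02-15"))
  expect_equal(parse_faers_date("202302"), as.Date("2023-02-01"))
  expect_equal(parse_faers_date("2023"), as.Date("2023-01-01"))
  expect_true(is.na(parse_faers_date("23-01")))
  expect_true(is.na(parse_faers_date("")))
})

test_that("dedup keeps the latest receipt, breaking ties by report ID", {
  demo <- tibble::tibble(
    primaryid = c("500", "501", "400", "300"),
    caseid = c("9", "9", "9", "8"),
    fda_dt = c("20230101", "20230101", "20230301", "20230101")
  )
  kept <- dedup_reports(demo)
  expect_setequal(kept$primaryid, c("400", "300"))

  # pure tie: larger report ID wins
  tie <- dedup_reports(demo[1:2, ])
  expect_equal(tie$primaryid, "501")
})

test_that("dedup is idempotent, order-independent, and tallies bad records", {
  set.seed(11)
  demo <- tibble::tibble(
    primaryid = as.character(1:60),
    caseid = as.character(sample(1:20, 60, replace = TRUE)),
    fda_dt = format(as.Date("2020-01-01") + sample(0:1000, 60), "%Y%m%d")
  )
  demo$caseid[c(3, 40)] <- c(NA, "")
  once <- dedup_reports(demo)
  twice <- dedup_reports(once)
  expect_equal(once$primaryid, twice$primaryid)
  expect_equal(attr(once, "n_dropped_missing_caseid"), 2)
  expect_lte(nrow(once), nrow(demo))
  expect_equal(anyDuplicated(once$caseid), 0)

  shuffled <- dedup_reports(demo[sample(nrow(demo)), ])
  expect_setequal(once$primaryid, shuffled$primaryid)
})

test_that("indication-matching events are removed, emptying reports if needed", {
  dir <- withr::local_tempdir()
  files <- write_tiny_quarter(dir)
  # 101 gains an event equal to its indication; 102's sole event becomes its indication
  writeLines(
    c("primaryid$pt", "101$nausea", "101$Glioblastoma", "102$nausea"),
    files$reac
  )
  writeLines(
    c("primaryid$indi_pt", "101$glioblastoma", "102$nausea"),
    files$indi
  )
  reports <- assemble_reports(read_faers_quarter(files))
  expect_equal(reports$events$pt, "nausea")
  expect_equal(reports$events$report_id, "101")
  expect_false("102" %in% reports$reports$report_id)
  expect_equal(unname(reports$dropped["indication_overlap_events"]), 2)
  expect_equal(unname(reports$dropped["reports_without_events"]), 1)
})

test_that("case versions across quarters collapse to one report", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  f1 <- write_tiny_quarter(dir1)
  writeLines(
    c(
      "primaryid$caseid$fda_dt$sex",
      "201$9009$20230101$M", "202$9009$20230215$M"
    ),
    f1$demo
  )
  writeLines(c("primaryid$pt", "201$rash", "202$rash"), f1$reac)
  writeLines(c("primaryid$drug_seq$role_cod$drugname", "201$1$PS$x", "202$1$PS$x"), f1$drug)
  writeLines("primaryid$outc_cod", f1$outc)
  writeLines("primaryid$dsg_drug_seq$start_dt", f1$ther)
  writeLines("primaryid$indi_pt", f1$indi)
  f2 <- write_tiny_quarter(dir2)
  writeLines(
    c("primaryid$caseid$fda_dt$sex", "209$9009$20230401$M"),
    f2$demo
  )
  writeLines(c("primaryid$pt", "209$rash"), f2$reac)
  writeLines(c("primaryid$drug_seq$role_cod$drugname", "209$1$PS$x"), f2$drug)
  writeLines("primaryid$outc_cod", f2$outc)
  writeLines("primaryid$dsg_drug_seq$start_dt", f2$ther)
  writeLines("primaryid$indi_pt", f2$indi)

  reports <- assemble_reports(list(
    read_faers_quarter(f1, "2023Q1"), read_faers_quarter(f2, "2023Q2")
  ))
  expect_equal(sum(reports$reports$case_id == "9009"), 1)
  expect_true("209" %in% reports$reports$report_id)
})

test_that("assembled counts plus dropped tallies account for every report", {
  sim <- simulate_faers(sim_config(n_reports = 400, seed = 5, duplicate_rate = 0.15))
  reports <- assemble_reports(sim$bundles)
  expect_equal(nrow(reports$reports), sim$truth$n_reports)
  expect_equal(
    nrow(reports$reports) + unname(reports$dropped["reports_without_events"]),
    sim$truth$n_reports
  )
})
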