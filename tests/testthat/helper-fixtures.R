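# Fixture builders shared across the suite. Everything is constructed in
# code; no stored data files.

# a minimal cohort object built straight from per-report vectors, for tests
# that exercise the summarisers on exactly known counts
make_cohort <- function(reports,
                        units = NULL,
                        drugs = NULL,
                        outcomes = NULL) {
  blank_units <- tibble::tibble(
    report_id = character(), pt = character(), is_case = logical()
  )
  blank_drugs <- tibble::tibble(
    report_id = character(), drug_name = character(), role = character(),
    sequence = integer()
  )
  blank_outcomes <- tibble::tibble(report_id = character(), outcome = character())
  defaults <- list(
    sex = NA_character_, age_years = NA_real_,
    reporter_occupation = NA_character_, reporter_country = NA_character_,
    event_date = as.Date(NA), therapy_start_date = as.Date(NA),
    is_case = TRUE
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(reports)) reports[[nm]] <- defaults[[nm]]
  }
  structure(
    list(
      reports = tibble::as_tibble(reports),
      units = units %||% blank_units,
      drugs = drugs %||% blank_drugs,
      outcomes = outcomes %||% blank_outcomes
    ),
    class = "faers_cohort"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# write a raw FAERS-style table file from a header and record lines
write_faers_file <- function(dir, name, header, lines = character()) {
  path <- file.path(dir, name)
  writeLines(c(header, lines), path)
  path
}

# a tiny two-report quarter on disk: report 101 (target PS, 2 events),
# report 102 (other drug, 1 event)
write_tiny_quarter <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  list(
    demo = write_faers_file(
      dir, "demo.txt",
      "primaryid$caseid$fda_dt$sex$age$age_cod$occp_cod$reporter_country$event_dt",
      c(
        "101$9001$20230101$M$55$YR$MD$US$20230110",
        "102$9002$20230201$F$60$YR$PH$JP$"
      )
    ),
    drug = write_faers_file(
      dir, "drug.txt", "primaryid$drug_seq$role_cod$drugname",
      c("101$1$PS$temozolomide", "102$1$PS$bevacizumab")
    ),
    reac = write_faers_file(
      dir, "reac.txt", "primaryid$pt",
      c("101$nausea", "101$thrombocytopenia", "102$nausea")
    ),
    outc = write_faers_file(
      dir, "outc.txt", "primaryid$outc_cod", c("101$HO", "102$DE")
    ),
    ther = write_faers_file(
      dir, "ther.txt", "primaryid$dsg_drug_seq$start_dt", "101$1$20230105"
    ),
    indi = write_faers_file(
      dir, "indi.txt", "primaryid$indi_pt", "101$glioblastoma"
    )
  )
}

# random well-filled 2x2 tables for oracle-equivalence and property tests
random_tables <- function(n, seed, lambda = c(30, 200, 300, 5000)) {
  set.seed(seed)
  tibble::tibble(
    a = rpois(n, lambda[1]) + 1,
    b = rpois(n, lambda[2]) + 1,
    c = rpois(n, lambda[3]) + 1,
    d = rpois(n, lambda[4]) + 1
  )
}
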