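# Reader for the public FAERS quarterly ASCII dialect: "$"-delimited, one
# header line, no quoting. Each quarter ships six tables keyed by the report
# identifier (primaryid analogue): DEMO, DRUG, REAC, OUTC, THER, INDI.

.faers_tables <- c("demo", "drug", "reac", "outc", "ther", "indi")

# canonical column names per table; the first entry of each alias vector is
# the canonical name used downstream
.faers_aliases <- list(
  demo = list(
    primaryid = c("primaryid", "isr"),
    caseid = c("caseid", "case"),
    fda_dt = c("fda_dt"),
    sex = c("sex", "gndr_cod"),
    age = c("age"),
    age_cod = c("age_cod"),
    occp_cod = c("occp_cod"),
    reporter_country = c("reporter_country", "occr_country"),
    event_dt = c("event_dt")
  ),
  drug = list(
    primaryid = c("primaryid", "isr"),
    drug_seq = c("drug_seq"),
    role_cod = c("role_cod"),
    drugname = c("drugname")
  ),
  reac = list(primaryid = c("primaryid", "isr"), pt = c("pt")),
  outc = list(primaryid = c("primaryid", "isr"), outc_cod = c("outc_cod")),
  ther = list(
    primaryid = c("primaryid", "isr"),
    dsg_drug_seq = c("dsg_drug_seq"),
    start_dt = c("start_dt")
  ),
  indi = list(primaryid = c("primaryid", "isr"), indi_pt = c("indi_pt"))
)

.rename_aliases <- function(df, aliases, table, file) {
  for (canon in names(aliases)) {
    hits <- intersect(aliases[[canon]], names(df))
    if (length(hits) > 0 && !canon %in% names(df)) {
      names(df)[names(df) == hits[[1]]] <- canon
    }
  }
  if (!"primaryid" %in% names(df)) {
    abort(sprintf(
      "FAERS format error in '%s' (%s table): no report-ID column (expected one of: %s)",
      file, table, paste(aliases$primaryid, collapse = ", ")
    ))
  }
  df
}

.read_faers_table <- function(file, table, aliases) {
  df <- readr::read_delim(
    file,
    delim = "$", quote = "", col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), trim_ws = FALSE, progress = FALSE,
    show_col_types = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf(
      "FAERS format error in '%s': unreadable line %d (%s)",
      file, probs$row[[1]], probs$expected[[1]]
    ))
  }
  .rename_aliases(as_tibble(df), aliases[[table]], table, file)
}

#' Read one FAERS-style quarterly bundle
#'
#' Parses the "$"-delimited ASCII tables of a single FAERS quarter into a
#' bundle of raw character tibbles. Fields are kept verbatim (one record per
#' data line, empty fields become `NA`); unknown columns are preserved so
#' nothing the source recorded is lost before cleaning.
#'
#' @param paths Named character vector or list of file paths. Names must be
#'   among `"demo"`, `"drug"`, `"reac"`, `"outc"`, `"ther"`, `"indi"`;
#'   `"demo"` is mandatory, the rest may be absent (treated as empty tables).
#' @param quarter_label Label for the quarter, e.g. `"2023Q1"`.
#' @param aliases Optional list of per-table column-name aliases, merged over
#'   the built-in ones, to absorb historical header drift (e.g. `isr` for
#'   `primaryid` in pre-2012 files).
#' @return A `faers_bundle`: a list with one tibble per table plus
#'   `quarter_label`.
#' @examples
#' dir <- tempfile()
#' cfg <- sim_config(n_reports = 50, seed = 1)
#' sim <- simulate_faers(cfg)
#' files <- write_faers_quarter(sim$bundles[[1]], dir)
#' bundle <- read_faers_quarter(files, quarter_label = sim$bundles[[1]]$quarter_label)
#' nrow(bundle$demo)
#' @export
read_faers_quarter <- function(paths, quarter_label = "unknown", aliases = NULL) {
  paths <- as.list(paths)
  bad <- setdiff(names(paths), .faers_tables)
  if (length(bad) > 0) {
    abort(sprintf("unknown FAERS table name(s): %s", paste(bad, collapse = ", ")))
  }
  if (!"demo" %in% names(paths)) abort("a FAERS quarter needs at least a 'demo' table")
  alias_tbl <- .faers_aliases
  for (tb in names(aliases %||% list())) {
    alias_tbl[[tb]] <- utils::modifyList(alias_tbl[[tb]], aliases[[tb]])
  }
  bundle <- lapply(setNames(.faers_tables, .faers_tables), function(tb) {
    if (is.null(paths[[tb]])) {
      return(tibble(primaryid = character()))
    }
    .read_faers_table(paths[[tb]], tb, alias_tbl)
  })
  bundle$quarter_label <- quarter_label
  structure(bundle, class = "faers_bundle")
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat("<faers_bundle> quarter", x$quarter_label, "\n")
  for (tb in .faers_tables) cat(sprintf("  %s: %d records\n", tb, nrow(x[[tb]])))
  invisible(x)
}

#' Parse FAERS-style dates
#'
#' FAERS dates are `YYYYMMDD` integers, sometimes truncated to `YYYYMM` or
#' `YYYY` when only a partial date was reported. Partial dates resolve to the
#' first day of the period, which biases derived durations conservatively
#' (never shortens a time-to-onset) while keeping them computable.
#'
#' @param x Character vector of raw date fields.
#' @return A `Date` vector; unparseable or empty fields become `NA`.
#' @export
parse_faers_date <- function(x) {
  x <- stringr::str_trim(as.character(x))
  x[!stringr::str_detect(x, "^\\d{4}(\\d{2}(\\d{2})?)?$") | is.na(x)] <- NA_character_
  padded <- dplyr::case_when(
    is.na(x) ~ NA_character_,
    nchar(x) == 4 ~ paste0(x, "0101"),
    nchar(x) == 6 ~ paste0(x, "01"),
    TRUE ~ x
  )
  # raw files repeat a few hundred distinct dates across many records;
  # converting unique values keeps large loads fast
  ud <- unique(padded)
  as.Date(ud, format = "%Y%m%d")[match(padded, ud)]
}

#' Deduplicate FAERS case versions
#'
#' FAERS redistributes an amended safety report as a new version under the
#' same case ID, so the raw files hold several versions of many cases. The
#' FDA's recommended rule is applied: for each case keep the version with the
#' latest receipt date, breaking ties by the largest report ID. Records with
#' a missing case ID cannot be versioned and are dropped (tallied, never
#' silent). The rule is deterministic, idempotent and independent of input
#' order.
#'
#' @param demo A data frame of raw DEMO records (possibly several quarters
#'   bound together) with columns `primaryid`, `caseid`, `fda_dt`.
#' @return A tibble with the retained DEMO records, one per case, carrying an
#'   attribute `n_dropped_missing_caseid`.
#' @examples
#' demo <- tibble::tibble(
#'   primaryid = c("500", "501", "700"),
#'   caseid = c("9", "9", "8"),
#'   fda_dt = c("20230101", "20230101", "20230301")
#' )
#' dedup_reports(demo) # keeps 501 (tie on date, larger ID) and 700
#' @export
dedup_reports <- function(demo) {
  demo <- as_tibble(demo)
  missing_case <- is.na(demo$caseid) | stringr::str_trim(demo$caseid) == ""
  kept <- demo[!missing_case, , drop = FALSE]
  ord_date <- parse_faers_date(kept$fda_dt)
  # numeric report-ID ordering where possible (FAERS primaryids are numeric)
  ord_id <- suppressWarnings(as.numeric(kept$primaryid))
  if (anyNA(ord_id)) ord_id <- xtfrm(kept$primaryid)
  out <- kept |>
    mutate(.date = ord_date, .id = ord_id) |>
    arrange(.data$caseid, desc(.data$.date), desc(.data$.id)) |>
    distinct(.data$caseid, .keep_all = TRUE) |>
    select(-".date", -".id")
  attr(out, "n_dropped_missing_caseid") <- sum(missing_case)
  out
}

.sex_levels <- c(F = "female", M = "male")
.age_to_years <- c(
  YR = 1, MON = 1 / 12, WK = 1 / 52, DY = 1 / 365.25, DEC = 10, HR = 1 / 8766
)
.role_codes <- c("PS", "SS", "C", "I")
.outcome_codes <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

.norm_term <- function(x) stringr::str_to_lower(stringr::str_trim(x))

#' Assemble deduplicated safety reports from quarterly bundles
#'
#' Joins DEMO, DRUG, REAC, OUTC and THER records across one or more quarters
#' into cleaned per-report tables. Deduplication (see [dedup_reports()]) is
#' applied jointly across all quarters first, since an amended case can recur
#' in a later quarter; then the remaining tables are joined on the retained
#' report IDs. Cleaning removes empty/whitespace event terms, drops any event
#' PT that exactly equals (case-insensitively, after trimming) an indication
#' PT recorded for the same report — an adverse event identical to the reason
#' for treatment is taken to be the disease, not a reaction — and finally
#' drops reports left with no event. Demographic blanks are kept as
#' `"unknown"` levels rather than dropped. Every removal is tallied.
#'
#' @param bundles A `faers_bundle` or list of them.
#' @return A `faers_reports` object: a list of tibbles `reports` (one row per
#'   retained report: `report_id`, `case_id`, `receipt_date`, `sex`,
#'   `age_years`, `reporter_occupation`, `reporter_country`, `event_date`,
#'   `therapy_start_date`), `drugs` (`report_id`, `drug_name`, `role`,
#'   `sequence`), `events` (`report_id`, `pt`; distinct pairs), `outcomes`
#'   (`report_id`, `outcome`), plus a named integer vector `dropped` of
#'   removal tallies.
#' @export
assemble_reports <- function(bundles) {
  if (inherits(bundles, "faers_bundle")) bundles <- list(bundles)
  pull_tab <- function(tb) {
    purrr::map(bundles, function(b) b[[tb]]) |> purrr::list_rbind()
  }
  demo <- pull_tab("demo")
  if (nrow(demo) == 0) abort("no DEMO records in the supplied bundles")
  drug <- pull_tab("drug")
  reac <- pull_tab("reac")
  outc <- pull_tab("outc")
  ther <- pull_tab("ther")
  indi <- pull_tab("indi")

  kept <- dedup_reports(demo)
  n_versions_removed <- nrow(demo) - nrow(kept) -
    attr(kept, "n_dropped_missing_caseid")
  ids <- kept$primaryid

  col_or_na <- function(df, col) if (col %in% names(df)) df[[col]] else NA_character_
  ensure_cols <- function(df, cols) {
    for (cl in setdiff(cols, names(df))) df[[cl]] <- NA_character_
    df
  }
  drug <- ensure_cols(drug, c("drugname", "role_cod", "drug_seq"))
  reac <- ensure_cols(reac, "pt")
  outc <- ensure_cols(outc, "outc_cod")
  ther <- ensure_cols(ther, "start_dt")

  reports <- tibble(
    report_id = kept$primaryid,
    case_id = kept$caseid,
    receipt_date = parse_faers_date(kept$fda_dt),
    sex = unname(.sex_levels[stringr::str_trim(col_or_na(kept, "sex"))]) |>
      dplyr::coalesce("unknown"),
    age_years = suppressWarnings(as.numeric(col_or_na(kept, "age"))) *
      unname(dplyr::coalesce(
        .age_to_years[stringr::str_trim(col_or_na(kept, "age_cod"))], 1
      )),
    reporter_occupation = dplyr::na_if(stringr::str_trim(col_or_na(kept, "occp_cod")), ""),
    reporter_country = dplyr::na_if(stringr::str_trim(col_or_na(kept, "reporter_country")), ""),
    event_date = parse_faers_date(col_or_na(kept, "event_dt"))
  )

  # orphans reference an ID never seen in DEMO at all; records belonging to
  # removed duplicate versions are dropped silently as part of dedup
  all_ids <- unique(demo$primaryid)
  orphan <- function(df) sum(!df$primaryid %in% all_ids)
  n_orphans <- orphan(drug) + orphan(reac) + orphan(outc) + orphan(ther)
  if (n_orphans > 0) {
    warn(sprintf("%d records reference report IDs absent from DEMO; skipped", n_orphans))
  }

  drugs <- drug |>
    filter(.data$primaryid %in% ids) |>
    transmute(
      report_id = .data$primaryid,
      drug_name = stringr::str_trim(.data$drugname),
      role = ifelse(.data$role_cod %in% .role_codes, .data$role_cod, NA_character_),
      sequence = suppressWarnings(as.integer(.data$drug_seq))
    )

  events <- reac |>
    filter(.data$primaryid %in% ids) |>
    transmute(report_id = .data$primaryid, pt = stringr::str_trim(.data$pt))
  n_blank_pt <- sum(is.na(events$pt) | events$pt == "")
  events <- events |>
    filter(!is.na(.data$pt), .data$pt != "") |>
    distinct(.data$report_id, .data$pt)

  # indication-overlap filter: an event PT equal to an indication PT recorded
  # for the same report is removed
  n_indication_overlap <- 0L
  if (nrow(indi) > 0 && "indi_pt" %in% names(indi)) {
    ind <- indi |>
      filter(.data$primaryid %in% ids) |>
      transmute(report_id = .data$primaryid, ind_pt = .norm_term(.data$indi_pt)) |>
      filter(!is.na(.data$ind_pt), .data$ind_pt != "") |>
      distinct()
    overlap <- events |>
      mutate(.pt_norm = .norm_term(.data$pt)) |>
      semi_join(ind, by = c(report_id = "report_id", .pt_norm = "ind_pt"))
    n_indication_overlap <- nrow(overlap)
    events <- anti_join(
      events |> mutate(.pt_norm = .norm_term(.data$pt)),
      ind,
      by = c(report_id = "report_id", .pt_norm = "ind_pt")
    ) |> select(-".pt_norm")
  }

  outcomes <- outc |>
    filter(.data$primaryid %in% ids) |>
    transmute(report_id = .data$primaryid, outcome = stringr::str_trim(.data$outc_cod)) |>
    filter(!is.na(.data$outcome), .data$outcome != "")

  # earliest therapy start per report; arrange + distinct avoids a slow
  # per-group min over Date objects
  ther_start <- ther |>
    filter(.data$primaryid %in% ids) |>
    mutate(start = parse_faers_date(.data$start_dt)) |>
    filter(!is.na(.data$start)) |>
    arrange(.data$primaryid, .data$start) |>
    distinct(.data$primaryid, .keep_all = TRUE) |>
    transmute(report_id = .data$primaryid, therapy_start_date = .data$start)
  reports <- left_join(reports, ther_start, by = "report_id")
  if (!"therapy_start_date" %in% names(reports)) {
    reports$therapy_start_date <- as.Date(NA)
  }

  with_events <- unique(events$report_id)
  n_no_events <- sum(!reports$report_id %in% with_events)
  reports <- filter(reports, .data$report_id %in% with_events)
  drugs <- filter(drugs, .data$report_id %in% with_events)
  outcomes <- filter(outcomes, .data$report_id %in% with_events)

  structure(
    list(
      reports = reports, drugs = drugs, events = events, outcomes = outcomes,
      dropped = c(
        missing_caseid = attr(kept, "n_dropped_missing_caseid"),
        duplicate_versions = n_versions_removed,
        orphan_records = n_orphans,
        blank_event_terms = n_blank_pt,
        indication_overlap_events = n_indication_overlap,
        reports_without_events = n_no_events
      )
    ),
    class = "faers_reports"
  )
}

#' @export
print.faers_reports <- function(x, ...) {
  cat(
    "<faers_reports>", nrow(x$reports), "deduplicated reports,",
    nrow(x$events), "report-event units\n"
  )
  d <- x$dropped[x$dropped > 0]
  if (length(d) > 0) {
    cat("  dropped:", paste(names(d), d, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
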