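# Case/non-case construction and the descriptive cohort summaries. A "case"
# is a deduplicated report whose primary-suspect (PS) drug matches the target
# synonym set; every other report is a non-case. All disproportionality
# statistics downstream are computed over this split.

#' Flag case reports and enumerate analysis units
#'
#' A report is a *case* when at least one of its drugs has role `PS`
#' (primary suspect) and a name matching the target synonym set. Drugs in
#' other roles (`SS`, `C`, `I`) never make a report a case: co-suspect or
#' concomitant exposure is not the exposure under study. Analysis units are
#' the distinct (report, PT) pairs, so a report reporting the same PT twice
#' contributes one unit.
#'
#' @param reports A `faers_reports` object from [assemble_reports()].
#' @param synonyms A [drug_synonyms()] object for the target drug.
#' @return A `faers_cohort`: list of tibbles `reports` (per-report fields
#'   plus `is_case`), `units` (`report_id`, `pt`, `is_case`), `drugs`,
#'   `outcomes`.
#' @export
flag_cases <- function(reports, synonyms) {
  stopifnot(inherits(reports, "faers_reports"))
  case_ids <- reports$drugs |>
    filter(.data$role == "PS", is_target_drug(.data$drug_name, synonyms)) |>
    pull(.data$report_id) |>
    unique()
  rep_tbl <- reports$reports |> mutate(is_case = .data$report_id %in% case_ids)
  units <- reports$events |>
    distinct(.data$report_id, .data$pt) |>
    mutate(is_case = .data$report_id %in% case_ids)
  structure(
    list(
      reports = rep_tbl, units = units,
      drugs = reports$drugs, outcomes = reports$outcomes
    ),
    class = "faers_cohort"
  )
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat(
    "<faers_cohort>", sum(x$reports$is_case), "case /",
    sum(!x$reports$is_case), "non-case reports,", nrow(x$units), "units\n"
  )
  invisible(x)
}

.pct <- function(count, denom, digits = 2) {
  if (denom == 0) {
    return(rep(NA_real_, length(count)))
  }
  round(100 * count / denom, digits)
}

.summary_block <- function(category, level_vec, level_order) {
  counts <- table(factor(level_vec, levels = level_order))
  tibble(
    category = category,
    level = names(counts),
    count = as.integer(counts),
    percentage = .pct(as.integer(counts), sum(counts))
  )
}

.age_breaks <- c(0, 18, 45, 65, 75, Inf)
.age_labels <- c("<18", "18-45", "45-65", "65-75", ">=75")

#' Demographic summary of case reports
#'
#' Tabulates sex, age group, reporter occupation and reporter country over
#' the case reports. Unknown values form their own level and stay in the
#' denominator (the number of case reports), so each category's counts sum
#' to that denominator and its percentages to 100 up to rounding. Age groups
#' are half-open on the left edge (`[45, 65)` contains 45) after converting
#' all reported units to years.
#'
#' @param cohort A `faers_cohort` from [flag_cases()].
#' @return A tibble with columns `category`, `level`, `count`, `percentage`
#'   (percent of case reports, 2 decimals).
#' @export
summarize_demographics <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cohort"))
  cases <- filter(cohort$reports, .data$is_case)
  age_grp <- cut(cases$age_years,
    breaks = .age_breaks, labels = .age_labels,
    right = FALSE, include.lowest = TRUE
  )
  bind_rows(
    .summary_block(
      "sex", dplyr::coalesce(cases$sex, "unknown"),
      c("female", "male", "unknown")
    ),
    .summary_block(
      "age", dplyr::coalesce(as.character(age_grp), "unknown"),
      c(.age_labels, "unknown")
    ),
    .summary_block(
      "reporter", dplyr::coalesce(cases$reporter_occupation, "unknown"),
      unique(c(sort(unique(cases$reporter_occupation)), "unknown"))
    ),
    .summary_block(
      "country", dplyr::coalesce(cases$reporter_country, "unknown"),
      unique(c(sort(unique(cases$reporter_country)), "unknown"))
    )
  )
}

.outcome_priority <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Outcome summary of case reports
#'
#' Each case report contributes one outcome, selected by the conventional
#' seriousness ranking death > life-threatening > hospitalisation >
#' disability > congenital anomaly > required intervention > other
#' (`DE > LT > HO > DS > CA > RI > OT`), so a report recorded as both
#' hospitalised and dead counts once, as a death. The denominator is the
#' number of case reports carrying at least one recognised outcome code;
#' reports with none are omitted rather than diluting the percentages.
#' Unrecognised codes are ignored with a tally in attribute
#' `n_unknown_codes`.
#'
#' @param cohort A `faers_cohort` from [flag_cases()].
#' @return A tibble (`category = "outcome"`, `level`, `count`, `percentage`)
#'   ordered by descending count.
#' @export
summarize_outcomes <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cohort"))
  case_ids <- cohort$reports$report_id[cohort$reports$is_case]
  oc <- filter(cohort$outcomes, .data$report_id %in% case_ids)
  n_unknown <- sum(!oc$outcome %in% .outcome_priority)
  if (n_unknown > 0) warn(sprintf("%d unrecognised outcome codes ignored", n_unknown))
  oc <- filter(oc, .data$outcome %in% .outcome_priority)
  worst <- if (nrow(oc) == 0) {
    tibble(report_id = character(), outcome = character())
  } else {
    oc |>
      mutate(rank = match(.data$outcome, .outcome_priority)) |>
      group_by(.data$report_id) |>
      summarise(outcome = .outcome_priority[min(.data$rank)], .groups = "drop")
  }
  counts <- table(factor(worst$outcome, levels = .outcome_priority))
  out <- tibble(
    category = "outcome",
    level = names(counts),
    count = as.integer(counts),
    percentage = .pct(as.integer(counts), sum(counts))
  ) |> arrange(desc(.data$count))
  attr(out, "n_unknown_codes") <- n_unknown
  out
}

.tto_breaks <- c(0, 7, 28, 60, Inf)
.tto_labels <- c("<7", "7-28", "28-60", ">=60")

#' Time-to-onset summary of case reports
#'
#' Time to onset (TTO) is the whole-day difference between the event date
#' and the earliest therapy start date, binned `[0,7)`, `[7,28)`, `[28,60)`,
#' `[60, Inf)` days. A report with partial time information — exactly one of
#' the two dates, or a negative difference (an event predating therapy
#' points to a data error) — falls in the `unknown` level; a report with
#' neither date carries no time information at all and is excluded from the
#' tabulation entirely. Percentages are over the tabulated reports (binned
#' plus unknown).
#'
#' @param cohort A `faers_cohort` from [flag_cases()].
#' @return A tibble (`category = "tto"`, `level`, `count`, `percentage`).
#' @export
summarize_tto <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cohort"))
  cases <- filter(cohort$reports, .data$is_case)
  tto <- as.numeric(cases$event_date - cases$therapy_start_date)
  has_any <- !is.na(cases$event_date) | !is.na(cases$therapy_start_date)
  known <- !is.na(tto) & tto >= 0
  lvl <- rep(NA_character_, nrow(cases))
  lvl[has_any & !known] <- "unknown"
  lvl[known] <- as.character(
    cut(tto[known], breaks = .tto_breaks, labels = .tto_labels, right = FALSE)
  )
  .summary_block("tto", lvl[!is.na(lvl)], c(.tto_labels, "unknown"))
}

#' Co-reporting fraction of a drug among cases with a given event
#'
#' Among the case reports that contain the given PT, counts how many also
#' list a drug (in any role) matching the co-medication synonym set — e.g.
#' concurrent dexamethasone among Pneumocystis pneumonia cases. The
#' co-medication need not be suspect: the question is concurrent exposure,
#' not suspicion.
#'
#' @param cohort A `faers_cohort` from [flag_cases()].
#' @param pt The event PT of interest (matched case-insensitively).
#' @param co_drug A [drug_synonyms()] object for the co-reported drug.
#' @return A one-row tibble: `pt`, `n_cases_with_pt`, `n_with_co_drug`,
#'   `percentage` (1 decimal; `NA` when no case carries the PT).
#' @export
co_reported_fraction <- function(cohort, pt, co_drug) {
  stopifnot(inherits(cohort, "faers_cohort"))
  with_pt <- cohort$units |>
    filter(.data$is_case, .norm_term(.data$pt) == .norm_term(!!pt)) |>
    pull(.data$report_id) |>
    unique()
  if (length(with_pt) == 0) {
    return(tibble(
      pt = pt, n_cases_with_pt = 0L, n_with_co_drug = 0L, percentage = NA_real_
    ))
  }
  with_co <- cohort$drugs |>
    filter(.data$report_id %in% with_pt, is_target_drug(.data$drug_name, co_drug)) |>
    pull(.data$report_id) |>
    unique()
  tibble(
    pt = pt,
    n_cases_with_pt = length(with_pt),
    n_with_co_drug = length(with_co),
    percentage = round(100 * length(with_co) / length(with_pt), 1)
  )
}
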