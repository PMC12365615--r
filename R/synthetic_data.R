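# Synthetic FAERS-like report generator with known ground truth. Every
# stage of the pipeline — parsing, deduplication, case flagging,
# disproportionality — can be exercised end to end without the real
# download, and planted reporting-rate multipliers give an exact oracle for
# parameter-recovery and null-calibration checks.
#
# Event model: each report carries each PT independently with a Zipf-skewed
# baseline probability (heavy-tailed PT frequencies, as in real spontaneous
# data); a planted multiplier for (drug, pt) multiplies the *odds* of that
# PT on reports whose primary-suspect drug matches, so the report-level odds
# ratio — the estimand of the ROR — equals the multiplier exactly. Reports
# that draw no event at all are discarded: a spontaneous report without a
# reaction does not exist.

#' Configuration for the synthetic report generator
#'
#' @param n_reports Number of reports to draw (those drawing zero events are
#'   discarded; the truth record holds the retained count).
#' @param n_drugs Number of distinct drugs; the first (`drug_01`) is the
#'   target and is the only primary-suspect drug carrying planted
#'   multipliers.
#' @param n_pts Number of distinct event PTs (`pt_0001`, ...).
#' @param n_socs Number of SOCs the PTs map onto (round-robin).
#' @param target_drug_share Probability a report's primary-suspect drug is
#'   the target.
#' @param events_per_report Mean number of PT presences per report before
#'   the zero-event discard (the Zipf baseline probabilities are scaled to
#'   sum to this).
#' @param rate_multipliers Optional tibble with columns `drug`, `pt`,
#'   `multiplier` (> 0): planted odds multipliers for PTs on reports whose
#'   PS drug matches.
#' @param duplicate_rate Probability a report additionally emits an earlier
#'   case version (same case ID, smaller report ID, earlier receipt date).
#' @param missingness Named list of per-field missingness probabilities:
#'   `sex`, `age`, `country`, `occupation`, `event_date`, `therapy_date`.
#' @param outcome_probs Named probabilities over
#'   `DE, LT, HO, DS, CA, RI, OT, none` for the report's primary outcome.
#' @param concomitant_rate Probability a report lists one extra
#'   non-primary-suspect drug.
#' @param indication_rate Probability a report carries an indication record
#'   (drawn from a dedicated indication vocabulary disjoint from the event
#'   PTs, so the indication-overlap filter is exercised without perturbing
#'   planted counts).
#' @param tto_meanlog,tto_sdlog Log-normal parameters of the time to onset
#'   in days.
#' @param n_quarters Number of quarterly bundles the reports are spread
#'   over.
#' @param start_year First calendar year of the simulated quarters.
#' @param seed Integer seed; fully determines the output.
#' @return A `faers_sim_config` object.
#' @export
sim_config <- function(n_reports = 5000,
                       n_drugs = 10,
                       n_pts = 30,
                       n_socs = 8,
                       target_drug_share = 0.1,
                       events_per_report = 2,
                       rate_multipliers = NULL,
                       duplicate_rate = 0,
                       missingness = list(),
                       outcome_probs = c(
                         DE = 0.10, LT = 0.03, HO = 0.20, DS = 0.02,
                         CA = 0.005, RI = 0.005, OT = 0.24, none = 0.40
                       ),
                       concomitant_rate = 0.3,
                       indication_rate = 0.05,
                       tto_meanlog = 3.2,
                       tto_sdlog = 1.1,
                       n_quarters = 4,
                       start_year = 2023,
                       seed = 1L) {
  miss_default <- list(
    sex = 0.02, age = 0.15, country = 0.05, occupation = 0.10,
    event_date = 0.25, therapy_date = 0.25
  )
  missingness <- utils::modifyList(miss_default, missingness)
  probs <- unlist(missingness)
  if (any(probs < 0 | probs > 1)) abort("missingness probabilities must lie in [0, 1]")
  if (target_drug_share < 0 || target_drug_share > 1) {
    abort("target_drug_share must lie in [0, 1]")
  }
  if (abs(sum(outcome_probs) - 1) > 1e-8) abort("outcome_probs must sum to 1")
  zipf <- (1 / seq_len(n_pts)) / sum(1 / seq_len(n_pts))
  base_p <- events_per_report * zipf
  if (any(base_p >= 1)) {
    abort(paste0(
      "infeasible config: events_per_report * max Zipf weight = ",
      signif(max(base_p), 3), " >= 1; reduce events_per_report or raise n_pts"
    ))
  }
  if (!is.null(rate_multipliers)) {
    rate_multipliers <- as_tibble(rate_multipliers)
    if (!all(c("drug", "pt", "multiplier") %in% names(rate_multipliers))) {
      abort("rate_multipliers needs columns drug, pt, multiplier")
    }
    if (any(rate_multipliers$multiplier <= 0)) abort("multipliers must be positive")
  }
  structure(
    list(
      n_reports = n_reports, n_drugs = n_drugs, n_pts = n_pts, n_socs = n_socs,
      target_drug_share = target_drug_share,
      events_per_report = events_per_report,
      base_pt_prob = base_p,
      rate_multipliers = rate_multipliers,
      duplicate_rate = duplicate_rate, missingness = missingness,
      outcome_probs = outcome_probs, concomitant_rate = concomitant_rate,
      indication_rate = indication_rate,
      tto_meanlog = tto_meanlog, tto_sdlog = tto_sdlog,
      n_quarters = n_quarters, start_year = start_year,
      seed = as.integer(seed)
    ),
    class = "faers_sim_config"
  )
}

.sim_drug_names <- function(n) sprintf("drug_%02d", seq_len(n))
.sim_pt_names <- function(n) sprintf("pt_%04d", seq_len(n))

.quarter_bounds <- function(year, q) {
  start <- as.Date(sprintf("%d-%02d-01", year, (q - 1) * 3 + 1))
  end <- seq(start, by = "3 months", length.out = 2)[2] - 1
  c(start, end)
}

.miss <- function(x, p) {
  x[runif(length(x)) < p] <- NA
  x
}

#' Generate synthetic FAERS-like quarterly bundles
#'
#' Draws `n_reports` independent reports under the configured event model,
#' splits them into quarterly bundles in the raw-table dialect read by
#' [read_faers_quarter()], and returns the ground truth alongside: the
#' planted multiplier map, exact pre-duplication report and per-PT case/
#' non-case counts, and the synthetic vocabulary (target-drug synonyms and
#' PT-to-SOC map) matching the generated names.
#'
#' @param config A [sim_config()].
#' @return A `faers_sim`: list with `bundles` (list of `faers_bundle`),
#'   `truth` (list: `n_reports`, `n_case_reports`, `pt_counts` tibble of
#'   exact per-PT case/non-case report counts, `multipliers`), `synonyms`
#'   ([drug_synonyms()] for the target) and `pt_soc` ([pt_soc_map()]).
#' @examples
#' sim <- simulate_faers(sim_config(n_reports = 200, seed = 42))
#' sim$truth$n_case_reports
#' @export
simulate_faers <- function(config) {
  stopifnot(inherits(config, "faers_sim_config"))
  set.seed(config$seed)
  n0 <- config$n_reports
  drugs <- .sim_drug_names(config$n_drugs)
  pts <- .sim_pt_names(config$n_pts)
  target <- drugs[[1]]

  # primary-suspect drug per report
  is_target <- runif(n0) < config$target_drug_share
  ps_drug <- ifelse(
    is_target, target,
    if (config$n_drugs > 1) sample(drugs[-1], n0, replace = TRUE) else target
  )

  # PT presence: baseline probabilities, multiplier-scaled odds where planted
  P <- matrix(config$base_pt_prob, nrow = n0, ncol = config$n_pts, byrow = TRUE)
  if (!is.null(config$rate_multipliers)) {
    for (i in seq_len(nrow(config$rate_multipliers))) {
      rm_i <- config$rate_multipliers[i, ]
      k <- match(rm_i$pt, pts)
      if (is.na(k)) abort(sprintf("multiplier names unknown pt '%s'", rm_i$pt))
      rows <- ps_drug == rm_i$drug
      p0 <- config$base_pt_prob[k]
      odds <- rm_i$multiplier * p0 / (1 - p0)
      P[rows, k] <- odds / (1 + odds)
    }
  }
  present <- matrix(runif(n0 * config$n_pts), nrow = n0) < P
  keep <- rowSums(present) > 0
  n <- sum(keep)
  present <- present[keep, , drop = FALSE]
  ps_drug <- ps_drug[keep]
  is_target <- is_target[keep]

  report_id <- as.character(100000L + seq_len(n))
  case_id <- as.character(500000L + seq_len(n))

  # demographics
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.47, 0.53))
  sex <- .miss(sex, config$missingness$sex)
  age <- pmax(round(rnorm(n, mean = 57, sd = 18)), 0)
  age <- .miss(age, config$missingness$age)
  occp <- sample(c("MD", "PH", "OT", "CN", "RN"), n,
    replace = TRUE, prob = c(0.32, 0.28, 0.20, 0.15, 0.05)
  )
  occp <- .miss(occp, config$missingness$occupation)
  country <- sample(c("US", "JP", "CA", "FR", "DE", "GB", "IT", "ES"), n,
    replace = TRUE, prob = c(0.5, 0.1, 0.08, 0.08, 0.07, 0.07, 0.05, 0.05)
  )
  country <- .miss(country, config$missingness$country)

  # dates: therapy start inside an assigned quarter, event after a
  # log-normal time to onset, receipt shortly after the event
  quarter_idx <- sample.int(config$n_quarters, n, replace = TRUE)
  q_year <- config$start_year + (quarter_idx - 1) %/% 4
  q_num <- (quarter_idx - 1) %% 4 + 1
  q_start <- as.Date(sprintf("%d-%02d-01", q_year, (q_num - 1) * 3 + 1))
  ther_start <- q_start + sample.int(28, n, replace = TRUE) - 1
  tto_days <- round(rlnorm(n, config$tto_meanlog, config$tto_sdlog))
  event_dt <- ther_start + tto_days
  fda_dt <- event_dt + sample.int(30, n, replace = TRUE)
  fmt <- function(d) format(d, "%Y%m%d")
  ther_chr <- .miss(fmt(ther_start), config$missingness$therapy_date)
  event_chr <- .miss(fmt(event_dt), config$missingness$event_date)

  demo <- tibble(
    primaryid = report_id, caseid = case_id, fda_dt = fmt(fda_dt),
    sex = sex, age = as.character(age), age_cod = ifelse(is.na(age), NA, "YR"),
    occp_cod = occp, reporter_country = country, event_dt = event_chr
  )

  # drugs: the PS drug plus an optional concomitant
  drug_rows <- tibble(
    primaryid = report_id, drug_seq = "1", role_cod = "PS", drugname = ps_drug
  )
  has_conc <- runif(n) < config$concomitant_rate
  if (any(has_conc)) {
    conc <- tibble(
      primaryid = report_id[has_conc],
      drug_seq = "2",
      role_cod = sample(c("SS", "C", "I"), sum(has_conc),
        replace = TRUE, prob = c(0.3, 0.6, 0.1)
      ),
      drugname = sample(drugs, sum(has_conc), replace = TRUE)
    )
    drug_rows <- bind_rows(drug_rows, conc)
  }

  idx <- which(present, arr.ind = TRUE)
  reac <- tibble(
    primaryid = report_id[idx[, 1]],
    pt = pts[idx[, 2]]
  ) |> arrange(.data$primaryid, .data$pt)

  # outcomes: primary outcome per report (possibly none)
  oc_draw <- sample(names(config$outcome_probs), n,
    replace = TRUE, prob = config$outcome_probs
  )
  outc <- tibble(primaryid = report_id, outc_cod = oc_draw) |>
    filter(.data$outc_cod != "none")

  ther <- tibble(
    primaryid = report_id, dsg_drug_seq = "1", start_dt = ther_chr
  ) |> filter(!is.na(.data$start_dt))

  has_indi <- runif(n) < config$indication_rate
  indi <- tibble(
    primaryid = report_id[has_indi],
    indi_pt = sample(sprintf("indication_%02d", 1:5), sum(has_indi), replace = TRUE)
  )

  # duplicate case versions: an earlier receipt under the same case ID
  dup <- runif(n) < config$duplicate_rate
  if (any(dup)) {
    old_id <- as.character(as.integer(report_id[dup]) - 90000L)
    demo_old <- demo[dup, ] |>
      mutate(
        primaryid = old_id,
        fda_dt = fmt(parse_faers_date(.data$fda_dt) - sample.int(180, sum(dup), replace = TRUE) - 30)
      )
    demo <- bind_rows(demo, demo_old)
    remap <- setNames(old_id, report_id[dup])
    dup_tab <- function(tb) {
      old <- tb[tb$primaryid %in% report_id[dup], , drop = FALSE]
      old$primaryid <- unname(remap[old$primaryid])
      bind_rows(tb, old)
    }
    drug_rows <- dup_tab(drug_rows)
    reac <- dup_tab(reac)
    outc <- dup_tab(outc)
    ther <- dup_tab(ther)
  }

  # split into quarterly bundles by the retained report's assigned quarter;
  # duplicate versions travel with their case's quarter
  q_label <- sprintf("%dQ%d", q_year, q_num)
  id_quarter <- setNames(q_label, report_id)
  assign_q <- function(tb) {
    base_id <- ifelse(tb$primaryid %in% report_id, tb$primaryid,
      as.character(as.integer(tb$primaryid) + 90000L)
    )
    unname(id_quarter[base_id])
  }
  labels <- sort(unique(q_label))
  bundles <- lapply(labels, function(lab) {
    b <- list(
      demo = demo[assign_q(demo) == lab, , drop = FALSE],
      drug = drug_rows[assign_q(drug_rows) == lab, , drop = FALSE],
      reac = reac[assign_q(reac) == lab, , drop = FALSE],
      outc = outc[assign_q(outc) == lab, , drop = FALSE],
      ther = ther[assign_q(ther) == lab, , drop = FALSE],
      indi = indi[assign_q(indi) == lab, , drop = FALSE],
      quarter_label = lab
    )
    structure(b, class = "faers_bundle")
  })

  pt_counts <- tibble(
    pt = pts,
    a = colSums(present[is_target, , drop = FALSE]),
    c = colSums(present[!is_target, , drop = FALSE])
  )
  soc_map <- pt_soc_map(
    tibble(
      pt = pts,
      soc = sprintf("soc_%02d", (seq_len(config$n_pts) - 1) %% config$n_socs + 1)
    ),
    version_label = "synthetic"
  )

  structure(
    list(
      bundles = bundles,
      truth = list(
        n_reports = n,
        n_case_reports = sum(is_target),
        pt_counts = pt_counts,
        multipliers = config$rate_multipliers,
        base_pt_prob = setNames(config$base_pt_prob, pts)
      ),
      synonyms = drug_synonyms(target),
      pt_soc = soc_map,
      config = config
    ),
    class = "faers_sim"
  )
}

#' @export
print.faers_sim <- function(x, ...) {
  cat(
    "<faers_sim>", x$truth$n_reports, "reports (",
    x$truth$n_case_reports, "target-drug ) across",
    length(x$bundles), "quarterly bundles\n"
  )
  invisible(x)
}

#' Write a bundle in the FAERS quarterly ASCII dialect
#'
#' Emits one "$"-delimited file per table (header line plus one line per
#' record, empty string for missing fields) into `directory`. Output is
#' byte-stable for a fixed bundle, so a fixed-seed simulation writes
#' identical files across runs.
#'
#' @param bundle A `faers_bundle`.
#' @param directory Output directory (created if absent).
#' @return Named character vector of the file paths, invisibly usable as
#'   the `paths` argument of [read_faers_quarter()].
#' @export
write_faers_quarter <- function(bundle, directory) {
  stopifnot(inherits(bundle, "faers_bundle"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tb in .faers_tables) {
    path <- file.path(directory, paste0(tb, ".txt"))
    readr::write_delim(bundle[[tb]], path, delim = "$", na = "")
    paths[tb] <- path
  }
  paths
}
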