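# One-command orchestration: parse -> dedup -> assemble -> flag -> tables ->
# statistics -> criteria -> summaries -> exports. Everything configurable is
# carried in one declarative config object so a run is reproducible from its
# config plus its inputs, and the run log records every active setting.

#' Pipeline run configuration
#'
#' @param input_dir Directory holding one subdirectory per quarter, each
#'   with the "$"-delimited tables (`demo.txt`, `drug.txt`, ...).
#' @param synonym_file One-column text file of target-drug spellings (first
#'   line canonical).
#' @param pt_soc_file Two-column TSV (`pt`, `soc`) mapping PTs to SOCs.
#' @param output_dir Where the TSV outputs and run log are written.
#' @param min_a,min_ror,ci_threshold,min_prr,min_chisq,min_ic Signal
#'   thresholds, defaulting to the conventional criteria (3, 2, 1, 2, 4, 0);
#'   see [evaluate_criteria()].
#' @param zero_cell `"none"` (infinite estimates excluded from ranked
#'   output) or `"haldane"` (+0.5 continuity correction).
#' @param counting Margin convention for [contingency_tables()].
#' @return A `faers_pipeline_config` object.
#' @export
pipeline_config <- function(input_dir, synonym_file, pt_soc_file, output_dir,
                            min_a = 3, min_ror = 2, ci_threshold = 1,
                            min_prr = 2, min_chisq = 4, min_ic = 0,
                            zero_cell = c("none", "haldane"),
                            counting = c("report", "unit")) {
  cfg <- list(
    input_dir = input_dir, synonym_file = synonym_file,
    pt_soc_file = pt_soc_file, output_dir = output_dir,
    min_a = min_a, min_ror = min_ror, ci_threshold = ci_threshold,
    min_prr = min_prr, min_chisq = min_chisq, min_ic = min_ic,
    zero_cell = match.arg(zero_cell), counting = match.arg(counting)
  )
  structure(cfg, class = "faers_pipeline_config")
}

.read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found", path))
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading a YAML config needs the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  needed <- c("input_dir", "synonym_file", "pt_soc_file", "output_dir")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("config is missing: %s", paste(missing, collapse = ", ")))
  }
  do.call(pipeline_config, raw)
}

.log_line <- function(con, ...) {
  writeLines(paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...)), con)
}

#' Run the full signal-detection pipeline
#'
#' Reads every quarter under `input_dir`, deduplicates and assembles the
#' reports, flags the case/non-case split, computes the four
#' disproportionality algorithms at PT and SOC level, and writes:
#' `summary.tsv` (descriptive characteristics of the case reports),
#' `soc_signals.tsv` and `pt_signals.tsv` (ranked signal tables),
#' `volcano.tsv` (PT-level volcano coordinates) and `run.log` (dropped-
#' record tallies, unmapped-PT tally and every active threshold). The run
#' is deterministic given fixed inputs and config. A dataset with zero
#' target-drug reports yields empty signal tables and a warning, not a
#' failure.
#'
#' @param config A [pipeline_config()] or the path to a YAML file with the
#'   same fields.
#' @return Invisibly, a list: `cohort`, `summaries`, `pt_scores`,
#'   `soc_scores`, `volcano`, `outputs` (named file paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- .read_pipeline_config(config)
  stopifnot(inherits(config, "faers_pipeline_config"))

  # config validation precedes any parsing
  if (!file.exists(config$synonym_file)) {
    abort(sprintf("stage config: synonym file '%s' not found", config$synonym_file))
  }
  if (!file.exists(config$pt_soc_file)) {
    abort(sprintf("stage config: PT-SOC map '%s' not found", config$pt_soc_file))
  }
  if (!dir.exists(config$input_dir)) {
    abort(sprintf("stage config: input directory '%s' not found", config$input_dir))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  stage <- "config"
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      .log_line(con, "FAILED at stage '%s': %s", stage, conditionMessage(e))
      abort(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)))
    })
  }

  synonyms <- run_stage("vocabulary", read_drug_synonyms(config$synonym_file))
  soc_map <- run_stage("vocabulary", read_pt_soc_map(config$pt_soc_file))
  .log_line(con, "stage vocabulary: target '%s' (%d spellings), %d PT->SOC entries",
    synonyms$canonical, length(synonyms$synonyms), nrow(soc_map$entries))

  quarter_dirs <- sort(list.dirs(config$input_dir, recursive = FALSE))
  quarter_dirs <- quarter_dirs[file.exists(file.path(quarter_dirs, "demo.txt"))]
  if (length(quarter_dirs) == 0) {
    abort(sprintf("stage parse: no quarter subdirectories with demo.txt under '%s'", config$input_dir))
  }
  bundles <- run_stage("parse", lapply(quarter_dirs, function(qd) {
    files <- file.path(qd, paste0(.faers_tables, ".txt"))
    names(files) <- .faers_tables
    read_faers_quarter(files[file.exists(files)], quarter_label = basename(qd))
  }))
  .log_line(con, "stage parse: %d quarters read", length(bundles))

  reports <- run_stage("assemble", assemble_reports(bundles))
  for (nm in names(reports$dropped)) {
    .log_line(con, "stage assemble: dropped %s = %d", nm, reports$dropped[[nm]])
  }
  .log_line(con, "stage assemble: %d deduplicated reports retained", nrow(reports$reports))

  cohort <- run_stage("flag", flag_cases(reports, synonyms))
  n_case <- sum(cohort$reports$is_case)
  .log_line(con, "stage flag: %d case / %d non-case reports", n_case,
    sum(!cohort$reports$is_case))
  if (n_case == 0) {
    warn("no target-drug case reports; signal tables will be empty")
    .log_line(con, "WARNING: zero case reports")
  }

  summaries <- run_stage("summaries", bind_rows(
    summarize_demographics(cohort),
    summarize_outcomes(cohort),
    summarize_tto(cohort)
  ))

  crit <- list(
    min_a = config$min_a, min_ror = config$min_ror,
    ci_threshold = config$ci_threshold, min_prr = config$min_prr,
    min_chisq = config$min_chisq, min_ic = config$min_ic
  )
  .log_line(con, "stage criteria: thresholds a>=%s ror>=%s ci>%s prr>=%s chisq>=%s ic2sd>%s; zero_cell=%s; counting=%s",
    crit$min_a, crit$min_ror, crit$ci_threshold, crit$min_prr, crit$min_chisq,
    crit$min_ic, config$zero_cell, config$counting)

  score_level <- function(level, map = NULL) {
    tabs <- contingency_tables(cohort, level = level, map = map,
      counting = config$counting)
    if (n_case == 0) tabs <- tabs[0, ]
    do.call(signal_scores, c(
      list(tables = tabs, zero_cell = config$zero_cell), crit
    ))
  }
  pt_scores <- run_stage("statistics", score_level("pt"))
  soc_scores <- run_stage("statistics", score_level("soc", soc_map))
  n_unmapped <- attr(
    pt_to_soc(unique(cohort$units$pt), soc_map), "n_unmapped"
  )
  .log_line(con, "stage statistics: %d PT and %d SOC tables scored; %d unmapped PTs",
    nrow(pt_scores), nrow(soc_scores), n_unmapped)

  volcano <- run_stage("volcano", volcano_points(pt_scores))

  outputs <- c(
    summary = file.path(config$output_dir, "summary.tsv"),
    soc_signals = file.path(config$output_dir, "soc_signals.tsv"),
    pt_signals = file.path(config$output_dir, "pt_signals.tsv"),
    volcano = file.path(config$output_dir, "volcano.tsv"),
    log = log_path
  )
  run_stage("export", {
    readr::write_tsv(summaries, outputs[["summary"]])
    readr::write_tsv(signal_table(soc_scores), outputs[["soc_signals"]])
    readr::write_tsv(signal_table(pt_scores), outputs[["pt_signals"]])
    readr::write_tsv(
      select(volcano, "event", "x", "y", "significant", "excluded"),
      outputs[["volcano"]]
    )
  })
  .log_line(con, "stage export: wrote %d files to %s", length(outputs),
    config$output_dir)

  invisible(list(
    cohort = cohort, summaries = summaries, pt_scores = pt_scores,
    soc_scores = soc_scores, volcano = volcano, outputs = outputs
  ))
}
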