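# Drug-name normalisation and PT -> SOC aggregation. MedDRA itself is
# licensed, so the package takes a user-supplied two-column TSV for real runs
# and ships a small synthetic vocabulary for examples and tests.

#' Build a drug synonym set
#'
#' Spontaneous reports name the same active substance many ways (brand names,
#' generic names, case and whitespace variants). A synonym set lists every
#' spelling to be treated as the target drug; matching is exact after
#' trimming and case-folding.
#'
#' @param canonical The canonical drug name.
#' @param synonyms Character vector of additional accepted spellings.
#' @return A `drug_synonyms` object.
#' @examples
#' tmz <- drug_synonyms("temozolomide", c("temodar", "temodal", "tmz"))
#' is_target_drug(c("TEMODAR ", "bevacizumab"), tmz)
#' @export
drug_synonyms <- function(canonical, synonyms = character()) {
  canonical <- stringr::str_trim(canonical)
  if (length(canonical) != 1 || is.na(canonical) || canonical == "") {
    abort("'canonical' must be a single non-empty drug name")
  }
  structure(
    list(
      canonical = canonical,
      synonyms = unique(c(.norm_term(canonical), .norm_term(synonyms)))
    ),
    class = "drug_synonyms"
  )
}

#' Read a drug synonym list from a one-column text file
#'
#' One spelling per line; the first line is taken as the canonical name.
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the synonym file.
#' @return A `drug_synonyms` object.
#' @export
read_drug_synonyms <- function(path) {
  lines <- stringr::str_trim(readr::read_lines(path))
  lines <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  if (length(lines) == 0) abort(sprintf("synonym file '%s' has no entries", path))
  drug_synonyms(lines[[1]], lines[-1])
}

#' @export
print.drug_synonyms <- function(x, ...) {
  cat(
    "<drug_synonyms>", x$canonical, "with", length(x$synonyms),
    "accepted spellings\n"
  )
  invisible(x)
}

#' Test drug names against a synonym set
#'
#' @param drug_name Character vector of raw drug names.
#' @param synonyms A [drug_synonyms()] object.
#' @return Logical vector: `TRUE` where the trimmed, case-folded name is in
#'   the synonym set; empty or missing names give `FALSE`.
#' @export
is_target_drug <- function(drug_name, synonyms) {
  stopifnot(inherits(synonyms, "drug_synonyms"))
  out <- .norm_term(drug_name) %in% synonyms$synonyms
  out[is.na(drug_name)] <- FALSE
  out
}

#' Build a PT-to-SOC mapping table
#'
#' Maps MedDRA-style preferred terms (PTs) to their primary system organ
#' class (SOC). Each PT maps to exactly one SOC, the MedDRA primary-SOC
#' convention; lookups are case-insensitive.
#'
#' @param entries A data frame with columns `pt` and `soc`.
#' @param version_label Free-text label of the vocabulary version.
#' @return A `pt_soc_map` object.
#' @export
pt_soc_map <- function(entries, version_label = "unversioned") {
  entries <- as_tibble(entries)
  if (!all(c("pt", "soc") %in% names(entries))) {
    abort("'entries' must have columns 'pt' and 'soc'")
  }
  entries <- entries |>
    transmute(pt = .norm_term(.data$pt), soc = stringr::str_trim(.data$soc)) |>
    distinct()
  dup <- entries$pt[duplicated(entries$pt)]
  if (length(dup) > 0) {
    abort(sprintf(
      "PT(s) mapped to more than one SOC (primary-SOC convention requires one): %s",
      paste(unique(dup), collapse = ", ")
    ))
  }
  structure(
    list(entries = entries, version_label = version_label),
    class = "pt_soc_map"
  )
}

#' Read a PT-to-SOC map from a two-column TSV
#'
#' @param path Path to a tab-separated file with header columns `pt` and
#'   `soc`.
#' @param version_label Vocabulary version label; defaults to the file name.
#' @return A `pt_soc_map` object.
#' @export
read_pt_soc_map <- function(path, version_label = basename(path)) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  pt_soc_map(df, version_label)
}

#' @export
print.pt_soc_map <- function(x, ...) {
  cat(
    "<pt_soc_map>", nrow(x$entries), "PTs,",
    dplyr::n_distinct(x$entries$soc), "SOCs (version", paste0(x$version_label, ")\n")
  )
  invisible(x)
}

#' Marker returned for PTs absent from the mapping
#' @export
unmapped_soc <- "(unmapped)"

#' Map preferred terms to system organ classes
#'
#' Unmapped PTs are returned as the explicit [unmapped_soc] marker and
#' counted in the `n_unmapped` attribute — they are never silently dropped,
#' so downstream SOC tables always account for every event.
#'
#' @param pt Character vector of PT terms.
#' @param map A [pt_soc_map()] object.
#' @return Character vector of SOC names, attribute `n_unmapped` holding the
#'   number of lookups that missed.
#' @export
pt_to_soc <- function(pt, map) {
  stopifnot(inherits(map, "pt_soc_map"))
  idx <- match(.norm_term(pt), map$entries$pt)
  out <- ifelse(is.na(idx), unmapped_soc, map$entries$soc[idx])
  attr(out, "n_unmapped") <- sum(is.na(idx) & !is.na(pt))
  out
}
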