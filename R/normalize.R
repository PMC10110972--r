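# Primary-suspect culprit-drug extraction, ingredient integration and ATC
# classification.
#
# The ingredient map replaces the manual pharmacist integration of
# same-active-ingredient forms (salt forms etc.) with a user-supplied,
# auditable table; unmapped names fall through as their canonicalized form
# so that an empty map is the identity. Every exclusion (missing generic
# name, ambiguous name, within-report duplicate) is tallied, never silent.

#' Marker for ambiguous raw names in an ingredient map
#' @export
AMBIGUOUS <- "AMBIGUOUS"

ATC_CODE_PATTERN <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

#' Create an ingredient map
#'
#' Maps normalized raw generic names to canonical ingredient names. Keys
#' are canonicalized (lowercased, trimmed, whitespace collapsed) on
#' construction. A value of [AMBIGUOUS] marks a raw name that cannot be
#' resolved to a single ingredient; such names are excluded from the
#' culprit list with reason `"ambiguous"`.
#'
#' @param entries Named character vector: `c(raw_name = canonical, ...)`.
#' @return An `ingredient_map`.
#' @export
ingredient_map <- function(entries = character()) {
  if (length(entries)) {
    if (is.null(names(entries)) || any(!nzchar(names(entries))))
      stop("ingredient map entries must be named", call. = FALSE)
    if (any(!nzchar(entries)))
      stop("ingredient map values must be nonempty", call. = FALSE)
    names(entries) <- canonicalize_name(names(entries))
    entries <- ifelse(entries == AMBIGUOUS, AMBIGUOUS,
                      canonicalize_name(entries))
    if (anyDuplicated(names(entries)))
      stop("duplicate raw names in ingredient map", call. = FALSE)
  }
  structure(as.character(entries), names = names(entries),
            class = "ingredient_map")
}

#' Read an ingredient map from a tab-delimited file
#'
#' Expected format: two columns `raw_name<TAB>canonical`, UTF-8, with a
#' header row. Use the literal value `AMBIGUOUS` in the second column to
#' mark unresolvable names.
#'
#' @param path File to read.
#' @return An [ingredient_map()].
#' @export
read_ingredient_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2)
    stop("ingredient map needs columns raw_name and canonical", call. = FALSE)
  ingredient_map(stats::setNames(df[[2]], df[[1]]))
}

#' Create an ATC map
#'
#' Maps canonical ingredient names to their full 7-character ATC codes
#' (e.g. `N03AX09`); the second-level therapeutic class is the first three
#' characters (e.g. `N03`, antiepileptics). A drug may carry several codes.
#'
#' @param entries Named list: `list(ingredient = c("N03AX09", ...), ...)`.
#' @return An `atc_map`.
#' @export
atc_map <- function(entries = list()) {
  if (length(entries)) {
    if (is.null(names(entries)) || any(!nzchar(names(entries))))
      stop("ATC map entries must be named by ingredient", call. = FALSE)
    names(entries) <- canonicalize_name(names(entries))
    entries <- lapply(entries, function(codes) {
      codes <- toupper(as.character(codes))
      bad <- codes[!grepl(ATC_CODE_PATTERN, codes)]
      if (length(bad))
        stop("malformed ATC code(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      codes
    })
  }
  structure(as.list(entries), class = "atc_map")
}

#' Read an ATC map from a tab-delimited file
#'
#' Expected format: `canonical<TAB>atc_code[,atc_code...]`, UTF-8, header
#' row.
#'
#' @param path File to read.
#' @return An [atc_map()].
#' @export
read_atc_map <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL,
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2)
    stop("ATC map needs columns canonical and atc_codes", call. = FALSE)
  atc_map(stats::setNames(lapply(strsplit(df[[2]], ","), trimws), df[[1]]))
}

#' Extract primary-suspect generic names from one report
#'
#' Only mentions with role `primary_suspect` (openFDA
#' `drugcharacterization = 1`) are culprit evidence; concomitant and
#' interacting drugs are ignored. Suspect mentions lacking a generic name
#' cannot be attributed to an ingredient and are tallied as excluded.
#'
#' @param report An [adverse_event_report()].
#' @return List with `names` (character vector of raw generic names) and
#'   `excluded` (named integer tally, currently `missing_name`).
#' @export
extract_primary_suspect_names <- function(report) {
  stopifnot(inherits(report, "adverse_event_report"))
  suspects <- Filter(function(d) d$role == "primary_suspect", report$drugs)
  names_raw <- vapply(suspects, `[[`, character(1), "generic_name")
  missing <- is.na(names_raw)
  list(names = names_raw[!missing],
       excluded = c(missing_name = sum(missing)))
}

#' Normalize raw drug names through an ingredient map
#'
#' Each raw name is canonicalized (lowercase, trimmed, whitespace
#' collapsed) and looked up in the map. Unmapped names pass through as
#' their canonical form (identity fallback); names mapped to [AMBIGUOUS]
#' are excluded with reason `"ambiguous"`; missing/empty names with reason
#' `"missing_name"`.
#'
#' @param raw Character vector of raw generic names (NA allowed).
#' @param imap An [ingredient_map()].
#' @return Data frame with columns `raw`, `canonical` (NA when excluded)
#'   and `reason` (`""`, `"missing_name"` or `"ambiguous"`).
#' @export
normalize_name <- function(raw, imap = ingredient_map()) {
  stopifnot(inherits(imap, "ingredient_map"))
  raw <- as.character(raw)
  key <- canonicalize_name(raw)
  canonical <- key
  reason <- rep("", length(raw))
  miss <- is.na(raw) | !nzchar(key)
  hit <- match(key, names(imap))
  mapped <- !is.na(hit) & !miss
  canonical[mapped] <- unclass(imap)[hit[mapped]]
  amb <- mapped & canonical == AMBIGUOUS
  reason[amb] <- "ambiguous"
  reason[miss] <- "missing_name"
  canonical[amb | miss] <- NA_character_
  data.frame(raw = raw, canonical = canonical, reason = reason,
             stringsAsFactors = FALSE)
}

#' Build the culprit-drug list from SCAR-related reports
#'
#' A culprit drug is an ingredient named as primary suspect in at least one
#' SCAR report. Suspect mentions are extracted, normalized through the
#' ingredient map, and the standard exclusions applied: mentions with
#' missing generic names, ambiguous names, and within-report duplicates of
#' the same canonical ingredient (each report contributes an ingredient at
#' most once). ATC codes are attached from the map; ingredients without a
#' mapping are retained with an empty code list and logged.
#'
#' @param scar_set Deduplicated [report_set()] of SMQ-matching reports.
#' @param imap An [ingredient_map()].
#' @param atcmap An [atc_map()].
#' @return A `culprit_list`: data frame with columns `canonical_name`,
#'   `n_reports`, `atc_codes` (list column) and `report_ids` (list column),
#'   sorted by `n_reports` descending then name ascending. Attributes:
#'   `exclusions` (named integer tally: missing_name, ambiguous,
#'   duplicated) and `unmapped_atc` (ingredients with no ATC entry).
#' @export
build_culprit_list <- function(scar_set, imap = ingredient_map(),
                               atcmap = atc_map()) {
  dr <- scar_set$drugs
  sus <- dr[dr$role == "primary_suspect", , drop = FALSE]
  norm <- normalize_name(sus$generic_name, imap)
  excl <- c(missing_name = sum(norm$reason == "missing_name"),
            ambiguous = sum(norm$reason == "ambiguous"),
            duplicated = 0L)
  ok <- norm$reason == ""
  rec <- sus$rec[ok]
  canonical <- norm$canonical[ok]
  dup <- duplicated(paste(rec, canonical, sep = "\r"))
  excl["duplicated"] <- sum(dup)
  rec <- rec[!dup]
  canonical <- canonical[!dup]
  if (length(canonical) == 0L) {
    out <- data.frame(canonical_name = character(), n_reports = integer(),
                      stringsAsFactors = FALSE)
    out$atc_codes <- list()
    out$report_ids <- list()
  } else {
    ids <- scar_set$reports$report_id[match(rec, scar_set$reports$rec)]
    by_drug <- split(ids, canonical)
    out <- data.frame(canonical_name = names(by_drug),
                      n_reports = lengths(by_drug),
                      stringsAsFactors = FALSE, row.names = NULL)
    out$report_ids <- unname(by_drug)
    ord <- order(-out$n_reports, out$canonical_name)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out$atc_codes <- lapply(out$canonical_name, function(nm)
      unclass(atcmap)[[nm]] %||% character(0))
    out <- out[, c("canonical_name", "n_reports", "atc_codes", "report_ids")]
  }
  attr(out, "exclusions") <- excl
  attr(out, "unmapped_atc") <- out$canonical_name[lengths(out$atc_codes) == 0L]
  class(out) <- c("culprit_list", "data.frame")
  out
}

#' Culprit-drug counts per SMQ/PT scope
#'
#' For every narrow PT of the SMQ, counts the culprit drugs that are
#' primary suspect in at least one matching report; the SMQ row is the
#' total culprit count (100.0%). Percentages are of the total culprit
#' list, rounded half away from zero to one decimal.
#'
#' @param culprits A [build_culprit_list()] result.
#' @param scar_set The SCAR report set the list was built from.
#' @param smq An [smq_definition()].
#' @return Data frame with columns `scope`, `n_drugs`, `percent`; PT rows
#'   sorted by count descending (ties by name), SMQ row last.
#' @export
culprit_counts_per_scope <- function(culprits, scar_set, smq = scar_smq()) {
  em <- scar_event_matrix(scar_set, smq)
  total <- nrow(culprits)
  pt_names <- smq$narrow_pts$name
  n_drugs <- integer(length(pt_names))
  if (total > 0 && nrow(scar_set$reports) > 0) {
    rows_by_drug <- lapply(culprits$report_ids, function(ids)
      match(ids, scar_set$reports$report_id))
    for (j in seq_along(pt_names)) {
      flag <- em[, 1L + j]
      n_drugs[j] <- sum(vapply(rows_by_drug, function(rws)
        any(flag[rws]), logical(1)))
    }
  }
  ord <- order(-n_drugs, pt_names)
  out <- data.frame(
    scope = c(pt_names[ord], smq$name),
    n_drugs = c(n_drugs[ord], total),
    stringsAsFactors = FALSE)
  out$percent <- percent_of(out$n_drugs, total, digits = 1)
  out
}
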