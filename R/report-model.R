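# Domain model for spontaneous adverse-event reports, plus readers/writers
# for the openFDA drug-event JSON dialect and a flat tab-delimited dialect.
#
# A report_set stores its reports relationally (one row per report, per
# reaction, per drug mention) keyed by an internal record index `rec`, so
# that pre-deduplication duplicates sharing a report_id remain distinct
# records. All user-facing accessors speak in terms of whole reports.

DRUG_ROLES <- c("primary_suspect", "concomitant", "interacting", "unknown")
SEX_LEVELS <- c("female", "male", "unknown")
REPORTER_LEVELS <- c("health_professional", "consumer_or_lawyer", "unknown")
REPORTER_DETAILS <- c("physician", "pharmacist", "other_health_professional",
                      "lawyer", "consumer")
OUTCOME_LEVELS <- c("death", "life_threatening", "hospitalization",
                    "disability", "congenital_anomaly", "other", "unknown")

# openFDA primarysource.qualification codes <-> reporter detail words
QUALIFICATION_CODES <- c(physician = "1", pharmacist = "2",
                         other_health_professional = "3",
                         lawyer = "4", consumer = "5")

empty_reports_df <- function() {
  data.frame(rec = integer(), report_id = character(),
             receive_date = as.Date(character()), reporter = character(),
             reporter_detail = character(), country = character(),
             sex = character(), age_years = numeric(), outcomes = character(),
             stringsAsFactors = FALSE)
}

empty_reactions_df <- function() {
  data.frame(rec = integer(), pt = character(), stringsAsFactors = FALSE)
}

empty_drugs_df <- function() {
  data.frame(rec = integer(), role = character(), generic_name = character(),
             raw_product_name = character(), stringsAsFactors = FALSE)
}

#' Create a drug mention
#'
#' One drug named on a report, with its reported role. The role follows the
#' openFDA `drugcharacterization` coding: 1 = primary suspect, 2 =
#' concomitant, 3 = interacting; anything else is `"unknown"`. Only
#' primary-suspect mentions are ever treated as culprit evidence.
#'
#' @param role One of `"primary_suspect"`, `"concomitant"`, `"interacting"`,
#'   `"unknown"`.
#' @param generic_name Generic (active-ingredient) name, or `NA` if the
#'   report lacks one.
#' @param raw_product_name Verbatim product name as reported, or `NA`.
#' @return A `drug_mention` object.
#' @export
drug_mention <- function(role, generic_name = NA_character_,
                         raw_product_name = NA_character_) {
  role <- match.arg(role, DRUG_ROLES)
  if ((is.na(generic_name) || !nzchar(generic_name)) &&
      (is.na(raw_product_name) || !nzchar(raw_product_name)) &&
      role == "unknown") {
    stop("a drug mention must carry a role or at least one name", call. = FALSE)
  }
  structure(list(role = role,
                 generic_name = if (is.na(generic_name) || !nzchar(generic_name))
                   NA_character_ else as.character(generic_name),
                 raw_product_name = if (is.na(raw_product_name) || !nzchar(raw_product_name))
                   NA_character_ else as.character(raw_product_name)),
            class = "drug_mention")
}

#' Create one spontaneous adverse-event report
#'
#' @param report_id Nonempty report identifier.
#' @param reactions Character vector of MedDRA preferred-term strings
#'   (must be nonempty).
#' @param drugs List of [drug_mention()] objects (may be empty).
#' @param receive_date A `Date` (or coercible string), or `NA` if unknown.
#' @param reporter `"health_professional"`, `"consumer_or_lawyer"` or
#'   `"unknown"`.
#' @param reporter_detail Optional finer qualification: one of
#'   `"physician"`, `"pharmacist"`, `"other_health_professional"`,
#'   `"lawyer"`, `"consumer"`. Defaults to the generic code for the
#'   reporter category so that round trips through the openFDA dialect are
#'   exact.
#' @param country ISO 3166 two-letter country code, or `NA` if unknown.
#' @param sex `"female"`, `"male"` or `"unknown"`.
#' @param age_years Non-negative age in years (< 150), or `NA` if unknown.
#' @param outcomes Character vector drawn from `death`, `life_threatening`,
#'   `hospitalization`, `disability`, `congenital_anomaly`, `other`,
#'   `unknown`.
#' @return An `adverse_event_report` object.
#' @export
adverse_event_report <- function(report_id, reactions, drugs = list(),
                                 receive_date = NA, reporter = "unknown",
                                 reporter_detail = NA_character_,
                                 country = NA_character_, sex = "unknown",
                                 age_years = NA_real_, outcomes = "unknown") {
  if (!is.character(report_id) || length(report_id) != 1L || !nzchar(report_id))
    stop("report_id must be a nonempty string", call. = FALSE)
  reactions <- as.character(reactions)
  if (length(reactions) == 0L || any(!nzchar(reactions)))
    stop("reactions must be a nonempty vector of nonempty strings", call. = FALSE)
  reporter <- match.arg(reporter, REPORTER_LEVELS)
  sex <- match.arg(sex, SEX_LEVELS)
  outcomes <- as.character(outcomes)
  bad <- setdiff(outcomes, OUTCOME_LEVELS)
  if (length(bad))
    stop("unknown outcome value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.na(age_years) && (age_years < 0 || age_years >= 150))
    stop("age_years must be in [0, 150) or NA", call. = FALSE)
  if (is.na(reporter_detail)) {
    reporter_detail <- switch(reporter,
                              health_professional = "other_health_professional",
                              consumer_or_lawyer = "consumer",
                              NA_character_)
  } else {
    reporter_detail <- match.arg(reporter_detail, REPORTER_DETAILS)
  }
  if (!all(vapply(drugs, inherits, logical(1), "drug_mention")))
    stop("drugs must be a list of drug_mention objects", call. = FALSE)
  structure(list(report_id = report_id,
                 receive_date = as.Date(receive_date),
                 reporter = reporter, reporter_detail = reporter_detail,
                 country = if (is.na(country)) NA_character_ else toupper(country),
                 sex = sex, age_years = as.numeric(age_years),
                 outcomes = unique(outcomes),
                 reactions = reactions, drugs = drugs),
            class = "adverse_event_report")
}

#' Assemble a report set
#'
#' The central container of the pipeline: an ordered collection of
#' [adverse_event_report()] records with a provenance label. Stored
#' relationally (report-, reaction- and drug-level tables keyed by an
#' internal record index) for vectorized downstream counting.
#'
#' @param reports List of `adverse_event_report` objects.
#' @param provenance Free-text label describing the origin of the data.
#' @return A `report_set`.
#' @export
report_set <- function(reports = list(), provenance = "") {
  if (!all(vapply(reports, inherits, logical(1), "adverse_event_report")))
    stop("reports must be a list of adverse_event_report objects", call. = FALSE)
  n <- length(reports)
  if (n == 0L) {
    return(new_report_set(empty_reports_df(), empty_reactions_df(),
                          empty_drugs_df(), provenance))
  }
  rep_df <- data.frame(
    rec = seq_len(n),
    report_id = vapply(reports, `[[`, character(1), "report_id"),
    receive_date = as.Date(vapply(reports, function(r)
      as.character(r$receive_date), character(1))),
    reporter = vapply(reports, `[[`, character(1), "reporter"),
    reporter_detail = vapply(reports, `[[`, character(1), "reporter_detail"),
    country = vapply(reports, `[[`, character(1), "country"),
    sex = vapply(reports, `[[`, character(1), "sex"),
    age_years = vapply(reports, `[[`, numeric(1), "age_years"),
    outcomes = vapply(reports, function(r) paste(r$outcomes, collapse = "|"),
                      character(1)),
    stringsAsFactors = FALSE)
  nrx <- vapply(reports, function(r) length(r$reactions), integer(1))
  rx_df <- data.frame(rec = rep.int(seq_len(n), nrx),
                      pt = unlist(lapply(reports, `[[`, "reactions"),
                                  use.names = FALSE),
                      stringsAsFactors = FALSE)
  ndr <- vapply(reports, function(r) length(r$drugs), integer(1))
  if (sum(ndr) == 0L) {
    dr_df <- empty_drugs_df()
  } else {
    mentions <- unlist(lapply(reports, `[[`, "drugs"), recursive = FALSE)
    dr_df <- data.frame(
      rec = rep.int(seq_len(n), ndr),
      role = vapply(mentions, `[[`, character(1), "role"),
      generic_name = vapply(mentions, `[[`, character(1), "generic_name"),
      raw_product_name = vapply(mentions, `[[`, character(1), "raw_product_name"),
      stringsAsFactors = FALSE)
  }
  new_report_set(rep_df, rx_df, dr_df, provenance)
}

new_report_set <- function(reports, reactions, drugs, provenance = "",
                           skip_tally = c(no_reactions = 0L,
                                          missing_report_id = 0L)) {
  rs <- structure(list(reports = reports, reactions = reactions,
                       drugs = drugs, provenance = provenance,
                       skip_tally = skip_tally),
                  class = "report_set")
  validate_report_set(rs)
  rs
}

validate_report_set <- function(rs) {
  rep_df <- rs$reports
  stopifnot(is.data.frame(rep_df), is.data.frame(rs$reactions),
            is.data.frame(rs$drugs))
  if (anyNA(rep_df$report_id) || any(!nzchar(rep_df$report_id)))
    stop("report_id must be nonempty for every report", call. = FALSE)
  if (any(!(rep_df$sex %in% SEX_LEVELS)))
    stop("invalid sex value in report table", call. = FALSE)
  if (any(!(rep_df$reporter %in% REPORTER_LEVELS)))
    stop("invalid reporter value in report table", call. = FALSE)
  age <- rep_df$age_years
  if (any(!is.na(age) & (age < 0 | age >= 150)))
    stop("age_years must be in [0, 150) or NA", call. = FALSE)
  if (nrow(rep_df) > 0 && !all(rep_df$rec %in% rs$reactions$rec))
    stop("every report must have at least one reaction", call. = FALSE)
  if (nrow(rs$drugs) > 0 && any(!(rs$drugs$role %in% DRUG_ROLES)))
    stop("invalid drug role in drug table", call. = FALSE)
  invisible(rs)
}

#' Number of reports in a report set
#' @param rs A `report_set`.
#' @return Integer count of report records.
#' @export
n_reports <- function(rs) nrow(rs$reports)

#' Report identifiers of a report set
#' @param rs A `report_set`.
#' @return Character vector of report ids, in input order (duplicates
#'   possible before deduplication).
#' @export
report_ids <- function(rs) rs$reports$report_id

#' Skip tally of a report set
#'
#' Records skipped while reading a file: records with no reactions and
#' records with no report id are dropped (with a count) rather than
#' erroring, because real spontaneous-report extracts contain them.
#'
#' @param rs A `report_set`.
#' @return Named integer vector of skip counts by reason.
#' @export
skip_tally <- function(rs) rs$skip_tally

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf("<report_set> %d report(s), %d reaction row(s), %d drug mention(s)\n",
              nrow(x$reports), nrow(x$reactions), nrow(x$drugs)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  if (any(x$skip_tally > 0))
    cat("  skipped on read:",
        paste(sprintf("%s=%d", names(x$skip_tally), x$skip_tally), collapse = ", "),
        "\n")
  invisible(x)
}

#' Materialize a report set as a list of report objects
#'
#' Inverse of [report_set()]: reconstructs one [adverse_event_report()] per
#' record. Used for round-trip checks and per-report operations.
#'
#' @param rs A `report_set`.
#' @return List of `adverse_event_report` objects in input order.
#' @export
report_records <- function(rs) {
  recs <- rs$reports$rec
  rx_by <- split(rs$reactions$pt, factor(rs$reactions$rec, levels = recs))
  dr_split <- split(seq_len(nrow(rs$drugs)),
                    factor(rs$drugs$rec, levels = recs))
  lapply(seq_along(recs), function(i) {
    r <- rs$reports[i, ]
    drows <- dr_split[[i]]
    drugs <- lapply(drows, function(j)
      drug_mention(rs$drugs$role[j], rs$drugs$generic_name[j],
                   rs$drugs$raw_product_name[j]))
    adverse_event_report(
      report_id = r$report_id, reactions = rx_by[[i]], drugs = drugs,
      receive_date = r$receive_date, reporter = r$reporter,
      reporter_detail = r$reporter_detail, country = r$country, sex = r$sex,
      age_years = r$age_years,
      outcomes = strsplit(r$outcomes, "|", fixed = TRUE)[[1]])
  })
}

# ---- openFDA drug-event JSON dialect ---------------------------------------

openfda_age_years <- function(age, unit) {
  age <- suppressWarnings(as.numeric(as.character(age %||% NA)))
  if (length(age) != 1L || is.na(age)) return(NA_real_)
  yrs <- switch(as.character(unit %||% "801"),
                "800" = age * 10, "801" = age, "802" = age / 12,
                "803" = age / 52.18, "804" = age / 365.25,
                "805" = age / 8766, NA_real_)
  if (is.na(yrs) || yrs < 0 || yrs >= 150) NA_real_ else yrs
}

openfda_record_to_report <- function(rec) {
  id <- rec$safetyreportid
  if (is.null(id) || !nzchar(as.character(id))) return("missing_report_id")
  pt <- vapply(rec$patient$reaction %||% list(), function(x)
    as.character(x$reactionmeddrapt %||% ""), character(1))
  pt <- pt[nzchar(pt)]
  if (length(pt) == 0L) return("no_reactions")

  qual <- as.character(rec$primarysource$qualification %||% "")
  detail <- names(QUALIFICATION_CODES)[match(qual, QUALIFICATION_CODES)]
  reporter <- if (is.na(detail)) "unknown"
  else if (detail %in% c("lawyer", "consumer")) "consumer_or_lawyer"
  else "health_professional"

  date_raw <- as.character(rec$receivedate %||% "")
  receive_date <- if (grepl("^[0-9]{8}$", date_raw))
    as.Date(date_raw, format = "%Y%m%d") else as.Date(NA)

  country <- as.character(rec$occurcountry %||% "")
  country <- if (grepl("^[A-Za-z]{2}$", country)) toupper(country) else NA_character_

  sex <- switch(as.character(rec$patient$patientsex %||% ""),
                "1" = "male", "2" = "female", "unknown")

  flags <- c(death = "seriousnessdeath",
             life_threatening = "seriousnesslifethreatening",
             hospitalization = "seriousnesshospitalization",
             disability = "seriousnessdisabling",
             congenital_anomaly = "seriousnesscongenitalanomali",
             other = "seriousnessother")
  outcomes <- names(flags)[vapply(flags, function(f)
    identical(as.character(rec[[f]] %||% ""), "1"), logical(1))]
  if (length(outcomes) == 0L) outcomes <- "unknown"

  drugs <- lapply(rec$patient$drug %||% list(), function(d) {
    role <- switch(as.character(d$drugcharacterization %||% ""),
                   "1" = "primary_suspect", "2" = "concomitant",
                   "3" = "interacting", "unknown")
    gname <- d$openfda$generic_name
    gname <- if (is.null(gname)) NA_character_ else as.character(unlist(gname))[1]
    raw <- as.character(d$medicinalproduct %||% NA_character_)
    if (role == "unknown" && is.na(gname) && (is.na(raw) || !nzchar(raw)))
      return(NULL)
    drug_mention(role, gname, raw)
  })
  drugs <- drugs[!vapply(drugs, is.null, logical(1))]

  adverse_event_report(
    report_id = as.character(id), reactions = pt, drugs = drugs,
    receive_date = receive_date, reporter = reporter,
    reporter_detail = if (is.na(detail)) NA_character_ else detail,
    country = country, sex = sex,
    age_years = openfda_age_years(rec$patient$patientonsetage,
                                  rec$patient$patientonsetageunit),
    outcomes = outcomes)
}

report_to_openfda_record <- function(r) {
  rec <- list(safetyreportid = r$report_id)
  if (!is.na(r$receive_date))
    rec$receivedate <- format(r$receive_date, "%Y%m%d")
  if (!is.na(r$reporter_detail))
    rec$primarysource <- list(
      qualification = unname(QUALIFICATION_CODES[r$reporter_detail]))
  if (!is.na(r$country)) rec$occurcountry <- r$country
  flags <- c(death = "seriousnessdeath",
             life_threatening = "seriousnesslifethreatening",
             hospitalization = "seriousnesshospitalization",
             disability = "seriousnessdisabling",
             congenital_anomaly = "seriousnesscongenitalanomali",
             other = "seriousnessother")
  for (o in r$outcomes) if (o != "unknown") rec[[flags[[o]]]] <- "1"
  patient <- list()
  if (r$sex != "unknown")
    patient$patientsex <- if (r$sex == "male") "1" else "2"
  if (!is.na(r$age_years)) {
    patient$patientonsetage <- as.character(r$age_years)
    patient$patientonsetageunit <- "801"
  }
  patient$reaction <- lapply(r$reactions, function(p)
    list(reactionmeddrapt = p))
  patient$drug <- lapply(r$drugs, function(d) {
    dd <- list(drugcharacterization = switch(d$role, primary_suspect = "1",
                                             concomitant = "2",
                                             interacting = "3", "0"))
    if (!is.na(d$raw_product_name)) dd$medicinalproduct <- d$raw_product_name
    if (!is.na(d$generic_name))
      dd$openfda <- list(generic_name = list(d$generic_name))
    dd
  })
  rec$patient <- patient
  rec
}

# ---- flat tab-delimited dialect --------------------------------------------

FLAT_COLUMNS <- c("record", "report_id", "receive_date", "reporter",
                  "reporter_detail", "country", "sex", "age_years",
                  "outcomes", "reaction", "drug_role", "generic_name",
                  "raw_product_name")

report_set_to_flat <- function(rs) {
  recs <- report_records(rs)
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    nd <- max(1L, length(r$drugs))
    grid <- expand.grid(rx = seq_along(r$reactions), dr = seq_len(nd),
                        KEEP.OUT.ATTRS = FALSE)
    has_drugs <- length(r$drugs) > 0
    data.frame(
      record = i, report_id = r$report_id,
      receive_date = if (is.na(r$receive_date)) "" else format(r$receive_date),
      reporter = r$reporter,
      reporter_detail = if (is.na(r$reporter_detail)) "" else r$reporter_detail,
      country = if (is.na(r$country)) "" else r$country,
      sex = r$sex,
      age_years = if (is.na(r$age_years)) "" else as.character(r$age_years),
      outcomes = paste(r$outcomes, collapse = "|"),
      reaction = r$reactions[grid$rx],
      drug_role = if (has_drugs)
        vapply(r$drugs[grid$dr], `[[`, character(1), "role") else "",
      generic_name = if (has_drugs)
        vapply(r$drugs[grid$dr], function(d)
          if (is.na(d$generic_name)) "" else d$generic_name, character(1)) else "",
      raw_product_name = if (has_drugs)
        vapply(r$drugs[grid$dr], function(d)
          if (is.na(d$raw_product_name)) "" else d$raw_product_name,
          character(1)) else "",
      stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(as.data.frame(stats::setNames(
      rep(list(character()), length(FLAT_COLUMNS)), FLAT_COLUMNS),
      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

flat_to_report_set <- function(df, provenance) {
  missing_cols <- setdiff(FLAT_COLUMNS, names(df))
  if (length(missing_cols))
    stop("flat table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  blank2na <- function(x) ifelse(nzchar(x), x, NA_character_)
  skipped <- c(no_reactions = 0L, missing_report_id = 0L)
  reports <- list()
  for (recno in unique(df$record)) {
    sub <- df[df$record == recno, , drop = FALSE]
    first <- sub[1, ]
    if (!nzchar(first$report_id)) {
      skipped["missing_report_id"] <- skipped["missing_report_id"] + 1L
      next
    }
    reactions <- unique(sub$reaction[nzchar(sub$reaction)])
    if (length(reactions) == 0L) {
      skipped["no_reactions"] <- skipped["no_reactions"] + 1L
      next
    }
    dsub <- unique(sub[nzchar(sub$drug_role),
                       c("drug_role", "generic_name", "raw_product_name")])
    drugs <- lapply(seq_len(nrow(dsub)), function(j)
      drug_mention(dsub$drug_role[j], blank2na(dsub$generic_name[j]),
                   blank2na(dsub$raw_product_name[j])))
    reports[[length(reports) + 1L]] <- adverse_event_report(
      report_id = first$report_id, reactions = reactions, drugs = drugs,
      receive_date = if (nzchar(first$receive_date))
        as.Date(first$receive_date) else NA,
      reporter = first$reporter,
      reporter_detail = blank2na(first$reporter_detail),
      country = blank2na(first$country), sex = first$sex,
      age_years = if (nzchar(first$age_years))
        as.numeric(first$age_years) else NA_real_,
      outcomes = strsplit(first$outcomes, "|", fixed = TRUE)[[1]])
  }
  rs <- report_set(reports, provenance)
  rs$skip_tally <- skipped
  rs
}

# ---- public readers/writers ------------------------------------------------

#' Read spontaneous reports from a file
#'
#' Two dialects are supported. `openfda_json` is the openFDA drug-event
#' subset: reaction preferred terms are read from
#' `patient.reaction.reactionmeddrapt`, the drug role from
#' `patient.drug.drugcharacterization` (1 = primary suspect) and the
#' generic name from `patient.drug.openfda.generic_name`; both the
#' `{"results": [...]}` envelope and newline-delimited JSON are accepted.
#' `flat_table` is a UTF-8 tab-delimited table with a header row and one
#' row per (report, drug, reaction) combination.
#'
#' Unknown or missing source fields become explicit unknown values in the
#' model, never silent defaults. Records without any reaction (and records
#' without a report id) are skipped and counted in [skip_tally()].
#'
#' @param path File to read.
#' @param dialect `"openfda_json"` or `"flat_table"`.
#' @return A [report_set()]; input record order is preserved.
#' @export
read_reports <- function(path, dialect = c("openfda_json", "flat_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (dialect == "flat_table") {
    df <- utils::read.delim(path, colClasses = "character",
                            na.strings = NULL, check.names = FALSE,
                            fileEncoding = "UTF-8")
    return(flat_to_report_set(df, provenance = path))
  }
  txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
               collapse = "\n")
  records <- tryCatch({
    if (grepl("^\\s*\\{", txt) &&
        !grepl("^\\s*\\{[^\n]*\\}\\s*\n\\s*\\{", txt)) {
      parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
      if (!is.null(parsed$results)) parsed$results else list(parsed)
    } else if (grepl("^\\s*\\[", txt)) {
      jsonlite::fromJSON(txt, simplifyVector = FALSE)
    } else {
      lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
      lines <- lines[nzchar(trimws(lines))]
      lapply(seq_along(lines), function(i) {
        tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                 error = function(e) stop(sprintf(
                   "cannot parse %s: record %d: %s", path, i,
                   conditionMessage(e)), call. = FALSE))
      })
    }
  }, error = function(e) stop(sprintf("cannot parse %s: %s", path,
                                      conditionMessage(e)), call. = FALSE))
  skipped <- c(no_reactions = 0L, missing_report_id = 0L)
  reports <- list()
  for (rec in records) {
    r <- openfda_record_to_report(rec)
    if (is.character(r)) {
      skipped[r] <- skipped[r] + 1L
    } else {
      reports[[length(reports) + 1L]] <- r
    }
  }
  rs <- report_set(reports, provenance = path)
  rs$skip_tally <- skipped
  rs
}

#' Write spontaneous reports to a file
#'
#' Inverse of [read_reports()]: all modeled fields round-trip exactly
#' through either dialect. The openFDA dialect is written in the
#' `{"results": [...]}` envelope form.
#'
#' @param rs A [report_set()].
#' @param path Output file.
#' @param dialect `"openfda_json"` or `"flat_table"`.
#' @return Invisibly, `path`.
#' @export
write_reports <- function(rs, path, dialect = c("openfda_json", "flat_table")) {
  dialect <- match.arg(dialect)
  validate_report_set(rs)
  if (dialect == "flat_table") {
    utils::write.table(report_set_to_flat(rs), path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  } else {
    records <- lapply(report_records(rs), report_to_openfda_record)
    jsonlite::write_json(list(results = records), path, auto_unbox = TRUE,
                         null = "null", digits = NA)
  }
  invisible(path)
}

#' Deduplicate a report set by report id
#'
#' Spontaneous-report databases contain duplicate submissions of the same
#' case. Among records sharing a `report_id`, the one with the latest
#' receive date is kept; ties (including all-unknown dates) keep the record
#' listed last in input order. Relative input order of the surviving
#' records is preserved. The operation is idempotent.
#'
#' @param rs A [report_set()].
#' @return A deduplicated `report_set` with unique report ids.
#' @export
deduplicate_reports <- function(rs) {
  rep_df <- rs$reports
  if (nrow(rep_df) <= 1L || !anyDuplicated(rep_df$report_id)) return(rs)
  score <- as.numeric(rep_df$receive_date)
  score[is.na(score)] <- -Inf
  # order by (id, score, position); the last row per id wins both tie rules
  ord <- order(rep_df$report_id, score, seq_len(nrow(rep_df)))
  keep_rows <- ord[!duplicated(rep_df$report_id[ord], fromLast = TRUE)]
  keep_rows <- sort(keep_rows)
  keep_recs <- rep_df$rec[keep_rows]
  rep_out <- rep_df[keep_rows, , drop = FALSE]
  rep_out$rec <- seq_along(keep_rows)
  rx_map <- match(rs$reactions$rec, keep_recs)
  rx_out <- rs$reactions[!is.na(rx_map), , drop = FALSE]
  rx_out$rec <- rx_map[!is.na(rx_map)]
  dr_map <- match(rs$drugs$rec, keep_recs)
  dr_out <- rs$drugs[!is.na(dr_map), , drop = FALSE]
  dr_out$rec <- dr_map[!is.na(dr_map)]
  rownames(rep_out) <- rownames(rx_out) <- rownames(dr_out) <- NULL
  out <- new_report_set(rep_out, rx_out, dr_out, rs$provenance, rs$skip_tally)
  if (anyDuplicated(out$reports$report_id))
    stop("internal error: duplicate report ids after deduplication")
  out
}
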