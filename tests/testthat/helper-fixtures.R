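# Small builders and independent oracles shared across the test files.
# Oracles deliberately walk report records one by one (report_records()),
# independent of the vectorized counting paths they check.

aer <- function(id, reactions, drugs = list(), ...) {
  adverse_event_report(report_id = id, reactions = reactions,
                       drugs = drugs, ...)
}

suspect <- function(name, raw = toupper(name)) {
  drug_mention("primary_suspect", generic_name = name,
               raw_product_name = raw)
}

# A small mixed report set exercising unknowns, multiple reactions, and
# multiple drug roles.
mixed_report_set <- function() {
  report_set(list(
    aer("R1", c("Stevens–Johnson syndrome", "Pyrexia"),
        list(suspect("LAMOTRIGINE"),
             drug_mention("concomitant", "VALPROATE", "VALPROATE TAB")),
        receive_date = "2019-03-05", reporter = "health_professional",
        country = "FR", sex = "female", age_years = 64,
        outcomes = c("death", "hospitalization")),
    aer("R2", "Toxic epidermal necrolysis",
        list(suspect("ALLOPURINOL"),
             drug_mention("interacting", NA, "UNKNOWN MIXTURE")),
        receive_date = "2020-11-20", reporter = "consumer_or_lawyer",
        country = "US", sex = "male", age_years = 35.5,
        outcomes = "life_threatening"),
    aer("R3", "Headache",
        list(drug_mention("primary_suspect", NA, "MYSTERY SYRUP")))),
    provenance = "fixture")
}

# Brute-force contingency recount: walks every record, applies the SMQ
# match and the primary-suspect rule per report, and tallies the 2x2
# cells for one (drug, scope) pair.
oracle_contingency <- function(rs, drug, scope, smq = scar_smq(),
                               imap = ingredient_map()) {
  recs <- report_records(rs)
  a <- b <- cc <- d <- 0L
  for (r in recs) {
    matched <- match_scar_pts(r, smq)
    has_event <- if (identical(scope, "SMQ")) length(matched) > 0
    else scope %in% matched
    sus_names <- extract_primary_suspect_names(r)$names
    canon <- normalize_name(sus_names, imap)
    canon <- canon$canonical[canon$reason == ""]
    has_drug <- drug %in% canon
    if (has_drug && has_event) a <- a + 1L
    else if (has_drug) b <- b + 1L
    else if (has_event) cc <- cc + 1L
    else d <- d + 1L
  }
  c(a = a, b = b, c = cc, d = d)
}

# Independent full-matrix recount: classifies every record once with the
# per-report primitives (match_scar_pts, extract_primary_suspect_names,
# normalize_name), then tallies the 2x2 cells and re-applies the
# positive-signal rule for every (drug, scope) pair. No code shared with
# the vectorized signal_matrix() counting path.
oracle_signal_table <- function(rs, drugs, smq = scar_smq(),
                                imap = ingredient_map()) {
  recs <- report_records(rs)
  matched <- lapply(recs, match_scar_pts, smq = smq)
  canon <- lapply(recs, function(r) {
    nm <- normalize_name(extract_primary_suspect_names(r)$names, imap)
    unique(nm$canonical[nm$reason == ""])
  })
  scopes <- c("SMQ", smq$narrow_pts$name)
  rows <- list()
  for (dname in drugs) {
    has_drug <- vapply(canon, function(x) dname %in% x, logical(1))
    for (s in scopes) {
      has_event <- if (identical(s, "SMQ")) lengths(matched) > 0
      else vapply(matched, function(x) s %in% x, logical(1))
      a <- sum(has_drug & has_event)
      b <- sum(has_drug & !has_event)
      cc <- sum(!has_drug & has_event)
      d <- sum(!has_drug & !has_event)
      rows[[length(rows) + 1L]] <- data.frame(
        drug = dname, scope = s, a = a, b = b, c = cc, d = d,
        positive = oracle_positive(a, b, cc, d), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Textbook odds ratio and 95% log-normal CI, written as the ratio of the
# two reporting odds (not a*d/(b*c)) with the variance terms summed in a
# different association order.
oracle_ror <- function(a, b, c, d) {
  or <- (a / c) / (b / d)
  se <- sqrt((1 / a + 1 / d) + (1 / b + 1 / c))
  list(ror = or, ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se))
}

# The positive-signal rule re-applied from scratch.
oracle_positive <- function(a, b, c, d) {
  if (a == 0 || b == 0 || c == 0 || d == 0) return(FALSE)
  res <- oracle_ror(a, b, c, d)
  res$ci_low > 1 && a >= 3
}

write_openfda_fixture <- function(path, records) {
  jsonlite::write_json(list(results = records), path, auto_unbox = TRUE)
  path
}

openfda_sjs_record <- function(id = "1001") {
  list(safetyreportid = id, receivedate = "20190305",
       primarysource = list(qualification = "1"),
       occurcountry = "FR",
       seriousnessdeath = "1",
       patient = list(
         patientsex = "2", patientonsetage = "64",
         patientonsetageunit = "801",
         reaction = list(
           list(reactionmeddrapt = "Stevens–Johnson syndrome")),
         drug = list(
           list(drugcharacterization = "1",
                medicinalproduct = "LAMICTAL",
                openfda = list(generic_name = list("LAMOTRIGINE"))))))
}
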