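# Synthetic spontaneous-report generator with known ground truth.
#
# Each base report draws one primary-suspect drug from the catalog; each
# SCAR narrow PT then appears with odds = baseline_pt_odds[pt] multiplied
# by any configured effect for the drawn drug (an SMQ-scope effect scales
# all 18 PTs). Odds -- not probabilities -- are multiplied, so the ROR
# estimand converges to the configured multiplier as baseline odds shrink.
# Filler (non-SCAR) reactions are drawn independently, with a guaranteed
# filler so no report has an empty reaction list. Demographics are sampled
# independently of drugs and reactions (no confounding, matching a method
# that makes no adjustment). Duplicate submissions are exact copies reusing
# an existing report id.

#' Specify one catalog drug for simulation
#'
#' @param name Canonical ingredient name.
#' @param atc_codes Character vector of full ATC codes (nonempty).
#' @param use_probability Probability that a report names this drug as its
#'   primary suspect; must sum to 1 over the catalog.
#' @return A `drug_spec`.
#' @export
drug_spec <- function(name, atc_codes, use_probability) {
  if (!is.character(name) || !nzchar(name))
    stop_field("catalog.name", "must be a nonempty string")
  if (length(atc_codes) == 0L)
    stop_field("catalog.atc_codes", "must be nonempty")
  if (!is.numeric(use_probability) || use_probability < 0)
    stop_field("catalog.use_probability", "must be a non-negative number")
  structure(list(name = canonicalize_name(name),
                 atc_codes = toupper(as.character(atc_codes)),
                 use_probability = use_probability),
            class = "drug_spec")
}

#' Specify an injected drug-reaction effect
#'
#' The ground truth a simulation hides: the odds of the scoped reaction(s)
#' for reports whose suspect is `drug` are multiplied by `odds_multiplier`
#' (1 = null). Scope `"SMQ"` scales every narrow PT of the SMQ.
#'
#' @param drug Canonical drug name (must exist in the catalog).
#' @param scope A narrow PT name or `"SMQ"`.
#' @param odds_multiplier Positive real; 1 is the null.
#' @return An `effect_spec`.
#' @export
effect_spec <- function(drug, scope, odds_multiplier) {
  if (!is.numeric(odds_multiplier) || odds_multiplier <= 0)
    stop_field("effects.odds_multiplier", "must be > 0")
  structure(list(drug = canonicalize_name(drug), scope = scope,
                 odds_multiplier = odds_multiplier),
            class = "effect_spec")
}

#' Assemble and validate a simulation configuration
#'
#' @param n_reports Number of base reports (duplicates come on top).
#' @param catalog List of [drug_spec()]s; use probabilities must sum to 1.
#' @param baseline_pt_odds Named numeric vector: baseline odds of each SCAR
#'   narrow PT appearing in a report (names must be narrow PTs of `smq`).
#' @param filler_reactions Named numeric vector: occurrence probability of
#'   each non-SCAR filler PT. The first filler is the guaranteed reaction
#'   added when all draws fail.
#' @param effects List of [effect_spec()]s (may be empty = global null).
#' @param missing_name_probability Probability the suspect's generic name
#'   is blanked (the raw product name is kept).
#' @param duplicate_probability Expected fraction of duplicate submissions
#'   appended as exact copies of random base reports.
#' @param concomitant_probability Probability a report carries one
#'   concomitant decoration drug drawn uniformly from the catalog.
#' @param demographics Demographic sampling distributions; see
#'   [default_demographics()].
#' @param seed Integer RNG seed: identical seed and config give an
#'   identical report set.
#' @param smq The [smq_definition()] the PT odds refer to.
#' @return A validated `simulation_config`.
#' @export
simulation_config <- function(n_reports, catalog, baseline_pt_odds,
                              filler_reactions = c("Nausea" = 0.2),
                              effects = list(),
                              missing_name_probability = 0.05,
                              duplicate_probability = 0.01,
                              concomitant_probability = 0.3,
                              demographics = default_demographics(),
                              seed = 1L, smq = scar_smq()) {
  if (!is.numeric(n_reports) || length(n_reports) != 1L || n_reports < 0 ||
      n_reports != round(n_reports))
    stop_field("n_reports", "must be a non-negative integer")
  if (length(catalog) == 0L ||
      !all(vapply(catalog, inherits, logical(1), "drug_spec")))
    stop_field("catalog", "must be a nonempty list of drug_spec objects")
  probs <- vapply(catalog, `[[`, numeric(1), "use_probability")
  if (abs(sum(probs) - 1) > 1e-8)
    stop_field("catalog.use_probability", "must sum to 1 over the catalog")
  drug_names <- vapply(catalog, `[[`, character(1), "name")
  if (anyDuplicated(drug_names))
    stop_field("catalog.name", "duplicate drug names")
  pt_names <- smq$narrow_pts$name
  if (is.null(names(baseline_pt_odds)) ||
      !all(names(baseline_pt_odds) %in% pt_names))
    stop_field("baseline_pt_odds",
               "must be named by narrow PTs of the SMQ")
  if (any(baseline_pt_odds < 0))
    stop_field("baseline_pt_odds", "odds must be non-negative")
  if (length(filler_reactions) == 0L || is.null(names(filler_reactions)))
    stop_field("filler_reactions", "must be a nonempty named vector")
  if (any(filler_reactions < 0 | filler_reactions > 1))
    stop_field("filler_reactions", "probabilities must lie in [0, 1]")
  if (any(normalize_pt(names(filler_reactions)) %in% normalize_pt(pt_names)))
    stop_field("filler_reactions", "must not contain SCAR narrow PTs")
  if (!all(vapply(effects, inherits, logical(1), "effect_spec")))
    stop_field("effects", "must be a list of effect_spec objects")
  for (e in effects) {
    if (!(e$drug %in% drug_names))
      stop_field("effects.drug", paste0("'", e$drug, "' not in catalog"))
    if (!identical(e$scope, SMQ_SCOPE_LABEL) &&
        !(normalize_pt(e$scope) %in% normalize_pt(names(baseline_pt_odds))))
      stop_field("effects.scope",
                 paste0("'", e$scope,
                        "' has no baseline odds and is not the SMQ scope"))
  }
  for (f in c("missing_name_probability", "duplicate_probability",
              "concomitant_probability")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1)
      stop_field(f, "must lie in [0, 1]")
  }
  validate_demographics(demographics)
  if (!is.numeric(seed) || seed != round(seed))
    stop_field("seed", "must be an integer")
  structure(list(n_reports = as.integer(n_reports), catalog = catalog,
                 baseline_pt_odds = baseline_pt_odds,
                 filler_reactions = filler_reactions, effects = effects,
                 missing_name_probability = missing_name_probability,
                 duplicate_probability = duplicate_probability,
                 concomitant_probability = concomitant_probability,
                 demographics = demographics, seed = as.integer(seed),
                 smq = smq),
            class = "simulation_config")
}

#' Default demographic sampling distributions
#'
#' Marginal distributions patterned on what large spontaneous-report
#' collections of severe cutaneous reactions look like: mostly
#' health-professional reporters (78%), more female than male patients,
#' ages peaking in the seventh decade, France and the United States as the
#' leading reporting countries, about 10% fatal outcomes, and report years
#' spanning 2004-2021 with a late peak. Each component is a named
#' probability vector; outcomes are independent per-outcome probabilities
#' (a report may carry several).
#'
#' @return A named list of distributions (`sex`, `reporter`, `country`,
#'   `age_decade`, `year`, `outcomes`).
#' @export
default_demographics <- function() {
  year_w <- c(1, 1, 1, 2, 2, 2, 3, 3, 4, 4, 5, 5, 6, 7, 8, 10, 9, 8)
  list(
    sex = c(female = 0.53, male = 0.40, unknown = 0.07),
    reporter = c(health_professional = 0.78, consumer_or_lawyer = 0.18,
                 unknown = 0.04),
    country = c(FR = 0.22, US = 0.21, JP = 0.09, DE = 0.08, GB = 0.07,
                IT = 0.06, CN = 0.06, ES = 0.05, CA = 0.05, BR = 0.04,
                KR = 0.04, AU = 0.03),
    age_decade = c("0-10" = 0.04, "11-20" = 0.05, "21-30" = 0.08,
                   "31-40" = 0.10, "41-50" = 0.12, "51-60" = 0.16,
                   "61-70" = 0.20, "71-80" = 0.14, "81-90" = 0.05,
                   ">90" = 0.01, unknown = 0.05),
    year = stats::setNames(year_w / sum(year_w), 2004:2021),
    outcomes = c(death = 0.10, life_threatening = 0.12,
                 hospitalization = 0.45, disability = 0.03,
                 congenital_anomaly = 0.005, other = 0.30))
}

validate_demographics <- function(d) {
  need <- c("sex", "reporter", "country", "age_decade", "year", "outcomes")
  if (!all(need %in% names(d)))
    stop_field("demographics", paste("must contain:",
                                     paste(need, collapse = ", ")))
  for (f in setdiff(need, "outcomes")) {
    v <- d[[f]]
    if (is.null(names(v)) || any(v < 0) || abs(sum(v) - 1) > 1e-6)
      stop_field(paste0("demographics.", f),
                 "must be a named probability vector summing to 1")
  }
  if (any(d$outcomes < 0 | d$outcomes > 1) ||
      !all(names(d$outcomes) %in% setdiff(OUTCOME_LEVELS, "unknown")))
    stop_field("demographics.outcomes",
               "must be per-outcome probabilities in [0, 1]")
  invisible(d)
}

# K x P matrix of effective odds multipliers (drugs x narrow PTs): the
# product of any PT-scope effect and any SMQ-scope effect for the drug.
effect_multiplier_matrix <- function(config) {
  drugs <- vapply(config$catalog, `[[`, character(1), "name")
  pts <- config$smq$narrow_pts$name
  m <- matrix(1, nrow = length(drugs), ncol = length(pts),
              dimnames = list(drugs, pts))
  for (e in config$effects) {
    if (identical(e$scope, SMQ_SCOPE_LABEL)) {
      m[e$drug, ] <- m[e$drug, ] * e$odds_multiplier
    } else {
      j <- match(normalize_pt(e$scope), normalize_pt(pts))
      m[e$drug, j] <- m[e$drug, j] * e$odds_multiplier
    }
  }
  m
}

sample_named <- function(n, dist) {
  names(dist)[sample.int(length(dist), n, replace = TRUE, prob = dist)]
}

#' Generate a synthetic spontaneous-report set
#'
#' Draws exactly `n_reports` base reports under the configured generative
#' model, then appends duplicate submissions. Identical seed and
#' configuration give an identical report set; the caller's RNG state is
#' left untouched.
#'
#' @param config A [simulation_config()].
#' @return A [report_set()] with provenance `"synthetic"`.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, generate_reports_impl(config))
}

generate_reports_impl <- function(config) {
  n <- config$n_reports
  if (n == 0L)
    return(new_report_set(empty_reports_df(), empty_reactions_df(),
                          empty_drugs_df(), provenance = "synthetic"))
  catalog <- config$catalog
  drug_names <- vapply(catalog, `[[`, character(1), "name")
  probs <- vapply(catalog, `[[`, numeric(1), "use_probability")
  drug_idx <- sample.int(length(catalog), n, replace = TRUE, prob = probs)

  # SCAR PT draws: independent Bernoulli per PT on the odds scale
  pts <- config$smq$narrow_pts$name
  base_odds <- rep(0, length(pts))
  j <- match(names(config$baseline_pt_odds), pts)
  base_odds[j] <- config$baseline_pt_odds
  mult <- effect_multiplier_matrix(config)
  odds <- matrix(base_odds, nrow = n, ncol = length(pts), byrow = TRUE) *
    mult[drug_idx, , drop = FALSE]
  p_scar <- odds / (1 + odds)
  scar_draw <- matrix(stats::runif(n * length(pts)), n) < p_scar

  # filler reactions, plus a guaranteed filler for all-miss reports
  fill_names <- names(config$filler_reactions)
  fill_draw <- matrix(stats::runif(n * length(fill_names)), n) <
    matrix(config$filler_reactions, nrow = n, ncol = length(fill_names),
           byrow = TRUE)
  empty <- rowSums(scar_draw) + rowSums(fill_draw) == 0L
  fill_draw[empty, 1L] <- TRUE

  hits_scar <- which(scar_draw, arr.ind = TRUE)
  hits_fill <- which(fill_draw, arr.ind = TRUE)
  rx_df <- data.frame(
    rec = c(hits_scar[, 1L], hits_fill[, 1L]),
    pt = c(pts[hits_scar[, 2L]], fill_names[hits_fill[, 2L]]),
    stringsAsFactors = FALSE)
  rx_df <- rx_df[order(rx_df$rec), , drop = FALSE]
  rownames(rx_df) <- NULL

  # primary-suspect mentions, with optional concomitant decorations
  blank <- stats::runif(n) < config$missing_name_probability
  sus_df <- data.frame(
    rec = seq_len(n), role = "primary_suspect",
    generic_name = ifelse(blank, NA_character_,
                          toupper(drug_names[drug_idx])),
    raw_product_name = toupper(drug_names[drug_idx]),
    stringsAsFactors = FALSE)
  conc <- which(stats::runif(n) < config$concomitant_probability)
  if (length(conc)) {
    cidx <- sample.int(length(catalog), length(conc), replace = TRUE)
    conc_df <- data.frame(
      rec = conc, role = "concomitant",
      generic_name = toupper(drug_names[cidx]),
      raw_product_name = toupper(drug_names[cidx]),
      stringsAsFactors = FALSE)
    dr_df <- rbind(sus_df, conc_df)
    dr_df <- dr_df[order(dr_df$rec), , drop = FALSE]
    rownames(dr_df) <- NULL
  } else {
    dr_df <- sus_df
  }

  # demographics, independent of drugs and reactions
  dem <- config$demographics
  decade <- sample_named(n, dem$age_decade)
  age <- decade_to_age(decade)
  year <- as.integer(sample_named(n, dem$year))
  dates <- as.Date(sprintf("%d-01-01", year)) +
    floor(stats::runif(n) * 365)
  out_draw <- matrix(stats::runif(n * length(dem$outcomes)), n) <
    matrix(dem$outcomes, nrow = n, ncol = length(dem$outcomes), byrow = TRUE)
  outcome_str <- apply(out_draw, 1L, function(z)
    if (any(z)) paste(names(dem$outcomes)[z], collapse = "|") else "unknown")
  reporter <- sample_named(n, dem$reporter)
  rep_df <- data.frame(
    rec = seq_len(n),
    report_id = sprintf("SYN%08d", seq_len(n)),
    receive_date = dates,
    reporter = reporter,
    reporter_detail = ifelse(
      reporter == "health_professional", "other_health_professional",
      ifelse(reporter == "consumer_or_lawyer", "consumer", NA_character_)),
    country = sample_named(n, dem$country),
    sex = sample_named(n, dem$sex),
    age_years = age,
    outcomes = outcome_str,
    stringsAsFactors = FALSE)

  # duplicate submissions: exact copies reusing the source report_id
  ndup <- stats::rbinom(1L, n, config$duplicate_probability)
  if (ndup > 0L) {
    src <- sample.int(n, ndup, replace = TRUE)
    dup_rec <- n + seq_len(ndup)
    dup_rep <- rep_df[src, , drop = FALSE]
    dup_rep$rec <- dup_rec
    rep_df <- rbind(rep_df, dup_rep)
    remap <- function(df) {
      idx <- split(seq_len(nrow(df)), factor(df$rec, levels = seq_len(n)))
      pick <- idx[src]
      dup <- df[unlist(pick, use.names = FALSE), , drop = FALSE]
      dup$rec <- rep.int(dup_rec, lengths(pick))
      rbind(df, dup)
    }
    rx_df <- remap(rx_df)
    dr_df <- remap(dr_df)
    rownames(rep_df) <- rownames(rx_df) <- rownames(dr_df) <- NULL
  }
  new_report_set(rep_df, rx_df, dr_df, provenance = "synthetic")
}

decade_to_age <- function(decade) {
  lo <- c("0-10" = 0, "11-20" = 11, "21-30" = 21, "31-40" = 31,
          "41-50" = 41, "51-60" = 51, "61-70" = 61, "71-80" = 71,
          "81-90" = 81, ">90" = 91)
  hi <- c("0-10" = 10, "11-20" = 20, "21-30" = 30, "31-40" = 40,
          "41-50" = 50, "51-60" = 60, "61-70" = 70, "71-80" = 80,
          "81-90" = 90, ">90" = 99)
  age <- rep(NA_real_, length(decade))
  known <- decade != "unknown"
  age[known] <- lo[decade[known]] +
    floor(stats::runif(sum(known)) * (hi[decade[known]] - lo[decade[known]] + 1))
  age
}

#' Ground-truth odds multipliers of a simulation configuration
#'
#' One row per (drug, scope) over catalog x (18 narrow PTs + SMQ). PT rows
#' report the effective per-PT odds multiplier (PT-scope times SMQ-scope
#' effects). The SMQ row reports a configured SMQ-scope multiplier
#' directly; when only PT-scope effects are present, the generative model
#' implies no single SMQ odds multiplier, so the row carries the marginal
#' odds ratio of "any narrow PT" for the drug versus baseline, computed by
#' enumeration over the model, and is flagged `induced`.
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns `drug`, `scope`, `odds_multiplier`,
#'   `induced`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  pts <- config$smq$narrow_pts$name
  base_odds <- rep(0, length(pts))
  base_odds[match(names(config$baseline_pt_odds), pts)] <-
    config$baseline_pt_odds
  mult <- effect_multiplier_matrix(config)
  drugs <- rownames(mult)
  p_any <- function(odds) 1 - prod(1 / (1 + odds))
  p0 <- p_any(base_odds)
  odds0 <- p0 / (1 - p0)
  smq_direct <- stats::setNames(rep(NA_real_, length(drugs)), drugs)
  for (e in config$effects) {
    if (identical(e$scope, SMQ_SCOPE_LABEL)) {
      cur <- smq_direct[e$drug]
      smq_direct[e$drug] <- ifelse(is.na(cur), e$odds_multiplier,
                                   cur * e$odds_multiplier)
    }
  }
  rows <- lapply(drugs, function(dname) {
    if (!is.na(smq_direct[dname])) {
      smq_mult <- unname(smq_direct[dname])
      induced <- FALSE
    } else if (all(mult[dname, ] == 1)) {
      smq_mult <- 1
      induced <- FALSE
    } else {
      pd <- p_any(base_odds * mult[dname, ])
      smq_mult <- (pd / (1 - pd)) / odds0
      induced <- TRUE
    }
    data.frame(drug = dname,
               scope = c(SMQ_SCOPE_LABEL, pts),
               odds_multiplier = c(smq_mult, unname(mult[dname, ])),
               induced = c(induced, rep(FALSE, length(pts))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Expected case counts implied by a simulation configuration
#'
#' Analytic expectation of the `a` cell (reports with drug and event) for
#' every (drug, scope) pair over the base reports, used to decide which
#' pairs are informative enough to evaluate (e.g. the expected `a >= 3`
#' gate in calibration studies).
#'
#' @param config A [simulation_config()].
#' @return Data frame with columns `drug`, `scope`, `expected_a`.
#' @export
expected_case_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  pts <- config$smq$narrow_pts$name
  base_odds <- rep(0, length(pts))
  base_odds[match(names(config$baseline_pt_odds), pts)] <-
    config$baseline_pt_odds
  mult <- effect_multiplier_matrix(config)
  use_p <- vapply(config$catalog, `[[`, numeric(1), "use_probability")
  n <- config$n_reports
  rows <- lapply(seq_along(config$catalog), function(k) {
    odds <- base_odds * mult[k, ]
    p_pt <- odds / (1 + odds)
    p_smq <- 1 - prod(1 - p_pt)
    data.frame(drug = config$catalog[[k]]$name,
               scope = c(SMQ_SCOPE_LABEL, pts),
               expected_a = n * use_p[k] * c(p_smq, p_pt),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read a simulation configuration from a JSON file
#'
#' The schema mirrors [simulation_config()]: top-level fields
#' `n_reports`, `catalog` (array of objects with `name`, `atc_codes`,
#' `use_probability`), `baseline_pt_odds` (object: PT name to odds),
#' `filler_reactions` (object: PT name to probability), `effects` (array
#' of objects with `drug`, `scope`, `odds_multiplier`),
#' `missing_name_probability`, `duplicate_probability`,
#' `concomitant_probability` and `seed`. Omitted optional fields take the
#' constructor defaults; demographics always take
#' [default_demographics()]. The file is validated through
#' [simulation_config()], so malformed fields fail with the field named.
#'
#' @param path JSON file to read.
#' @return A validated [simulation_config()].
#' @seealso [write_simulation_config()]
#' @export
read_simulation_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  need <- c("n_reports", "catalog", "baseline_pt_odds")
  missing_f <- setdiff(need, names(raw))
  if (length(missing_f))
    stop_field(missing_f[1], "required in simulation config file")
  args <- list(
    n_reports = raw$n_reports,
    catalog = lapply(raw$catalog, function(d)
      drug_spec(d$name, unlist(d$atc_codes), d$use_probability)),
    baseline_pt_odds = unlist(raw$baseline_pt_odds),
    effects = lapply(raw$effects %||% list(), function(e)
      effect_spec(e$drug, e$scope, e$odds_multiplier)))
  for (f in c("filler_reactions", "missing_name_probability",
              "duplicate_probability", "concomitant_probability", "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- unlist(raw[[f]])
  }
  do.call(simulation_config, args)
}

#' Write a simulation configuration to a JSON file
#'
#' Inverse of [read_simulation_config()]; the demographics component is
#' not serialized (files always use the package defaults).
#'
#' @param config A [simulation_config()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  out <- list(
    n_reports = config$n_reports,
    catalog = lapply(config$catalog, function(d)
      list(name = d$name, atc_codes = as.list(d$atc_codes),
           use_probability = d$use_probability)),
    baseline_pt_odds = as.list(config$baseline_pt_odds),
    filler_reactions = as.list(config$filler_reactions),
    effects = lapply(config$effects, function(e)
      list(drug = e$drug, scope = e$scope,
           odds_multiplier = e$odds_multiplier)),
    missing_name_probability = config$missing_name_probability,
    duplicate_probability = config$duplicate_probability,
    concomitant_probability = config$concomitant_probability,
    seed = config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' A ready-made study-scale simulation configuration
#'
#' Twenty catalog drugs spanning the therapeutic classes most often
#' reported with severe cutaneous reactions (antiepileptics,
#' antibacterials, analgesics, urate-lowering agents, antineoplastics,
#' ...), with a mildly skewed use distribution; baseline PT odds chosen so
#' that Stevens-Johnson syndrome is the most frequent narrow PT and
#' SCAR-related reports stay a small fraction (under one percent at the
#' null) of all reports, as in large spontaneous-report databases. All
#' effects default to the null; pass `effects` to inject signals.
#'
#' @param n_reports Number of base reports.
#' @param effects List of [effect_spec()]s to inject.
#' @param seed RNG seed.
#' @param ... Further arguments passed to [simulation_config()].
#' @return A [simulation_config()].
#' @export
default_simulation_config <- function(n_reports = 100000, effects = list(),
                                      seed = 1L, ...) {
  catalog <- default_drug_catalog()
  simulation_config(
    n_reports = n_reports, catalog = catalog,
    baseline_pt_odds = default_baseline_pt_odds(),
    filler_reactions = c("Nausea" = 0.25, "Headache" = 0.20,
                         "Fatigue" = 0.15, "Dizziness" = 0.10,
                         "Vomiting" = 0.08, "Pyrexia" = 0.06,
                         "Rash" = 0.05, "Diarrhoea" = 0.05),
    effects = effects, seed = seed, ...)
}

default_drug_catalog <- function() {
  specs <- list(
    list("lamotrigine", "N03AX09", 0.08),
    list("carbamazepine", "N03AF01", 0.05),
    list("phenytoin", "N03AB02", 0.04),
    list("allopurinol", "M04AA01", 0.06),
    list("sulfamethoxazole/trimethoprim", "J01EE01", 0.05),
    list("amoxicillin", "J01CA04", 0.07),
    list("ceftriaxone", "J01DD04", 0.04),
    list("vancomycin", "J01XA01", 0.04),
    list("acetaminophen", "N02BE01", 0.08),
    list("ibuprofen", "M01AE01", 0.05),
    list("diclofenac", "M01AB05", 0.04),
    list("naproxen", "M01AE02", 0.03),
    list("furosemide", "C03CA01", 0.05),
    list("omeprazole", "A02BC01", 0.05),
    list("pembrolizumab", "L01FF02", 0.04),
    list("vemurafenib", "L01EC01", 0.03),
    list("metformin", "A10BA02", 0.05),
    list("amlodipine", "C08CA01", 0.05),
    list("atorvastatin", "C10AA05", 0.05),
    list("lisinopril", "C09AA03", 0.05))
  lapply(specs, function(s) drug_spec(s[[1]], s[[2]], s[[3]]))
}

default_baseline_pt_odds <- function() {
  c("Stevens–Johnson syndrome" = 0.0012,
    "Toxic epidermal necrolysis" = 0.0008,
    "Erythema multiforme" = 0.0009,
    "Drug reaction with eosinophilia and systemic symptoms" = 0.0007,
    "Dermatitis exfoliative" = 0.0006,
    "Dermatitis bullous" = 0.0005,
    "Toxic skin eruption" = 0.0005,
    "Skin necrosis" = 0.0004,
    "Exfoliative rash" = 0.0004,
    "Acute generalized exanthematous pustulosis" = 0.0003,
    "Dermatitis exfoliative generalized" = 0.0002,
    "Cutaneous vasculitis" = 0.0002,
    "Epidermal necrosis" = 0.0001,
    "Oculomucocutaneous syndrome" = 0.00005,
    "SJS–TEN overlap" = 0.00005,
    "Bullous hemorrhagic dermatosis" = 0.00003,
    "Target skin lesion" = 0.00002,
    "Erythrodermic atopic dermatitis" = 0.00002)
}
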