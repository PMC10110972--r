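# End-to-end orchestration: read (or simulate) -> deduplicate -> SCAR
# filter -> culprit list -> 19-signal disproportionality -> positive
# screening -> summary tables, with a machine-readable run manifest.

#' Assemble and validate a pipeline configuration
#'
#' Exactly one of `input` (a report file) or `simulation` (a
#' [simulation_config()]) must be given. Map paths are optional; absent
#' maps mean identity ingredient normalization and no ATC classes (the
#' ATC-class proportion table is then skipped).
#'
#' @param input Path to a report file, or `NULL` to simulate.
#' @param dialect Input dialect, see [read_reports()].
#' @param simulation A [simulation_config()], or `NULL` to read `input`.
#' @param ingredient_map_path Optional path to a tab-delimited ingredient
#'   map.
#' @param atc_map_path Optional path to a tab-delimited ATC map.
#' @param out_dir Output directory (created if needed).
#' @param background Background convention for [signal_matrix()].
#' @param zero_cell Zero-cell mode for [compute_ror()].
#' @param top_n Rows kept in reporting-proportion tables.
#' @param seed Integer seed controlling any randomness in the run.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, dialect = "openfda_json",
                            simulation = NULL, ingredient_map_path = NULL,
                            atc_map_path = NULL, out_dir,
                            background = c("faers_background", "scar_only"),
                            zero_cell = c("none", "haldane"),
                            top_n = 10L, seed = 1L) {
  if (is.null(input) == is.null(simulation))
    stop_field("input/simulation", "exactly one must be provided")
  if (!is.null(input) && !file.exists(input))
    stop_field("input", paste("file not found:", input))
  if (!is.null(simulation) && !inherits(simulation, "simulation_config"))
    stop_field("simulation", "must be a simulation_config")
  for (p in c(ingredient_map = ingredient_map_path, atc_map = atc_map_path)) {
    if (!is.null(p) && !file.exists(p))
      stop_field("map path", paste("file not found:", p))
  }
  if (!is.numeric(top_n) || top_n < 1)
    stop_field("top_n", "must be a positive integer")
  structure(list(input = input, dialect = dialect, simulation = simulation,
                 ingredient_map_path = ingredient_map_path,
                 atc_map_path = atc_map_path, out_dir = out_dir,
                 background = match.arg(background),
                 zero_cell = match.arg(zero_cell),
                 top_n = as.integer(top_n), seed = as.integer(seed)),
            class = "pipeline_config")
}

write_summary_tsv <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Run the full SCAR pharmacovigilance pipeline
#'
#' Executes every stage in order, logging record counts per stage, and
#' writes tab-delimited outputs plus a JSON manifest (`manifest.json`)
#' recording the package version, seed, conventions, exclusion tallies and
#' stage counts. Identical configuration and seed give identical outputs.
#' On error the incomplete output directory is marked by removing the
#' manifest, so a present manifest implies a complete run.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress stage logging.
#' @return Invisibly, the manifest list (also written as JSON).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  if (file.exists(manifest_path)) unlink(manifest_path)

  stage <- "ingest"
  result <- tryCatch({
    raw <- if (!is.null(cfg$simulation)) {
      generate_reports(cfg$simulation)
    } else {
      read_reports(cfg$input, cfg$dialect)
    }
    say("[ingest] %d report record(s), skipped: %s", n_reports(raw),
        paste(sprintf("%s=%d", names(skip_tally(raw)), skip_tally(raw)),
              collapse = ", "))

    stage <- "deduplicate"
    dedup <- deduplicate_reports(raw)
    say("[deduplicate] %d -> %d report(s)", n_reports(raw), n_reports(dedup))

    stage <- "scar_filter"
    smq <- scar_smq()
    flt <- filter_scar_reports(dedup, smq)
    say("[scar_filter] %d SCAR-related report(s)", flt$smq_count)

    stage <- "normalize"
    imap <- if (is.null(cfg$ingredient_map_path)) ingredient_map()
    else read_ingredient_map(cfg$ingredient_map_path)
    amap <- if (is.null(cfg$atc_map_path)) atc_map()
    else read_atc_map(cfg$atc_map_path)
    if (!is.null(cfg$simulation) && is.null(cfg$atc_map_path)) {
      amap <- atc_map(stats::setNames(
        lapply(cfg$simulation$catalog, `[[`, "atc_codes"),
        vapply(cfg$simulation$catalog, `[[`, character(1), "name")))
    }
    culprits <- build_culprit_list(flt$scar_set, imap, amap)
    excl <- attr(culprits, "exclusions")
    say("[normalize] %d culprit drug(s); excluded: %s", nrow(culprits),
        paste(sprintf("%s=%d", names(excl), excl), collapse = ", "))

    stage <- "signals"
    sm <- signal_matrix(dedup, culprits, smq, imap,
                        zero_cell = cfg$zero_cell,
                        background = cfg$background)
    screened <- screen_positive_drugs(sm)
    say("[signals] %d drug(s) with at least one positive signal",
        length(screened$drugs))

    stage <- "summarize"
    desc <- descriptive_summary(flt$scar_set, smq)
    scope_counts <- culprit_counts_per_scope(culprits, flt$scar_set, smq)
    top_drugs <- reporting_proportions(flt$scar_set, culprits, "drug",
                                       cfg$top_n, "SMQ", smq)
    has_atc <- any(lengths(culprits$atc_codes) > 0)
    top_classes <- if (has_atc)
      reporting_proportions(flt$scar_set, culprits, "atc2", cfg$top_n,
                            "SMQ", smq)
    psd <- positive_signal_distribution(sm)

    stage <- "write"
    sig_out <- as.data.frame(sm)
    sig_out$ror_display <- round_half_away(sig_out$ror, 2)
    sig_out$ci_low_display <- round_half_away(sig_out$ci_low, 2)
    sig_out$ci_high_display <- round_half_away(sig_out$ci_high, 2)
    utils::write.table(sig_out, file.path(cfg$out_dir, "signals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    culprit_out <- data.frame(
      canonical_name = culprits$canonical_name,
      n_reports = culprits$n_reports,
      atc_codes = vapply(culprits$atc_codes, paste, character(1),
                         collapse = ","),
      stringsAsFactors = FALSE)
    utils::write.table(culprit_out,
                       file.path(cfg$out_dir, "culprit_drugs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    for (nm in names(desc))
      write_summary_tsv(desc[[nm]],
                        file.path(cfg$out_dir, paste0("summary_", nm, ".tsv")))
    utils::write.table(scope_counts,
                       file.path(cfg$out_dir, "culprit_counts_per_scope.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    write_summary_tsv(top_drugs, file.path(cfg$out_dir, "top_drugs.tsv"))
    if (has_atc)
      write_summary_tsv(top_classes, file.path(cfg$out_dir, "top_classes.tsv"))
    write_summary_tsv(psd,
                      file.path(cfg$out_dir, "positive_signal_distribution.tsv"))

    files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
    manifest <- list(
      package = "scarsignal",
      version = as.character(utils::packageVersion("scarsignal")),
      seed = cfg$seed,
      conventions = list(background = cfg$background,
                         zero_cell = cfg$zero_cell,
                         ci_quantile = 1.96, min_cases = 3,
                         top_n = cfg$top_n,
                         multiple_testing_adjustment = "none"),
      counts = list(raw_records = n_reports(raw),
                    skipped_on_read = as.list(skip_tally(raw)),
                    deduplicated = n_reports(dedup),
                    duplicates_removed = n_reports(raw) - n_reports(dedup),
                    scar_reports = flt$smq_count,
                    culprit_drugs = nrow(culprits),
                    positive_drugs = length(screened$drugs)),
      exclusions = as.list(excl),
      unmapped_atc = as.list(attr(culprits, "unmapped_atc")),
      outputs = as.list(files))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    manifest
  }, error = function(e) {
    unlink(manifest_path)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
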