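# Descriptive products: demographic distributions, per-PT report and
# culprit counts, top-10 reporting proportions, and the positive-signal
# count distribution. All outputs are tables; plotting is left to the
# user.

#' Construct a summary table
#'
#' An ordered (label, count, percent) table with an explicit denominator.
#' Percentages are recomputed from the counts at construction, rounded
#' half away from zero.
#'
#' @param name Table name.
#' @param labels Character vector of row labels.
#' @param counts Integer vector of row counts.
#' @param denominator Denominator for the percentages.
#' @param digits Decimal places for percentages (1 for proportion tables,
#'   0 for outcome percentages).
#' @param partition `TRUE` if the rows partition the denominator (so
#'   counts sum to it); top-n and multi-membership tables set `FALSE`.
#' @return A `summary_table` (data frame with columns `label`, `count`,
#'   `percent`; attributes `table_name`, `denominator`, `partition`).
#' @export
summary_table <- function(name, labels, counts, denominator,
                          digits = 1, partition = TRUE) {
  stopifnot(length(labels) == length(counts))
  counts <- as.integer(counts)
  if (any(is.na(counts) | counts < 0))
    stop("summary counts must be non-negative integers", call. = FALSE)
  if (partition && length(counts) && sum(counts) != denominator)
    stop(sprintf("rows of '%s' do not partition the denominator (%d != %d)",
                 name, sum(counts), denominator), call. = FALSE)
  out <- data.frame(label = as.character(labels), count = counts,
                    percent = percent_of(counts, denominator, digits),
                    stringsAsFactors = FALSE)
  attr(out, "table_name") <- name
  attr(out, "denominator") <- as.integer(denominator)
  attr(out, "partition") <- partition
  class(out) <- c("summary_table", "data.frame")
  out
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("<summary_table> %s (denominator %d)\n",
              attr(x, "table_name"), attr(x, "denominator")))
  print(as.data.frame(x))
  invisible(x)
}

AGE_DECADE_LABELS <- c("0-10", "11-20", "21-30", "31-40", "41-50", "51-60",
                       "61-70", "71-80", "81-90", ">90")

age_decade_bin <- function(age) {
  bin <- as.character(cut(age, breaks = c(-1e-9, seq(10, 90, 10), 150),
                          labels = AGE_DECADE_LABELS))
  ifelse(is.na(age), "unknown", bin)
}

#' Descriptive summary of a SCAR report set
#'
#' The basic-information products over the SCAR-related reports: yearly
#' report counts, reporter type, top-10 reporting countries, patient sex,
#' age in decade bins (0-10, 11-20, ..., 81-90, >90, unknown), outcomes
#' (a report may carry several; percentages, including the death
#' percentage, use the report count as denominator and are rounded to
#' integer percent), and per-PT report counts.
#'
#' @param scar_set Deduplicated [report_set()] of SMQ-matching reports.
#' @param smq An [smq_definition()].
#' @return Named list of [summary_table()]s: `year`, `reporter`,
#'   `country`, `sex`, `age`, `outcome`, `pt`.
#' @export
descriptive_summary <- function(scar_set, smq = scar_smq()) {
  rep_df <- scar_set$reports
  n <- nrow(rep_df)
  count_of <- function(x, levels) {
    tab <- table(factor(x, levels = levels))
    as.integer(tab)
  }

  yr <- format(rep_df$receive_date, "%Y")
  yr[is.na(yr)] <- "unknown"
  yr_levels <- c(sort(unique(yr[yr != "unknown"])),
                 if (any(yr == "unknown")) "unknown")
  year_tab <- summary_table("year", yr_levels, count_of(yr, yr_levels), n)

  reporter_tab <- summary_table("reporter", REPORTER_LEVELS,
                                count_of(rep_df$reporter, REPORTER_LEVELS), n)

  ctry <- rep_df$country[!is.na(rep_df$country)]
  ctab <- table(ctry)
  cdf <- data.frame(label = if (length(ctab)) names(ctab) else character(0),
                    count = as.integer(ctab), stringsAsFactors = FALSE)
  cdf <- cdf[order(-cdf$count, cdf$label), , drop = FALSE]
  cdf <- utils::head(cdf, 10L)
  country_tab <- summary_table("country", cdf$label, cdf$count, n,
                               partition = FALSE)

  sex_tab <- summary_table("sex", SEX_LEVELS,
                           count_of(rep_df$sex, SEX_LEVELS), n)

  bins <- age_decade_bin(rep_df$age_years)
  age_levels <- c(AGE_DECADE_LABELS, "unknown")
  age_tab <- summary_table("age", age_levels, count_of(bins, age_levels), n)

  olist <- strsplit(rep_df$outcomes, "|", fixed = TRUE)
  oc <- table(factor(unlist(olist), levels = OUTCOME_LEVELS))
  outcome_tab <- summary_table("outcome", OUTCOME_LEVELS, as.integer(oc), n,
                               digits = 0, partition = FALSE)

  em <- scar_event_matrix(scar_set, smq)
  pt_counts <- colSums(em[, -1L, drop = FALSE])
  ord <- order(-pt_counts, smq$narrow_pts$name)
  pt_tab <- summary_table("pt", smq$narrow_pts$name[ord],
                          pt_counts[ord], n, partition = FALSE)

  list(year = year_tab, reporter = reporter_tab, country = country_tab,
       sex = sex_tab, age = age_tab, outcome = outcome_tab, pt = pt_tab)
}

#' Top-n reporting proportions of drugs or ATC classes
#'
#' Within an event scope (the SMQ or one narrow PT), the reporting
#' proportion of a drug is the fraction of in-scope reports naming it as
#' primary suspect; for a second-level ATC class it is the fraction of
#' in-scope reports with at least one primary-suspect drug in the class
#' (distinct-report semantics: a report with two same-class suspects
#' counts once). Drugs carrying several ATC codes contribute to each of
#' their classes.
#'
#' @param scar_set Deduplicated SCAR [report_set()].
#' @param culprits A [build_culprit_list()] result.
#' @param level `"drug"` or `"atc2"`.
#' @param top_n Number of rows kept (>= 1).
#' @param scope `"SMQ"` or a narrow PT name.
#' @param smq An [smq_definition()].
#' @return A [summary_table()] sorted by count descending then label
#'   ascending, truncated to `top_n`; the denominator is the number of
#'   in-scope reports.
#' @export
reporting_proportions <- function(scar_set, culprits,
                                  level = c("drug", "atc2"), top_n = 10L,
                                  scope = "SMQ", smq = scar_smq()) {
  level <- match.arg(level)
  if (!is.numeric(top_n) || top_n < 1)
    stop("top_n must be a positive integer", call. = FALSE)
  em <- scar_event_matrix(scar_set, smq)
  in_scope <- em[, scope_column(scope, smq)]
  denom <- sum(in_scope)
  scope_ids <- scar_set$reports$report_id[in_scope]
  if (level == "drug") {
    labels <- culprits$canonical_name
    counts <- vapply(culprits$report_ids, function(ids)
      sum(ids %in% scope_ids), integer(1))
  } else {
    class_ids <- list()
    for (k in seq_len(nrow(culprits))) {
      classes <- unique(substr(culprits$atc_codes[[k]], 1L, 3L))
      for (cl in classes) {
        class_ids[[cl]] <- c(class_ids[[cl]], culprits$report_ids[[k]])
      }
    }
    labels <- names(class_ids)
    counts <- vapply(class_ids, function(ids)
      sum(unique(ids) %in% scope_ids), integer(1))
  }
  keep <- counts > 0L
  labels <- labels[keep]; counts <- counts[keep]
  ord <- order(-counts, labels)
  ord <- utils::head(ord, top_n)
  summary_table(paste0("top_", level, "_", scope), labels[ord], counts[ord],
                denom, partition = FALSE)
}

#' Distribution of positive-signal counts across culprit drugs
#'
#' Summarizes how many drugs carry 0, 1, 2, ... positive signals out of
#' their 19 (SMQ + 18 PT) disproportionality results, with a Total row.
#' The companion scalar reports the number of drugs with at least one
#' positive signal.
#'
#' @param matrices A [signal_matrix()], or a precomputed histogram data
#'   frame with columns `n_positive` and `n_drugs`.
#' @return A [summary_table()] with rows in descending signal-count order
#'   plus a `Total` row (100.0%); attribute `n_at_least_one` holds the
#'   at-least-one-positive drug count.
#' @export
positive_signal_distribution <- function(matrices) {
  hist <- if (inherits(matrices, "signal_matrix")) {
    screen_positive_drugs(matrices)$histogram
  } else {
    stopifnot(is.data.frame(matrices),
              all(c("n_positive", "n_drugs") %in% names(matrices)))
    matrices[order(-matrices$n_positive), c("n_positive", "n_drugs")]
  }
  total <- sum(hist$n_drugs)
  out <- summary_table("positive_signal_distribution",
                       c(as.character(hist$n_positive), "Total"),
                       c(hist$n_drugs, total),
                       denominator = total, partition = FALSE)
  zero <- hist$n_drugs[hist$n_positive == 0L]
  attr(out, "n_at_least_one") <- total - if (length(zero)) zero else 0L
  out
}
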