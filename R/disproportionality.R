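# Reporting odds ratio disproportionality analysis.
#
# For each culprit drug and each of 19 event scopes (the SMQ level plus the
# 18 narrow PTs) a 2x2 report-level contingency table is formed against the
# background set and the ROR with its 95% Wald confidence interval on the
# log-odds scale is computed:
#
#   ROR = (a/c) / (b/d) = (a*d) / (b*c)
#   95% CI = exp( ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d) )
#
# A positive signal requires the CI lower bound to exceed 1 (strictly) with
# at least three case reports (a >= 3). No multiple-testing adjustment is
# applied; every result row states the convention used.

#' Create a 2x2 contingency table for disproportionality analysis
#'
#' Report-level counts for one (drug, event scope) pair: `a` reports with
#' the drug (primary suspect) and the event, `b` with the drug but not the
#' event, `c` with the event but not the drug, `d` with neither. The four
#' cells sum to the size of the background report set.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("contingency cells must be non-negative integers", call. = FALSE)
  structure(as.list(stats::setNames(as.integer(round(cells)),
                                    c("a", "b", "c", "d"))),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("event", "other events"),
                              c("drug", "other drugs")))
  print(m)
  invisible(x)
}

# Vectorized ROR + 95% CI over parallel cell vectors. With
# zero_cell = "none", any zero cell makes the result not evaluable (ROR and
# CI are NA); with "haldane", 0.5 is added to every cell of tables that
# contain a zero (Haldane-Anscombe correction) and the result is flagged
# `corrected`. 1.96 is the fixed 95% normal quantile of the method.
ror_cells <- function(a, b, c, d, zero_cell = c("none", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  if (any(c(a, b, c, d) < 0)) stop("negative contingency cell", call. = FALSE)
  has_zero <- a == 0 | b == 0 | c == 0 | d == 0
  corrected <- rep(FALSE, length(a))
  if (zero_cell == "none") {
    evaluable <- !has_zero
    aa <- a; bb <- b; cc <- c; dd <- d
  } else {
    evaluable <- rep(TRUE, length(a))
    corrected <- has_zero
    shift <- ifelse(has_zero, 0.5, 0)
    aa <- a + shift; bb <- b + shift; cc <- c + shift; dd <- d + shift
  }
  ror <- ci_low <- ci_high <- rep(NA_real_, length(a))
  i <- evaluable
  if (any(i)) {
    ror[i] <- (aa[i] * dd[i]) / (bb[i] * cc[i])
    half <- 1.96 * sqrt(1 / aa[i] + 1 / bb[i] + 1 / cc[i] + 1 / dd[i])
    ci_low[i] <- exp(log(ror[i]) - half)
    ci_high[i] <- exp(log(ror[i]) + half)
  }
  data.frame(ror = ror, ci_low = ci_low, ci_high = ci_high,
             evaluable = evaluable, corrected = corrected)
}

#' Compute the reporting odds ratio with 95% confidence interval
#'
#' `ROR = (a*d)/(b*c)`; the confidence interval is the Wald interval on the
#' log-odds-ratio scale, `exp(ln ROR +/- 1.96 * sqrt(1/a+1/b+1/c+1/d))`.
#' By default a table containing any zero cell is *not evaluable* (ROR and
#' CI are `NA`); the optional Haldane-Anscombe mode adds 0.5 to every cell
#' of such tables and flags the result as `corrected`.
#'
#' @param t A [contingency_table()].
#' @param zero_cell `"none"` (default: zero cells make the result not
#'   evaluable) or `"haldane"` (+0.5 to all cells of zero-containing
#'   tables).
#' @return A list with `ror`, `ci_low`, `ci_high`, `evaluable`,
#'   `corrected`.
#' @examples
#' compute_ror(contingency_table(10, 90, 100, 9900))  # ROR = 11
#' @export
compute_ror <- function(t, zero_cell = c("none", "haldane")) {
  stopifnot(inherits(t, "contingency_table"))
  res <- ror_cells(t$a, t$b, t$c, t$d, zero_cell)
  as.list(res[1, ])
}

#' Classify a disproportionality result as a positive signal
#'
#' The positive-signal criterion: the lower limit of the 95% CI of the ROR
#' strictly exceeds 1 and there are at least three case reports
#' (`a >= 3`). The case-count gate always applies to the raw `a`, even
#' under the Haldane-Anscombe mode. Non-evaluable results are negative.
#'
#' @param res A result from [compute_ror()] (or any list with `ci_low` and
#'   `evaluable`).
#' @param a Raw case count of the underlying table.
#' @return `TRUE` for a positive signal, else `FALSE`.
#' @export
classify_signal <- function(res, a) {
  isTRUE(res$evaluable) && !is.na(res$ci_low) && res$ci_low > 1 && a >= 3
}

# Positions (row indices into rs$reports) of reports naming each canonical
# drug as primary suspect, after ingredient-map normalization. Returns a
# list keyed by canonical name covering `drugs`.
suspect_rows_by_drug <- function(rs, drugs, imap = ingredient_map()) {
  dr <- rs$drugs
  sus <- dr[dr$role == "primary_suspect", , drop = FALSE]
  norm <- normalize_name(sus$generic_name, imap)
  ok <- norm$reason == ""
  rows <- match(sus$rec[ok], rs$reports$rec)
  canon <- norm$canonical[ok]
  by <- lapply(split(rows, canon), unique)
  out <- stats::setNames(vector("list", length(drugs)), drugs)
  for (dname in drugs) out[[dname]] <- by[[dname]] %||% integer(0)
  out
}

#' Build the contingency table for one drug and one event scope
#'
#' The counting unit is the report. A report counts toward "with drug" if
#' any of its primary-suspect mentions normalizes to the given canonical
#' name, and toward "with event" if it matches the SMQ (scope `"SMQ"`) or
#' the given narrow PT. The background set is the full report collection
#' (SCAR and non-SCAR alike); every report falls in exactly one cell.
#'
#' @param all_reports Deduplicated [report_set()] forming the background.
#' @param drug Canonical ingredient name.
#' @param scope `"SMQ"` or one of the narrow PT names of `smq`.
#' @param smq An [smq_definition()].
#' @param imap An [ingredient_map()].
#' @return A [contingency_table()].
#' @export
build_contingency <- function(all_reports, drug, scope = "SMQ",
                              smq = scar_smq(), imap = ingredient_map()) {
  em <- scar_event_matrix(all_reports, smq)
  col <- scope_column(scope, smq)
  event <- em[, col]
  rows <- suspect_rows_by_drug(all_reports, drug, imap)[[drug]]
  with_drug <- rep(FALSE, nrow(all_reports$reports))
  with_drug[rows] <- TRUE
  contingency_table(a = sum(with_drug & event),
                    b = sum(with_drug & !event),
                    c = sum(!with_drug & event),
                    d = sum(!with_drug & !event))
}

scope_column <- function(scope, smq) {
  if (identical(scope, SMQ_SCOPE_LABEL) || identical(scope, smq$name))
    return(1L)
  j <- match(normalize_pt(scope), normalize_pt(smq$narrow_pts$name))
  if (is.na(j))
    stop("unknown event scope: ", scope, call. = FALSE)
  1L + j
}

#' Compute the 19-signal matrix for every culprit drug
#'
#' For each culprit drug, 19 disproportionality results: the SMQ level
#' first, then the 18 narrow PTs in SMQ table order. Cell counts come from
#' the chosen background set; `n_positive` counts the positive signals per
#' drug. Output order is deterministic: drugs as sorted in the culprit
#' list, scopes in table order.
#'
#' @param all_reports Deduplicated [report_set()] (the full collection the
#'   SCAR subset was drawn from).
#' @param culprits A [build_culprit_list()] result.
#' @param smq An [smq_definition()].
#' @param imap The [ingredient_map()] used to build the culprit list.
#' @param zero_cell Zero-cell handling, see [compute_ror()].
#' @param background `"faers_background"` (default: b/c/d counted against
#'   the full collection) or `"scar_only"` (background restricted to the
#'   SMQ-matching subset).
#' @return A `signal_matrix`: data frame with 19 rows per drug and columns
#'   `drug`, `scope`, `a`, `b`, `c`, `d`, `ror`, `ci_low`, `ci_high`,
#'   `evaluable`, `corrected`, `positive`, `n_positive`. Attribute
#'   `conventions` records the background, zero-cell mode and the absence
#'   of any multiple-testing adjustment.
#' @export
signal_matrix <- function(all_reports, culprits, smq = scar_smq(),
                          imap = ingredient_map(),
                          zero_cell = c("none", "haldane"),
                          background = c("faers_background", "scar_only")) {
  zero_cell <- match.arg(zero_cell)
  background <- match.arg(background)
  em <- scar_event_matrix(all_reports, smq)
  if (background == "scar_only") {
    bg <- subset_report_set(all_reports, which(em[, 1L]))
    em <- em[em[, 1L], , drop = FALSE]
  } else {
    bg <- all_reports
  }
  n_bg <- nrow(bg$reports)
  scopes <- c(SMQ_SCOPE_LABEL, smq$narrow_pts$name)
  event_totals <- colSums(em)
  drugs <- culprits$canonical_name
  rows_by_drug <- suspect_rows_by_drug(bg, drugs, imap)
  blocks <- lapply(drugs, function(dname) {
    rows <- rows_by_drug[[dname]]
    nd <- length(rows)
    a <- if (nd) colSums(em[rows, , drop = FALSE]) else numeric(ncol(em))
    b <- nd - a
    cc <- event_totals - a
    d <- n_bg - nd - cc
    res <- ror_cells(a, b, cc, d, zero_cell)
    positive <- res$evaluable & !is.na(res$ci_low) & res$ci_low > 1 & a >= 3
    data.frame(drug = dname, scope = scopes,
               a = as.integer(a), b = as.integer(b), c = as.integer(cc),
               d = as.integer(d), res, positive = positive,
               n_positive = sum(positive), stringsAsFactors = FALSE)
  })
  out <- if (length(blocks))
    do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(drug = character(), scope = character(), a = integer(),
                      b = integer(), c = integer(), d = integer(),
                      ror = numeric(), ci_low = numeric(),
                      ci_high = numeric(), evaluable = logical(),
                      corrected = logical(), positive = logical(),
                      n_positive = integer(), stringsAsFactors = FALSE)
  }
  attr(out, "conventions") <- list(
    background = background, zero_cell = zero_cell,
    ci_quantile = 1.96, min_cases = 3L,
    multiple_testing_adjustment = "none")
  class(out) <- c("signal_matrix", "data.frame")
  out
}

#' Screen drugs with at least one positive signal
#'
#' @param matrices A [signal_matrix()].
#' @return List with `drugs` (canonical names with `n_positive >= 1`,
#'   preserving the matrix's drug order) and `histogram` (data frame of
#'   `n_positive` value vs. number of drugs, descending), the input to the
#'   positive-signal distribution table.
#' @export
screen_positive_drugs <- function(matrices) {
  stopifnot(inherits(matrices, "signal_matrix"))
  per_drug <- matrices[!duplicated(matrices$drug),
                       c("drug", "n_positive"), drop = FALSE]
  counts <- table(factor(per_drug$n_positive))
  vals <- as.integer(names(counts))
  ord <- order(-vals)
  list(drugs = per_drug$drug[per_drug$n_positive >= 1L],
       histogram = data.frame(n_positive = vals[ord],
                              n_drugs = as.integer(counts)[ord]))
}
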