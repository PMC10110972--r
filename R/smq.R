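# SCAR report identification via the narrow scope of the severe cutaneous
# adverse reactions Standardized MedDRA Query (SMQ 20000020, MedDRA 23.0).

# The 18 narrow-scope preferred terms, in canonical table order. Matching is
# by normalized PT name (openFDA carries PT strings, not codes); the MedDRA
# codes are retained for documentation and the shipped SMQ resource.
SCAR_NARROW_PTS <- data.frame(
  name = c("Acute generalized exanthematous pustulosis",
           "Bullous hemorrhagic dermatosis",
           "Cutaneous vasculitis",
           "Dermatitis bullous",
           "Dermatitis exfoliative",
           "Dermatitis exfoliative generalized",
           "Drug reaction with eosinophilia and systemic symptoms",
           "Epidermal necrosis",
           "Erythema multiforme",
           "Erythrodermic atopic dermatitis",
           "Exfoliative rash",
           "Oculomucocutaneous syndrome",
           "SJS–TEN overlap",
           "Skin necrosis",
           "Stevens–Johnson syndrome",
           "Target skin lesion",
           "Toxic epidermal necrolysis",
           "Toxic skin eruption"),
  code = c(10048799L, 10083809L, 10011686L, 10012441L, 10012455L, 10012456L,
           10073508L, 10059284L, 10015218L, 10082985L, 10064579L, 10030081L,
           10083164L, 10040893L, 10042033L, 10081998L, 10044223L, 10057970L),
  stringsAsFactors = FALSE)

SMQ_SCOPE_LABEL <- "SMQ"

#' Create an SMQ definition
#'
#' A Standardized MedDRA Query restricted to its narrow scope: the set of
#' preferred terms highly likely to represent the clinical concept. Users
#' can supply their own PT table to target a different SMQ.
#'
#' @param name SMQ name.
#' @param smq_code Integer SMQ-level MedDRA code.
#' @param narrow_pts Data frame with columns `name` (PT string) and `code`
#'   (8-digit MedDRA code).
#' @return An `smq_definition` object.
#' @export
smq_definition <- function(name, smq_code, narrow_pts) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.data.frame(narrow_pts),
            all(c("name", "code") %in% names(narrow_pts)))
  if (any(!nzchar(narrow_pts$name)))
    stop("PT names must be nonempty", call. = FALSE)
  code <- as.integer(narrow_pts$code)
  if (any(is.na(code) | code < 10000000L | code > 99999999L))
    stop("MedDRA PT codes must be 8-digit integers", call. = FALSE)
  if (anyDuplicated(normalize_pt(narrow_pts$name)))
    stop("duplicate PT names in narrow scope", call. = FALSE)
  structure(list(name = name, smq_code = as.integer(smq_code),
                 narrow_pts = data.frame(name = narrow_pts$name, code = code,
                                         stringsAsFactors = FALSE)),
            class = "smq_definition")
}

#' The built-in SCAR SMQ (narrow scope)
#'
#' The severe cutaneous adverse reactions SMQ (code 20000020) as defined in
#' MedDRA 23.0: exactly 18 narrow-scope preferred terms, from acute
#' generalized exanthematous pustulosis to toxic skin eruption. This
#' constant defines what counts as a SCAR-related report throughout the
#' package. The same table ships as a tab-delimited resource at
#' `system.file("extdata", "scar_smq_narrow.tsv", package = "scarsignal")`.
#'
#' @return An [smq_definition()] with 18 narrow PTs.
#' @examples
#' smq <- scar_smq()
#' nrow(smq$narrow_pts)  # 18
#' @export
scar_smq <- function() {
  smq_definition("Severe cutaneous adverse reactions (SMQ)", 20000020L,
                 SCAR_NARROW_PTS)
}

#' @export
print.smq_definition <- function(x, ...) {
  cat(sprintf("<smq_definition> %s [code %d], %d narrow PT(s)\n",
              x$name, x$smq_code, nrow(x$narrow_pts)))
  invisible(x)
}

#' Match a report's reactions against an SMQ's narrow PTs
#'
#' Matching is on the normalized PT name: case-insensitive, surrounding
#' whitespace stripped, internal whitespace collapsed, and en-/em-dashes
#' unified with hyphens (so "SJS-TEN overlap" matches the en-dash spelling).
#' An empty result means the report is not related to the SMQ concept.
#'
#' @param report An [adverse_event_report()].
#' @param smq An [smq_definition()]; defaults to the SCAR SMQ.
#' @return Character vector of matched PT names in the SMQ's canonical
#'   spelling (subset of `smq$narrow_pts$name`).
#' @export
match_scar_pts <- function(report, smq = scar_smq()) {
  stopifnot(inherits(report, "adverse_event_report"))
  keys <- normalize_pt(smq$narrow_pts$name)
  hit <- keys %in% normalize_pt(report$reactions)
  smq$narrow_pts$name[hit]
}

# n x (1 + k) logical matrix of event flags for every record of rs:
# column 1 is the SMQ level (any narrow PT), remaining columns one per PT
# in smq table order. Row order follows rs$reports.
scar_event_matrix <- function(rs, smq = scar_smq()) {
  keys <- normalize_pt(smq$narrow_pts$name)
  n <- nrow(rs$reports)
  m <- matrix(FALSE, nrow = n, ncol = 1L + length(keys),
              dimnames = list(NULL, c(SMQ_SCOPE_LABEL, smq$narrow_pts$name)))
  if (n == 0L || nrow(rs$reactions) == 0L) return(m)
  rec_index <- match(rs$reactions$rec, rs$reports$rec)
  pt_index <- match(normalize_pt(rs$reactions$pt), keys)
  ok <- !is.na(pt_index)
  if (any(ok)) {
    m[cbind(rec_index[ok], 1L + pt_index[ok])] <- TRUE
    m[, 1L] <- rowSums(m[, -1L, drop = FALSE]) > 0L
  }
  m
}

#' Filter a report set down to SMQ-related reports
#'
#' @param rs A deduplicated [report_set()].
#' @param smq An [smq_definition()]; defaults to the SCAR SMQ.
#' @return A list with components:
#'   \describe{
#'     \item{scar_set}{`report_set` of the reports matching at least one
#'       narrow PT (order preserved).}
#'     \item{pt_report_counts}{Named integer vector, one entry per narrow
#'       PT in table order: the number of matching reports naming that PT.
#'       A report matching k PTs contributes 1 to each of the k counts.}
#'     \item{smq_count}{Number of SMQ-level reports, i.e. the size of
#'       `scar_set` (a multi-PT report counts once).}
#'   }
#' @export
filter_scar_reports <- function(rs, smq = scar_smq()) {
  em <- scar_event_matrix(rs, smq)
  keep <- em[, 1L]
  pt_counts <- colSums(em[, -1L, drop = FALSE])
  storage.mode(pt_counts) <- "integer"
  scar_set <- subset_report_set(rs, which(keep))
  list(scar_set = scar_set, pt_report_counts = pt_counts,
       smq_count = n_reports(scar_set))
}

# Row-subset a report_set by positions into rs$reports (order preserved,
# records renumbered 1..m).
subset_report_set <- function(rs, rows) {
  keep_recs <- rs$reports$rec[rows]
  rep_out <- rs$reports[rows, , drop = FALSE]
  rep_out$rec <- seq_along(rows)
  rx_map <- match(rs$reactions$rec, keep_recs)
  rx_out <- rs$reactions[!is.na(rx_map), , drop = FALSE]
  rx_out$rec <- rx_map[!is.na(rx_map)]
  dr_map <- match(rs$drugs$rec, keep_recs)
  dr_out <- rs$drugs[!is.na(dr_map), , drop = FALSE]
  dr_out$rec <- dr_map[!is.na(dr_map)]
  rownames(rep_out) <- rownames(rx_out) <- rownames(dr_out) <- NULL
  new_report_set(rep_out, rx_out, dr_out, rs$provenance, rs$skip_tally)
}
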