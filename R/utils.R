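# Shared string/number helpers used across the pipeline.

#' Round half away from zero
#'
#' Commercial rounding as used for all displayed percentages: ties go away
#' from zero rather than to even (the behaviour of base [round()]).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded to `digits` places.
#' @examples
#' round_half_away(80.45, 1)  # 80.5
#' round_half_away(0.5, 0)    # 1
#' @export
round_half_away <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Percentage of a count over a denominator
#'
#' Computes `100 * count / denominator` rounded half away from zero. A zero
#' denominator yields 0 rather than NaN so that degenerate (empty) summary
#' tables stay well defined.
#'
#' @param count Numeric vector of counts.
#' @param denominator Scalar denominator.
#' @param digits Decimal places kept (1 for proportion tables, 0 for
#'   outcome percentages).
#' @return Numeric vector of percentages.
#' @export
percent_of <- function(count, denominator, digits = 1) {
  if (denominator == 0) return(rep(0, length(count)))
  round_half_away(100 * count / denominator, digits)
}

#' Canonicalize a drug name
#'
#' Lowercases, trims surrounding whitespace and collapses internal runs of
#' whitespace to single spaces. This is the key form used by ingredient
#' maps and the identity fallback for unmapped generic names.
#'
#' @param x Character vector of raw names.
#' @return Character vector of canonical-form names.
#' @export
canonicalize_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Normalize a MedDRA preferred-term string for matching
#'
#' Case-insensitive, surrounding whitespace stripped, internal whitespace
#' collapsed, en-/em-dashes unified with plain hyphens. This is the key
#' form used when matching reaction strings against an SMQ's narrow PTs.
#'
#' @param x Character vector of PT strings.
#' @return Character vector of normalized keys.
#' @export
normalize_pt <- function(x) {
  x <- gsub("–|—", "-", x)
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}
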