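---
title: "Disproportionality analysis of severe cutaneous adverse reaction reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality analysis of severe cutaneous adverse reaction reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarsignal)
```

## The problem

Severe cutaneous adverse reactions (SCARs) — Stevens–Johnson syndrome
(SJS), toxic epidermal necrolysis (TEN), drug reaction with eosinophilia
and systemic symptoms (DRESS), acute generalized exanthematous pustulosis
(AGEP) and related conditions — are rare but life-threatening,
immunologically mediated drug reactions. Because the first mandatory step
in managing a SCAR patient is identifying and withdrawing the culprit
drug, clinicians need a broad, quantitative picture of which drugs are
reported with these reactions and how strong each drug–reaction
association is. Spontaneous adverse-event reporting databases are the
standard post-marketing source for this kind of signal detection, and
`scarsignal` implements the complete analysis pipeline over such data:
SCAR report identification, culprit-drug extraction, reporting odds ratio
(ROR) disproportionality, positive-signal screening, and descriptive
summarization.

## Case definition: the SCAR SMQ narrow scope

A report is considered SCAR-related when at least one of its reaction
preferred terms (PTs) belongs to the narrow scope of the SCAR
Standardized MedDRA Query (SMQ code 20000020, MedDRA 23.0): 18 PTs, from
acute generalized exanthematous pustulosis (10048799) to toxic skin
eruption (10057970). Narrow-scope terms are those highly likely to
represent the condition; broad-scope terms are excluded by construction.

Matching is by normalized PT *name* (case-insensitive, whitespace
collapsed, en-dashes unified with hyphens), not by MedDRA code, because
the openFDA reaction field carries PT strings. The code table is retained
for documentation and ships as a text resource
(`system.file("extdata", "scar_smq_narrow.tsv", package = "scarsignal")`)
so users can substitute another SMQ via `smq_definition()`.

```{r}
smq <- scar_smq()
head(smq$narrow_pts, 4)
```

## The disproportionality model

For one drug and one event scope (the whole SMQ, or one narrow PT), every
report in the background set falls into exactly one cell of a 2×2 table:
`a` (drug and event), `b` (drug, no event), `c` (event, no drug), `d`
(neither). The counting unit is the report; a report "has the drug" when
any of its *primary-suspect* mentions normalizes to the drug, and
"has the event" when it matches the scope. The ROR and its 95% CI are

$$\mathrm{ROR} = \frac{a/c}{b/d} = \frac{ad}{bc}, \qquad
\mathrm{CI}_{95\%} = e^{\ln \mathrm{ROR} \pm 1.96\sqrt{\frac1a+\frac1b+\frac1c+\frac1d}}.$$

A **positive signal** requires the CI lower bound to exceed 1 *strictly*
with at least three case reports ($a \ge 3$). Each culprit drug receives
19 results: one at the SMQ level and one per narrow PT.

Numerical and design choices, all surfaced in the output metadata:

* **Zero cells.** A table with any zero cell is *not evaluable* (and
  therefore negative) by default, rather than silently corrected. An
  optional Haldane–Anscombe mode (`zero_cell = "haldane"`) adds 0.5 to
  every cell of zero-containing tables and flags those rows `corrected`.
  The $a \ge 3$ gate always applies to the raw count.
* **Background set.** `b`, `c`, `d` are counted against the entire report
  collection (`faers_background`), mirroring a comparison of the drug
  against all other drugs in the database. A `scar_only` alternative
  restricts the background to the SMQ-matching subset; it is provided as
  a convention switch, degenerate at the SMQ level by construction.
* **1.96** is hard-coded as the 95% normal quantile — it is part of the
  method's definition, not recomputed at higher precision.
* **No multiple-testing adjustment** is applied across the 19 signals per
  drug (or across drugs); the output manifest states this prominently.

## Culprit-drug extraction and normalization

Only primary-suspect mentions (openFDA `drugcharacterization = 1`) count
as culprit evidence. Three exclusions apply, each tallied and never
silent: mentions with missing generic names; names mapped to the
`AMBIGUOUS` marker of the user-supplied ingredient map; and within-report
duplicates of the same canonical ingredient (a report contributes an
ingredient once). The ingredient map replaces the manual pharmacist
integration of salt forms that a production analysis would use; unmapped
names fall through as their canonicalized form, so an empty map is the
identity. The "duplicated" exclusion is read as within-report set
semantics — the across-list reading would conflate distinct drugs.
Ingredients without an ATC entry are kept (logged as unmapped) so drug
totals are conserved; drugs with several ATC codes contribute to each of
their second-level classes in class summaries, which can multi-count a
drug across classes but never a report within one class
(distinct-report semantics).

Duplicate *reports* are resolved before any counting: among records
sharing a report id the one with the latest receive date survives, ties
keeping the record listed last. Spontaneous-report databases do contain
such duplicates, and the rule is deterministic and idempotent; it is a
documented convention of this package, since no universal standard
exists.

## The synthetic-report generator

Real spontaneous-report databases cannot ship with a package, so
`generate_reports()` produces report sets with *known* ground truth. The
generative model:

1. Each of `n_reports` base reports draws one primary-suspect drug from
   the catalog (probabilities sum to 1).
2. Each narrow PT appears independently with odds
   `baseline_pt_odds[pt] × multiplier(drug, pt)`; an SMQ-scope effect
   multiplies the odds of all 18 PTs. Odds, not probabilities, are
   multiplied, so the ROR estimand approaches the configured multiplier
   as baseline odds shrink.
3. Filler (non-SCAR) reactions are drawn independently; a guaranteed
   filler prevents empty reaction lists, which the reader would skip.
4. Demographics (sex, age decade, reporter, country, year, outcomes) are
   sampled independently of drugs and reactions — the analysis performs
   no adjustment, so no confounding is simulated by default.
5. With `missing_name_probability` the suspect's generic name is blanked
   (the raw product name remains, keeping the mention non-empty); with
   `duplicate_probability` exact duplicate submissions reusing an
   existing report id are appended, exercising deduplication.

`default_simulation_config()` encodes a study-scale null: 20 catalog
drugs spanning the classes most reported with SCARs, mildly skewed use
probabilities, and baseline PT odds making SJS the most frequent narrow
PT while keeping the SCAR-related fraction under one percent of all
reports — the order of magnitude seen in large databases, where SCARs
are roughly half a percent of reports, with health professionals
reporting ~78%, more female than male patients, ages peaking in the
seventh decade, and ~10% fatal outcomes. These defaults *are* the study
conditions used by the package's tests; they were fixed from those
field-level descriptions, not tuned to test outcomes.

`ground_truth()` tabulates the injected multipliers per (drug, scope).
When only PT-level effects are injected, no single SMQ-level odds
multiplier exists; the SMQ row then carries the marginal odds ratio of
"any narrow PT" implied by the model, computed by enumeration and
flagged `induced`. `expected_case_counts()` gives the analytic
expectation of each `a` cell, used to decide which pairs are informative
enough to evaluate in calibration studies.

What the generator deliberately does **not** emulate: reporting trends
over time (Weber effect), notoriety bias, confounding by indication or
comorbidity, and correlated reactions beyond the shared-drug mechanism.
Passing tests therefore demonstrate the pipeline's counting and
inferential logic under a clean generative model, not robustness to
those real-data biases — which the disproportionality method itself does
not address.

## Validation design

The test suite checks the pipeline at three levels, with problem sizes
chosen to keep a full run within a few minutes on one CPU:

* **Worked-cell arithmetic.** The rounding and aggregation rules
  (half-away-from-zero to one decimal for proportion tables, integer
  percent for outcomes) reproduce published-style summary cells exactly,
  e.g. 981 of 1,219 drugs → 80.5%, and a 17-bin positive-signal
  histogram → 776 drugs with at least one positive signal.
* **Oracle equivalence.** On datasets of up to 1,000 reports, every cell
  of every contingency table matches an independent per-record recount,
  and every positive flag matches re-application of the signal criterion
  from scratch. The ROR/CI formulas match a textbook odds-ratio
  computation to 1e-12 relative tolerance on 1,000 random tables.
* **Statistical behaviour.** Under the global null (all multipliers 1,
  20 drugs, 200,000 reports, 20 seeds), the positive-signal rate among
  (drug, scope) pairs with expected $a \ge 3$ stays at or below 5% —
  consistent with the nominal one-sided 2.5% of the CI rule plus the
  case-count gate. An injected SMQ-scope multiplier of 5 with expected
  $a \ge 10$ is flagged positive in at least 95% of seeds.

`scripts/acceptance.R` re-runs the same computations from scratch on the
installed package and writes the headline numbers as JSON.

## Limitations

The ROR is a reporting association, not a risk estimate: it cannot
establish causality, is sensitive to the background mix of drugs and
events, and carries all the biases of voluntary reporting. The package
deliberately implements only the unadjusted report-level ROR with Wald
CIs — no PRR, Bayesian shrinkage (IC/EBGM), stratification, or
multiplicity control — because that is the method under study; users
needing shrinkage estimators should treat these results as a first-pass
screen.
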