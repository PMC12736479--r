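---
title: "Methods: claims-based screening for potentially inappropriate medications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based screening for potentially inappropriate medications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pimscreen)
```

## The screening problem

Explicit prescribing-quality indicator sets such as the Beers Criteria
list medications whose risks generally outweigh their benefits in adults
aged 65 and over. Applying them to administrative dispensing claims is
attractive — claims cover whole populations — but claims carry no
diagnoses, prescribed posology or indication. `pimscreen` therefore
implements only the claims-decidable subset of the 2019 criteria:
drugs to avoid, drugs to use with caution, and strong anticholinergics.
Criteria that hinge on clinical data (drug–disease interactions, the
drug–drug interaction table, renal-function dose adjustments) are out of
scope by design, and results must be read as *potentially* inappropriate
dispensing patterns that merit clinical review, never as verdicts on
individual therapy.

The unit of observation is a reimbursed dispensation, not a prescription
order, and every condition is expressed over dispensing dates and ATC
codes. The catalog is data, not code (YAML, versioned), so criteria
updates or national adaptations (we retain ticlopidine, removed from the
2019 update only because it left the US market, as it remains reimbursed
in Italy) are file edits.

## Condition semantics and their rationale

For one patient and one rule, with the rule's ATC prefixes selecting the
matching dispensations:

* **Use beyond 8 weeks** (PPIs). Consecutive distinct dispensing dates are
  screened for a gap strictly greater than 56 days and at most 180 days.
  The lower bound is strict and the upper inclusive, and only consecutive
  pairs count — no exposure-episode construction with grace periods, which
  is the common alternative in drug-utilization research. The literal
  pairwise rule is simpler, reproducible, and what the test oracle
  enumerates; an episode-based variant would change counts and is noted
  as a limitation, not silently substituted. The event is attributed to
  the year of the later date of the first qualifying pair.
* **Co-dispensing** (NSAID with a vitamin K antagonist). Two drug classes
  dispensed within 90 days of each other ("3 months"; a fixed 90-day
  inclusive window keeps the predicate free of calendar ambiguity). The
  event year is the year of the index-drug date.
* **Chronic use**. Five or more dispensing events of a drug (distinct
  dates, ATC level 5) within a calendar year — the threshold commonly
  used in drug-utilization research. Same-day duplicate rows, which in
  claims usually encode multiple packages, collapse to one event so that
  pack-level duplication cannot fabricate chronic use; the raw rows are
  preserved as event triggers.
* **Dose limits** (aspirin > 325 mg/day). Claims carry no prescribed
  daily dose, so the unit dose of the dispensed product is used as a
  proxy, taken from an explicit `unit_dose_mg` column or parsed from the
  medication name (first number followed by `mg`/`g`). The comparison is
  strict. A matching dispensation with no recoverable unit dose makes the
  rule indeterminate for that patient-year: it is skipped and logged
  (`attr(events, "skipped")`), never guessed.
* **Route and form** are keyword-derived from medication names
  (multilingual whole-token dictionary; `UNKNOWN` only when nothing
  matches), since injectable or topical presentations can change a
  rule's relevance.

Detection (`detect_all()`) emits at most one event per
(patient, rule, year) and is pure and deterministic: its output is the
union of per-(patient, rule, year) evaluations, ordered by patient, year
and rule id. Rules of the same reporting group share a label (e.g. both
NSAID rules), and frequency tables group by label, which realizes ATC
level-4 class grouping for class-wide rules.

## Cohort rules

Eligibility is assessed at the window end (default 2018-01-01 to
2021-12-31): completed age ≥ 65 at that date (so patients turning 65
during the window qualify), at least one in-window dispensation, and no
registered death on or before the window end. Ages and age strata
(65–74, 75–84, ≥ 85) are computed once, at the window end. Yearly
prevalence denominators contain every eligible patient with a
dispensation in that calendar year; we deliberately include
pre-65th-birthday dispensations of patients who qualify by window end,
consistent with the single end-of-study age computation (the alternative
— per-year age gating — is a documented sensitivity choice, not the
default).

## Reporting conventions

Percentages are rounded half-up at one decimal; R's default half-to-even
rounding does not reproduce published drug-utilization tables. Quartiles
use linear interpolation between order statistics (`quantile()` type 7);
Tukey hinges are the obvious alternative and would differ at small n, so
the choice is fixed and documented. "PIMs per patient" counts trigger
dispensations (not distinct rules), the convention that matches
claims-level medians of roughly seven per patient-year in this field.
Ranked tables break count ties by label, ascending, so output is fully
deterministic.

## The synthetic-data generator

`generate_claims()` emulates the record schema and study conditions the
screening assumes, with a single seeded RNG stream and fixed draw order
(all demographics first, then per-patient dispensing in patient order):

* demographics: sex male with probability 0.40; age at window end from a
  triangular distribution on 65–100 with mode 70, whose median (≈ 77)
  matches the age structure typical of older claims populations; a death
  date inside the window with probability 0.05, exercising the exclusion
  path;
* background dispensing: five non-catalog drugs (analgesic, metformin,
  ACE inhibitor, statin, antibiotic) at Poisson yearly rates near one,
  so denominators resemble real "patients with any dispensation" counts;
* injected patterns, independently per patient, each satisfying its rule
  by construction: a PPI pair 60–170 days apart inside one year; chronic
  paroxetine (5–8 roughly monthly dates in one year); sulfonylurea,
  ticlopidine (4–8 dates, matching the reported median of ~6
  dispensations/year) and furosemide dispensings; an NSAID/warfarin pair
  within 90 days; and a multi-anticholinergic patient with k (default 3)
  distinct chronic agents in the final year. Default rates (PPI 0.45,
  furosemide 0.30, paroxetine 0.05, sulfonylurea 0.04, co-dispensing
  0.02, ticlopidine 0.015, multi-anticholinergic 0.002) echo the relative
  frequencies reported for regional claims, with PPIs and furosemide
  dominating their categories;
* specificity controls (rates default 0): a PPI pair with gap ≤ 56 days
  and an NSAID at 4 dispensations/year — patterns that must never be
  detected.

Ground truth is computed at generation time by running the package's own
condition predicates over each eligible patient's assembled history, so
it stays exact under arbitrary pattern combinations (e.g. a ticlopidine
patient who also receives the co-dispensing pair). To avoid circularity,
the test suite re-derives events with an independent brute-force
evaluator — explicit loops, exhaustive pair enumeration, its own prefix
matcher — and requires exact agreement, both on 200 randomized
micro-cohorts and on generator output.

What the generator does *not* emulate: the full national drug mix beyond
the headline drugs, regional heterogeneity, seasonality, or
prescription-to-dispensation slippage. Passing end-to-end tests therefore
demonstrates correctness of the screening logic under the stated
conditions, not calibration of absolute prevalence against any real
region.

## Numerical and degenerate-input choices

* Dates are `Date` integers; all gap arithmetic is exact integer day
  counts, so results are platform-independent.
* Half-up rounding adds a machine-epsilon guard before `floor(x + 0.5)`
  so ratios of integers whose decimal expansion sits one ulp below .5 in
  binary round as printed.
* Zero or one dispensing date makes every gap predicate false; empty
  cohorts, empty event sets and header-only files flow through as empty
  tables, not errors; a zero denominator is an error for `percent()` but
  yields an `NA` cell in prevalence tables (a year with no users has no
  defined prevalence).
* Ingest is strict by default (fail fast); lenient mode skips malformed
  rows and returns them with row numbers. Duplicate death records keep
  the earliest date. Inconsistent birth dates for one patient id are
  always fatal — silently picking one would corrupt age strata.
* ACB lookup is longest-prefix-wins so a specific agent can override a
  class score; scores are clamped to the defined set {0, 1, 2, 3} by
  catalog validation.

## Problem sizes

The test suite validates the engine on 200 randomized micro-cohorts
(3–10 patients, ≤ 5 drugs each) against the brute-force oracle, and
end-to-end on synthetic cohorts of 250–2000 patients (the 2000-patient
run checks exact ground-truth recovery; a 10,000-patient draw checks the
demographic targets). These sizes give tight binomial bands (± 2 SE ≈
± 1 percentage point on the sex share at n = 10,000) while keeping the
whole suite under two minutes on one core; the engine itself scales
linearly in patients and was sized for regional databases of 10⁵–10⁶
patients.

## Known limitations

* Dispensing ≠ ingestion: exposure misclassification is inherent to
  claims.
* The literal consecutive-gap rule for "> 8 weeks" can miss continuous
  use recorded as many short gaps (all ≤ 56 days ... none qualifying) and
  flags isolated refill pairs; it is kept because it is the transparent,
  stated operationalization.
* Unit dose as daily-dose proxy under-detects multi-unit regimens and
  over-detects split tablets.
* The shipped catalog covers the drugs and classes that dominate
  reported PIM rankings; it is deliberately extensible rather than a
  complete Beers reproduction, and completeness of any local adaptation
  is the user's responsibility.
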