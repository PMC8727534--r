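---
title: "Methods: disproportionality screening of spontaneous reports"
author: "faerspv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faerspv)
options(faerspv.quiet = TRUE)
```

## The data model and its assumptions

Spontaneous reporting systems such as FAERS collect voluntary reports: one
patient, one or more drug entries with role codes (primary suspect PS,
secondary suspect SS, concomitant C, interacting I), one or more reaction
Preferred Terms (PTs), outcome codes, indications, and dates. Three
properties of these data drive every design decision in this package:

* **No denominators.** Reporting rates, not incidence rates, are observed.
  All inference is therefore *disproportionality*: is the drug–event pair
  reported more often than expected if drug and event were independent
  across reports?
* **Duplication.** Cases are resubmitted as new versions (new PRIMARYID,
  same CASEID). We keep, per CASEID, the version with the latest FDA
  receipt date, breaking ties toward the larger PRIMARYID; a missing
  receipt date sorts earliest. This is deterministic and idempotent, and on
  synthetic data with a known duplicate structure recovers exactly one
  report per case.
* **Incompleteness.** Dates arrive as YYYY, YYYYMM or YYYYMMDD. We store
  the precision explicitly and never impute finer components. An impossible
  month or day drops that component (downgrading precision) rather than
  discarding the whole date.

## The four screening statistics

With cells a (drug + event), b (event, other drugs), c (drug, other
events), d (neither), N = a+b+c+d and s = √(1/a+1/b+1/c+1/d):

* ROR = (a·d)/(b·c), CI95 = ROR·e^(±1.96·s); criterion: CI low > 1 and N ≥ 2.
* PRR = [a/(a+c)]/[b/(b+d)] with the Pearson χ² summed over all four cells
  (expectations from the margins; no Yates correction by default, a flag
  enables it); criterion: PRR ≥ 2, χ² ≥ 4, N ≥ 3.
* IC = log₂(aN/((a+c)(a+b))), IC025 = IC·e^(−1.96·s); criterion: IC025 > 0.
* EBGM = aN/((a+c)(a+b)) — identically 2^IC — and
  EB05 = EBGM·e^(−1.64·s); criterion: EB05 ≥ 2, N > 0.

A pair is a *positive signal* when at least one criterion is met. An
undefined statistic never satisfies its criterion.

### The interval forms, taken literally — and what that costs

The IC025 and EB05 above are the multiplicative closed forms printed in the
surveillance literature this package follows. They are **not** the
canonical BCPNN posterior interval or the gamma-Poisson shrinkage bound,
and we deliberately do not substitute those: the package reproduces the
published procedure, and a "canonical" mode is out of scope.

Two consequences deserve emphasis.

1. `IC025 = IC·e^(−1.96·s)` keeps the sign of IC, so it is positive exactly
   when IC is positive, and the criterion "IC025 > 0" degenerates to
   "observed co-reporting above expectation". Under planted independence
   roughly half of all universes have IC > 0, so the *any-criterion*
   false-alarm rate of the four-algorithm battery is about 50%, dominated
   entirely by the BCPNN rule; the other three criteria are conservative.
   The acceptance script reports this measured null rate
   (`null_any_positive_false_rate`) rather than hiding it.
2. Because IC ≤ 0 makes ln(IC) undefined, IC025 is reported as undefined
   (with a reason, not an error) in that case — which is also the only
   regime in which the literal formula differs in *decision* from the
   canonical one.

Zero cells make all four statistics undefined by default; an optional
Haldane-style +0.5 continuity correction to all cells can be enabled. Real
FAERS-scale tables never hit zero cells; small synthetic ones do.

## Cohort construction

* **Drug matching.** Verbatim drug strings are uppercased, punctuation is
  stripped, and dose/form tokens (`200MG`, `TABLET`, ...) are removed; the
  result (or the active-ingredient field) must match a configured synonym
  list exactly. Only entries with the **PS role** qualify a report for cell
  `a`; the cell definitions for b/c/d are applied literally to everything
  else, i.e. the PS restriction is not mirrored on "other medications".
  This follows the printed cell footnotes; it is flagged as a sensitivity
  point, not varied silently.
* **Event matching.** By PT code when present, else case-insensitive PT
  name, against a configured set. The shipped default is the 17
  kidney-injury PTs (with MedDRA codes) used by the surveillance study the
  package reproduces; "Dialysis" names a procedure rather than an injury
  but is part of that printed set, so it stays in the default and
  `kidney_injury_pts(include_dialysis = FALSE)` drops it.
* **Suicide/intentional-overdose flag.** A report is flagged when any
  indication term contains one of the configured terms (case-insensitive
  substring; defaults drawn from the indications observed in overdose
  tables: intentional overdose, poisoning deliberate, suicidal ideation,
  suicide attempt, intentional product misuse, overdose) **or** the summed
  reported dose of the target drug exceeds 12 g/day. Doses convert to grams
  from MG/G/KG/UG; unknown units are treated as missing and counted.
* **Study window.** The configuration defaults to 2004-01-01–2021-03-31
  (the published text and table captions disagree by one quarter; the
  window is a config value, so either is expressible).

## Descriptive analyses

Age bands <18, 18–44, 45–64, 65–74, >74, Unknown after unit conversion
(DEC×10, YR, MON/12, WK/52.18, DY/365.25, HR/8766; a value with no unit is
taken as years). Percentages are half-up at two decimals, matching printed
tables (base R's round-half-to-even disagrees at .xx5). For age and sex a
known-only percentage (denominator excluding Unknown) is also emitted — the
published abstract quotes those — plus a ≥65 aggregate.

Outcome percentages use the all-cases denominator as primary, and the
with-outcome denominator is reported alongside: the published death
percentage for the ibuprofen cohort (7.36%) is not 178/2,453 under any
rounding, so the package reports both honestly (178/2,453 = 7.26%) and
documents the discrepancy instead of patching it. Similarly, the 33 printed
acetaminophen overdose doses yield a computed median of 27 g where the
text states 28 g; `dose_summary` reports the computed value.

Quartiles (dose and onset IQRs) use linear interpolation between order
statistics (`quantile` type 7), fixed once for the whole package since the
source states IQRs without a convention. Rate comparisons default to the
two-sided Fisher exact test; Pearson's χ² is used when requested and all
expected counts are ≥ 5 (otherwise it falls back with a message). The
tests themselves are delegated to `stats::fisher.test` /
`stats::chisq.test`; the test suite checks them against exhaustive
hypergeometric enumeration.

## Time to onset

Onset is `event_date − earliest PS-role start date of the target drug`, in
whole days. Both dates must have day precision; partial dates are excluded
(reason `partial_date`), absent dates excluded (`missing_date`), and an
event strictly before the start is the "incorrect input" exclusion
(`event_before_start`). A same-day pair is included with onset 0 — the
published lower IQR bound of 0 days forces that choice. When a report
carries several start dates for the target drug the earliest is used
(first exposure; deterministic). Exclusion counts plus included counts
always partition the cohort. Group comparison is the two-sided
Mann-Whitney test via `stats::wilcox.test` (exact when small and tie-free,
tie-corrected normal approximation otherwise), checked in the suite
against full permutation enumeration at 3+3.

## The synthetic generator

`synth_truth()` draws, per case: exposure (multinomial over the target
drugs and "unexposed"), the target event (Bernoulli with probability
`baseline_event_prob`, multiplied by the planted relative risk under
exposure), an intentional-overdose flag, a log-normal onset, and a
duplicate count. `synth_faers()` materializes that truth as the six quarter
tables, adding background drugs and PTs, outcome draws, demographics,
duplicate versions (same CASEID, later receipt dates), and date degradation
(missing / month-precision at configured rates). Identical parameters give
byte-identical files; each table has its own RNG stream derived from the
master seed so extending one table never perturbs another.

Defaults and why:

* `planted_rr = 2.4` — the magnitude of the published
  acetaminophen–kidney-injury disproportionality, the scenario of interest.
* `drug_exposure_prob = 0.02` per drug and `baseline_event_prob = 0.05` —
  desk-scale compromises: real FAERS frequencies are far smaller, but at
  10^4–10^5 reports these values give cohort sizes comparable to the
  published ones while keeping cells non-degenerate.
* `onset_median_days = c(5, 2)`, `onset_sigma = 1.5` — the published
  medians for the two drugs; no distributional form is published, and a
  log-normal matches the long right tail of binned onset histograms in
  this literature.
* `duplicate_rate = 0.5` — roughly the published raw-to-deduplicated ratio
  (3,673 raw versions to 2,453 cases implies ~0.50 extra versions/case).
* Demographic margins follow the published ibuprofen cohort's age, sex,
  region and reporter distributions; outcome probabilities for target
  cases follow its outcome table.

What the generator does **not** emulate: real quarterly volumes, drug
co-prescription structure, country-specific reporting cultures, MedDRA
hierarchy, or correlated missingness. Passing recovery tests on this
generator therefore demonstrates the *pipeline's* correctness (counting,
dedup, matching, statistics), not robustness to every pathology of real
spontaneous data.

### Recovery expectations

With exposure prevalence p and planted relative risk RR, the
observed/expected ratio that EBGM estimates is RR/(1 + p(RR−1)) — slightly
below RR because exposed cases inflate the "expected" margin — and the ROR
sits slightly above RR because odds exceed risks. At the sizes used for
recovery runs (single drug, p = 0.05, baseline event probability 0.02,
~416,000 reports so that a ≈ 1,000) both effects are under 7%, inside the
10% recovery band.

## Problem sizes used in validation

The suite and acceptance script run on one CPU in a few minutes total:
identity checks on 10,000 random tables; Fisher oracle over all ~45,000
tables with n₁+n₂ ≤ 30; χ² null calibration at 2,000 replicates
(expected cell counts large enough for the 1-df reference to apply);
planted-RR recovery as the median of 50 universes with a ≈ 1,000; null
behaviour over 200 universes of 50,000 reports; full-pipeline dedup and
onset runs at 2,453 and 26,000 cases. Larger replicated simulations use
the generator's ground-truth ledger directly; a confluence test proves the
ledger recount equals `build_contingency` on written-and-reparsed files,
which licenses the shortcut.

## Known limitations

* The literal BCPNN/MGPS interval forms (above) make the four-criterion
  battery's null false-alarm rate ≈ 50%; interpret `any_positive` under
  that caveat, or rely on the ROR/PRR/MGPS flags.
* Drug matching is exact after normalization — misspelled verbatim names
  miss; there is no fuzzy matching and no ingredient dictionary beyond the
  configured synonyms.
* One report may legitimately match several target drugs and then appears
  in both cohorts; the 2×2 construction is per-pair, as in the published
  procedure, so such reports contribute to `a` for each drug.
* Region mapping covers ISO 3166-1 alpha-2 codes; unmapped codes report as
  Unknown.
* No multivariable adjustment, MedDRA hierarchy roll-ups, or survival
  modelling of onset — deliberately out of scope.
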