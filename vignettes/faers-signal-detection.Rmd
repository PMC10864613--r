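---
title: "Disproportionality signal detection and time-to-onset modelling for spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection and time-to-onset modelling for spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

faersignal implements the standard post-marketing pharmacovigilance workflow
for FAERS-style spontaneous-report data, from raw quarterly ASCII tables to
signal tables and onset-time models. This vignette explains the statistical
procedures, the choices the package makes where the conventions leave room,
and what its synthetic data generator does and does not emulate.

## The data model and its pitfalls

FAERS distributes quarterly bundles of "$"-delimited tables: DEMO (one row
per submitted report version, with demographics and the receipt date FDA_DT),
DRUG (one row per reported drug, role-coded PS/SS/C/I), REAC (one row per
reaction, coded as a MedDRA-style preferred term, PT), THER (therapy start
and end dates), INDI (treatment indications) and OUTC (outcome codes).
Three properties of these data drive the pipeline design:

* **Versioning.** Cases are re-submitted across quarters under the same
  CASEID. Before any counting, `dedup_cases()` keeps, per CASEID, the
  version with the most recent FDA_DT, breaking ties by the higher
  PRIMARYID. A missing FDA_DT loses to any present date — "most recent"
  cannot select an unknown date — and two missing dates fall through to the
  PRIMARYID rule. The kept set is a pure function of the key fields, so it
  is order-invariant and idempotent, which the tests verify by permutation.
* **Dirty dates.** Dates arrive as digit strings, and a sizeable share are
  partial (`YYYYMM`) or malformed. The readers never coerce or drop at parse
  time; every date is retained with a validity flag and excluded only where
  a rule requires it (time-to-onset), with the reason tallied in an audit.
* **Role codes.** A report "belongs" to a drug for signal purposes only when
  that drug is its primary suspect (PS). `select_primary_suspect()` applies
  the drug dictionary (generic + brand names, case-insensitive whole-string
  matching by default; a word-boundary substring mode catches salt forms
  like "... MESYLATE" at the cost of specificity) and the PS role jointly.

The counting unit downstream is the **event**: one distinct PT per report.
Repeated identical PTs within one report count once. Organ-class (SOC)
counts aggregate those same events through a user-supplied PT-to-SOC map, so
per-SOC counts sum exactly to the drug's total event count — the convention
under which published per-class tables reconcile with their PT totals.
Events whose term equals one of the drug's treatment indications are removed
before signal detection (`exclude_indication_terms()`), so the disease being
treated is not read as a drug effect; the default exclusion set is derived
from the cohort's own INDI records.

## Disproportionality statistics

For each term, the 2x2 table against the background of all other drugs'
events in the window is: `a` target-drug events with the term, `b` its other
events, `c` background events with the term, `d` the rest; `N = a+b+c+d`.
Three statistics are computed, each with its conventional signal criterion,
and a term is a **consensus signal** only when all three criteria hold
simultaneously — the intersection rule trades sensitivity for a lower
false-positive rate:

* **ROR** `= ad/bc`, Woolf interval
  `exp(ln ROR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`; criterion: lower bound
  > 1 and `a ≥ 3`.
* **PRR** `= a(c+d) / (c(a+b))` with the plain Pearson chi-squared
  `(ad−bc)² N / ((a+b)(c+d)(a+c)(b+d))`; criterion: PRR ≥ 2, chi-squared
  ≥ 4, `a ≥ 3`. No Yates correction by default (a corrected variant is a
  switch for sensitivity analysis); the statistic is verified against the
  expected-count Pearson formulation to 1e-9 on a thousand random tables.
* **IC** `= log2(aN / ((a+c)(a+b)))`, the Bayesian information component;
  criterion: the lower 95% credibility bound IC025 > 0.

Zero cells are left alone by default: the printed formulas are then
undefined, the statistic is `NA`, and an undefined statistic never signals.
An optional Haldane–Anscombe +0.5 correction is available. With `b, c, d`
fixed, ROR and PRR are strictly increasing in `a`; the raw IC is too in the
typical regime where the term margin dominates `a`, but not unconditionally
(its derivative `b/(a(a+b)) + 1/N − 1/(a+c)` turns negative once `a` grows
comparable to `a+c`), which is worth knowing before using IC to rank very
common terms.

### The IC credibility interval

The package treats the cell probabilities as Dirichlet-distributed with unit
prior pseudo-counts, so the posterior is `Dirichlet(a+1, b+1, c+1, d+1)` and
IC025 is the 2.5% posterior quantile of
`log2(p11 / ((p11+p12)(p11+p13)))`. Two routes are provided:

* `method = "monte_carlo"` draws from the posterior and takes empirical
  percentiles — the transparent reference.
* `method = "closed_form"` (default) computes the same quantile
  deterministically. Writing `m = p11+p12 ~ Beta`, `u = p11/m ~ Beta` and
  `v = p21/(1−m) ~ Beta` — independent by the Dirichlet's aggregation
  property — the IC is `[ln u − ln(um + v(1−m))]/ln 2`, monotone in `u` for
  fixed `(m, v)`. Its posterior CDF is therefore a two-dimensional integral
  of a Beta CDF, evaluated by 32-point tensor Gauss–Legendre quadrature in
  quantile space and inverted by root-finding. The two routes agree to about
  0.002 on ordinary tables; the test suite requires 0.1 at 100,000 draws.

The older normal approximation with mean ± 2 standard deviations and
margin-tied hyper-priors (`method = "bate"`) is retained for comparison with
literature values. It is **not** the default because its prior shrinks the
mean heavily whenever the expected count is small, placing its lower bound
several log2 units away from the posterior quantile the criterion is meant
to approximate; with a unit-prior posterior available exactly, there is no
reason to accept that distortion. Note that published IC025 columns in this
literature are not always reconstructible from any count-based variance —
when validating against a published table, compare the raw IC and the counts
first.

A consensus signal absent from the drug's label-term list is flagged
**unexpected** (`flag_unexpected()`); the label list is a configuration
input, since product labels are versioned documents outside the data.

## Time to onset

TTO is `EVENT_DT − START_DT` in whole days, computed once per case:
START_DT is the earliest complete, calendar-valid start among therapy rows
linked to the matched PS drug entry (several rows per drug are common;
taking the earliest full date is the package's resolution and is logged as
such). Cases are excluded — and audited — for missing or partial event
dates, absent valid starts, and onsets preceding therapy start. Day 0 is a
real observation: the event began on the first day of dosing.

The Weibull model summarises the hazard trend: shape below 1 means a
falling event rate ("early failure"), near 1 constant, above 1 rising
("wear-out"). Because whole-day intervals are rounded dates, not exact
times, `fit_weibull()` maximises the interval-censored likelihood — day `d`
is read as `(d−0.5, d+0.5)`, day 0 as left-censored at half a day. This
matters: at the shape values typical of early-failure profiles (around 0.6)
roughly a tenth of the onset mass lies below half a day, and fitting the
rounded values as exact numbers with day 0 floored to 0.5 inflates the
shape estimate by about 7% at n = 2000 — outside the package's own 5%
recovery tolerance — while the interval likelihood is unbiased to a few
tenths of a percent in the same experiment. Confidence intervals are Wald
intervals on the log-parameter scale (delta method from the observed
information), and `classify_hazard()` uses the whole interval, not the
point estimate: early-failure only when the entire CI lies below 1.
Degenerate samples (all-identical intervals) return a non-converged fit
classified indeterminate rather than an error. Fits are refused below 10
records by default — a floor, not a recommendation.

## The synthetic scenario

Nothing in FAERS can be redistributed conveniently, and real signals have
no ground truth, so every stage is exercised against `faers_simulate()`,
whose scenario object fixes all study conditions:

* 50,000 unique cases over 2019Q3–2023Q1 by default, the scale at which the
  recovery properties are stated; smaller runs are used in unit tests where
  only structure matters.
* a vocabulary of 130 synthetic PTs in 26 synthetic organ classes (the
  granularity of the real dictionary's top level) with background weights
  cycling common-to-rare; names are invented to avoid licensed content.
* the target drug appears as primary suspect in 2% of cases — enough for
  roughly a thousand cohort reports, matching the order of magnitude of a
  recently approved oncology drug against a large background.
* six planted signals with rate ratios 2, 3, 4, 4, 8, 8 on half-weight
  terms. Within target-drug reports the term's sampling weight is
  multiplied by its rate ratio; each case draws 1–10 distinct PTs (truncated
  geometric, mean about 2) without replacement. Planting on half-weight
  terms keeps the planted probability mass near 8% of the total, so null
  terms stay within ±15% of rate ratio 1 — with heavier planted mass the
  weight renormalisation alone would push null terms visibly below 1, which
  is a real phenomenon (competition bias) but would confound the
  false-positive calibration.
* duplication of 8% of cases (newer submission, higher PRIMARYID, later
  FDA_DT; a fifth of duplicates tie the FDA_DT to exercise the tie-break),
  Table-2-like demographic missingness (age unknown 90%, weight 65%), 25%
  missing and 10% partial event dates, 2% of cases with onset recorded
  before therapy start, and Weibull onset intervals with shape 0.56 and
  scale 30 days (median about 16 days) rounded to whole days.

The generator emits raw character tables exactly as the ASCII distribution
carries them, plus a ground-truth ledger (true rate ratios, duplicate
versions, cohort membership, true onset days). With a fixed seed the output
is byte-identical across runs.

What it does **not** emulate, hence what passing tests cannot show about
real data: cross-CASEID duplicates (same patient, different case numbers —
FAERS's harder deduplication problem), reporting-delay dynamics and
secular trends, correlated reaction terms (syndromes), drug–drug
confounding, multi-axial SOC membership, and free-text drug-name noise
beyond case/whitespace/brand variation. Calibration conclusions are about
the algorithms under independence-style sampling, not about FAERS biases.

## Numerical and design choices

* Percentages print at one decimal, rounded half away from zero
  (`round_half_up()`), the regulatory-table convention; an epsilon guards
  against binary representation just below the half. Published baseline
  tables recompute under this rule almost everywhere — the bundled
  reference tables (`published_reference()`) include a handful of cells
  that match under no rounding convention and are flagged by
  `check_percentages()`, which is the expected outcome of an honest
  transcription check.
* Age normalisation: AGE_COD decades multiply by 10, months divide by 12,
  weeks by 52, days by 365; unknown codes yield missing, never a guess.
* Quantiles for TTO medians/IQRs are linear-interpolation (type 7)
  quantiles.
* The analysis window is applied after deduplication, so the kept version
  of a case decides membership; `assemble_cases()` can also window at
  assembly for single-window workflows.
* Ranking of signal tables is a stable descending sort by case count or
  IC025 with alphabetical tie-break, so output tables are diffable across
  runs.
* The chi-squared homogeneity comparison of two drugs' organ-class profiles
  is delegated to `stats::chisq.test(correct = FALSE)` after dropping
  all-zero classes.

Problem sizes in the shipped tests: the recovery suite runs twenty
50,000-report replicates; the IC oracle comparison uses 200 tables at
100,000 posterior draws; Weibull coverage uses 200 replicates at n = 1000.
`scripts/acceptance.R` reproduces the same quantities at ten replicates.

## Known limitations

* Exact-key deduplication only; probabilistic record linkage across CASEIDs
  is out of scope.
* One drug per pipeline run; the two-drug comparisons in the reporting
  module operate on two event tables produced by two runs.
* Expectedness flags are only as good as the supplied label-term list;
  terms are matched by case-folded equality, not by MedDRA hierarchy.
* The Weibull model is a single-population fit; competing risks, cure
  fractions, and dose dependence are not modelled.
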