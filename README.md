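# faersignal

Signal detection for spontaneous adverse-event reports, built for
FAERS-style quarterly data: ingestion of the raw "$"-delimited DEMO / DRUG /
REAC / THER / INDI / OUTC tables, FDA-recommended deduplication,
primary-suspect cohort construction, disproportionality analysis with a
triple-algorithm consensus rule, unexpected-signal flagging against a label
list, Weibull time-to-onset modelling, and the descriptive tables
(demographics, annual counts, organ-class profiles) that accompany a
pharmacovigilance study. A synthetic report generator with planted signals
of known strength makes the whole pipeline testable end to end without
downloading the live database.

It is written for pharmacoepidemiologists and biostatisticians who work
with spontaneous-report data and want the standard methods as composable,
tested functions: every stage takes and returns tibbles (or small typed
objects with `tidy()` / `glance()` / `autoplot()` methods) and chains with
the pipe.

## The statistics

For each term (MedDRA-style preferred term, PT, or its organ class, SOC)
the package forms the 2x2 table of the target drug against all other drugs
— `a` target events with the term, `b` its other events, `c` background
events with the term, `d` the rest — and computes:

| Algorithm | Estimate | Signal criterion |
|---|---|---|
| ROR | `ad/bc`, Woolf 95% CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))` | CI lower bound > 1, a ≥ 3 |
| PRR | `a(c+d)/(c(a+b))`, Pearson `χ² = (ad−bc)²N/((a+b)(c+d)(a+c)(b+d))` | PRR ≥ 2, χ² ≥ 4, a ≥ 3 |
| BCPNN | `IC = log₂(aN/((a+c)(a+b)))`, 95% credibility interval from the Dirichlet(counts + 1) posterior | IC025 > 0 |

A term is a **consensus signal** when all three criteria hold at once;
consensus signals absent from the drug's label-term list are flagged
**unexpected**. The IC interval is computed deterministically as the exact
posterior quantile (quadrature + root-finding), with a Monte-Carlo sampler
as the cross-checking reference and the classical normal approximation
available for comparison with older literature.

Time to onset (`EVENT_DT − START_DT`, whole days, one record per case) is
summarised by median/IQR and fixed reporting periods, and fitted with an
interval-censored Weibull likelihood; shape < 1 (the whole confidence
interval below 1) classifies the hazard as early-failure — the adverse-event
rate declines with time on drug.

## Worked example

Simulate a 20,000-report stream with six planted drug–event signals (rate
ratios 2–8), run the full pipeline, and inspect what comes back:

```r
library(faersignal)
library(dplyr)

scn  <- synth_scenario(n_reports = 20000, seed = 42)
sim  <- faers_simulate(scn)
dict <- drug_dictionary("targetinib", brand = "TARGETRA")
res  <- faers_pipeline(sim, dict, scn$pt_vocabulary)

res$signals_pt |> filter(consensus) |> rank_signals("case_number") |>
  select(term, a, ror, ror_low, prr, chi2, ic, ic025)
#> # A tibble: 7 × 8
#>   term                   a   ror ror_low   prr   chi2    ic ic025
#>   <chr>              <int> <dbl>   <dbl> <dbl>  <dbl> <dbl> <dbl>
#> 1 Synthetic term 024    24  8.27    5.33  8.06 127.    2.81 2.27
#> 2 Synthetic term 029    24  6.82    4.42  6.65 101.    2.57 2.03
#> 3 Synthetic term 014    10  3.22    1.69  3.19  14.1   1.61 0.759
#> 4 Synthetic term 004     8  2.36    1.15  2.34   5.89  1.19 0.239
#> 5 Synthetic term 009     8  2.64    1.29  2.63   7.66  1.34 0.397
#> 6 Synthetic term 075     4  3.03    1.10  3.02   5.07  1.53 0.236
#> 7 Synthetic term 100     4  2.75    1.00  2.75   4.20  1.40 0.108
```

Reading the first row: the planted rate-ratio-8 term was reported 24 times
with the target drug; its reporting odds ratio is 8.3 (lower bound 5.3),
PRR 8.1 with χ² = 127, and the information component's lower credibility
bound is 2.27 — all three criteria fire, so it is a consensus signal. Terms
075 and 100 are false positives sitting just over the thresholds (a = 4,
ROR lower bounds 1.10 and 1.00) — the kind of marginal consensus hit the
a ≥ 3 floor is meant to keep rare. Against the generator's ground truth,
five of the six planted terms reach consensus at this scale; the missed one
is a rate-ratio-4 term observed only 7 times:

```r
inner_join(res$signals_pt, sim$truth$signals, by = c(term = "pt")) |>
  filter(lambda > 1) |> select(term, lambda, a, ror, consensus)
#> # A tibble: 6 × 5
#>   term               lambda     a   ror consensus
#> 1 Synthetic term 004      2     8  2.36 TRUE
#> 2 Synthetic term 009      3     8  2.64 TRUE
#> 3 Synthetic term 014      4    10  3.22 TRUE
#> 4 Synthetic term 019      4     7  2.05 FALSE
#> 5 Synthetic term 024      8    24  8.27 TRUE
#> 6 Synthetic term 029      8    24  6.82 TRUE
```

Onset modelling on the same run (the scenario plants Weibull shape 0.56,
scale 30 days):

```r
res$weibull
#> <weibull_fit> n = 118
#>   shape 0.592 (0.514-0.683)  scale 32.9 d (23.8-45.4)  hazard: early-failure

tto_periods(res$tto$records)
#> # A tibble: 6 × 3
#>   period      n   pct
#> 1 0-30       75  63.6
#> 2 31-60      14  11.9
#> 3 61-90      11   9.3
#> 4 91-180     10   8.5
#> 5 181-360     5   4.2
#> 6 >360        3   2.5
```

The shape estimate 0.59 (CI entirely below 1) recovers the planted 0.56 and
classifies the hazard as early-failure: most onsets fall in the first month
and the rate declines thereafter.

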