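---
title: "Disproportionality methods for spontaneous-report signal detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods for spontaneous-report signal detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The case/non-case design

Spontaneous-reporting databases collect adverse-event reports without any
measure of how many patients took each drug, so incidence cannot be
estimated. What can be estimated is *disproportionality*: whether an event is
reported more often with the drug of interest than the rest of the database
would predict. `faersignal` implements the case/non-case form of this
design. A deduplicated report is a **case** when at least one of its drugs
carries the primary-suspect (PS) role and matches the target drug's synonym
set; all other reports are **non-cases**. For each event term the fourfold
table `(a, b, c, d)` splits case and non-case reports by presence of the
event, counting each report once per event term.

Two margin conventions are offered by `contingency_tables()`. Under
`counting = "report"` (the default) `b` and `d` complete the *report* counts:
`a + b` is the number of case reports and `n` the number of reports. Under
`counting = "unit"` they complete the (report, event)-pair counts, the
convention that matches database totals quoted as reaction-record counts.
The default is the report convention because it is the design's natural
reading — the table then estimates a per-report odds ratio, and in the
synthetic generator (below) that estimand equals the planted multiplier
exactly, which makes calibration checks interpretable. The unit convention
is retained for comparisons against published screens whose `n` is a
reaction-record total.

## The four algorithms

All four scores are computed on the same table; they differ in how they
stabilise small counts.

**ROR.** `ad/bc` with the log-Wald interval
`exp(ln ROR ± z √(1/a + 1/b + 1/c + 1/d))`, `z = qnorm(0.975)` at the
default 95% level. No shrinkage: with an empty `b` or `c` cell the estimate
is infinite and reported as such (see *Degenerate inputs*).

**PRR and Yates chi-square.** `[a/(a+b)]/[c/(c+d)]`, with the Wald variance
`1/a − 1/(a+b) + 1/c − 1/(c+d)` on the log scale. The PRR interval formula
is the standard log-Wald choice; published screens print PRR intervals
without stating a formula, and this is the convention that reproduces them.
The accompanying test statistic is the continuity-corrected chi-square
`n(|ad−bc| − n/2)²/[(a+b)(a+c)(c+d)(b+d)]`, floored at zero when
`|ad−bc| < n/2` — without the floor, tables *below* independence would score
positive.

**BCPNN information component.** With margins `C = n`, `Cx = a+b`,
`Cy = a+c`, `Cxy = a` and hyperparameters
`α₁ = β₁ = 1, α = β = 2, γ₁₁ = 1` (the conventional uninformative choice,
exposed via `bcpnn_hyperparams()`), the per-table
`γ = γ₁₁(C+α)(C+β)/[(Cx+α₁)(Cy+β₁)]` centres the prior IC at zero; then

```
EIC = log2[ (Cxy+γ₁₁)(C+α)(C+β) / ((C+γ)(Cx+α₁)(Cy+β₁)) ]
```

and the posterior variance `VIC` is `1/ln²2` times the sum of the three
per-margin terms `(C−Cxy+γ−γ₁₁)/[(Cxy+γ₁₁)(1+C+γ)]` and its `Cx`, `Cy`
analogues. The signal bound is `IC−2SD = EIC − 2√VIC`. Published columns
labelled "IC025" are sometimes a posterior 2.5th percentile instead; the
two differ by the normal approximation, and this package computes and
labels the `EIC − 2√VIC` form (`ic_2sd`) because it is the closed form the
algorithm defines.

**MGPS / EBGM.** Counts are modelled `a ~ Poisson(λE)` with
`E = (a+b)(a+c)/n` and a two-component gamma-mixture prior on λ shared
across all tables of a screen. The prior is fit by maximising the
negative-binomial-mixture marginal likelihood (`fit_mgps_prior()`,
Nelder–Mead on log/logit-transformed parameters); the classical starting
point `(shape 0.2, rate 0.1) + (shape 2, rate 4), weight 1/3` is also the
fallback if the optimiser fails, with a warning — shrinking with a
documented default beats shrinking with a half-converged fit. The posterior
is again a two-gamma mixture; `EBGM = exp(E[ln λ])` uses
`E[ln Gamma(s, r)] = ψ(s) − ln r` per component, and EBGM05 solves the
mixture CDF at 0.05 by bisection between the component quantiles. EBGM
always lies between 1 and `a/E` for elevated pairs under a mean-1 prior —
the property suite asserts this shrinkage bound. Because published screens
never state their prior, exact reproduction of published EBGM columns is
not expected; the bounds and monotonicity are what the implementation
guarantees.

## Signal criteria and multiplicity

`evaluate_criteria()` applies the conventional sets — `a ≥ 3` throughout;
`ROR ≥ 2` with CI lower bound > 1; `PRR ≥ 2` with `χ² ≥ 4`; `IC−2SD > 0` —
each threshold exposed as an argument and logged by the pipeline. The
combined `signal` flag is the *conjunction* of the three sets, a
deliberately conservative labelling; the per-algorithm flags are always
exported so any other convention can be recovered downstream.

For the volcano view the only defined test statistic, the Yates chi-square,
is converted to an upper-tail 1-df p-value and adjusted across all events at
the screen's level by Benjamini–Hochberg (`bh_adjust()`, a validated front
on `stats::p.adjust`). BH is the standard false-discovery-rate convention
for volcano displays; both raw and adjusted p-values are kept. A point is
significant when `log2(PRR) > 0` and `−log10(p_adj) > 1.3`
(`1.3 ≈ −log10(0.05)`). One property BH does *not* have is idempotence:
re-adjusting adjusted values inflates them again, because the step-up
correction multiplies each order statistic by `n/rank` regardless of its
provenance. The suite therefore checks conservativeness and permutation
equivariance, not re-application.

## Reading and cleaning FAERS-style data

The reader is frozen to the public quarterly ASCII dialect: `$`-delimited,
one header line, no quoting, UTF-8. Column aliases per table absorb
historical header drift (`isr` for `primaryid` in older files) and are
user-extensible. Dates are `YYYYMMDD` with truncated `YYYYMM`/`YYYY`
variants resolved to the first day of the period — the conservative choice
that never shortens a time-to-onset while keeping it computable.

Deduplication applies the FDA's recommended rule jointly across all
quarters, since amended cases recur in later files: per case ID keep the
latest receipt date, ties broken by the largest report ID. The rule is
deterministic, idempotent and order-independent, and it runs *before* the
indication filter — the filter needs each case's final version, not its
history. Cleaning then drops empty event terms, removes any event PT that
exactly equals (trimmed, case-folded) an indication PT recorded for the same
report — an "adverse event" identical to the treated disease is the disease
— and drops reports left with no event. Demographic blanks are *kept* as
explicit `unknown` levels: descriptive tables need them in the denominator.
Every removal is tallied and logged; nothing is dropped silently.

## Descriptive summaries

Three denominator conventions coexist in the characteristic tables, each
forced by what the quantity means:

- demographics (sex, age, reporter, country): all case reports, unknowns as
  a level — percentages describe the whole cohort;
- outcomes: one outcome per report, chosen by the seriousness priority
  `DE > LT > HO > DS > CA > RI > OT`, over reports carrying at least one
  outcome code — a report both hospitalised and dead is a death, and
  reports with no outcome say nothing about outcome distribution;
- time to onset (event date minus earliest therapy start, whole days,
  bins `[0,7)`, `[7,28)`, `[28,60)`, `[60,∞)`): reports with exactly one of
  the two dates or a negative difference are `unknown`; reports with
  neither date carry no time information and leave the tabulation entirely.

Age units are converted to years (`month/12`, `week/52`, `day/365.25`,
`decade×10`, `hour/8766`) and binned `[0,18)`, `[18,45)`, `[45,65)`,
`[65,75)`, `[75,∞)`; bins are half-open on the left so 45 falls in 45–65.
The bin-edge and denominator conventions are stated here precisely because
published tables rarely state theirs.

## Reconstructing published rows

`reconstruct_contingency()` inverts a published `(a, n, ROR, PRR)` row back
to its real-valued fourfold table: the PRR equation eliminates the event
margin (`Cy = a + a(n−Cx)/(PRR·Cx)`), leaving a one-dimensional root-find in
the case margin `Cx`, bracketed on a 128-point log-spaced grid and bisected
to `1e-10` relative tolerance. The branch requires `ROR > PRR > 1`; at
`ROR = PRR` the system degenerates and the function refuses rather than
returning an arbitrary table. Because the printed ROR/PRR are rounded to
two decimals, statistics recomputed from a reconstruction inherit that
rounding — a relative error of a few parts in a thousand on the chi-square
is expected and observed.

## The synthetic generator

`simulate_faers()` emulates the features of a FAERS extract that the
pipeline must handle: multi-table quarterly bundles keyed by report and case
IDs, duplicate case versions with earlier receipt dates, drug role codes
with one primary suspect per report, multiple PT events per report,
outcome codes, therapy/event dates with configurable missingness, and an
indication table (drawn from a vocabulary disjoint from the event PTs, so
the overlap filter is exercised without perturbing planted counts).

The event model is the package's own design choice and the point where it
deliberately departs from a draw-counts-then-sample-terms scheme: each
report carries each PT *independently* with a Zipf-skewed baseline
probability (scaled to a configurable mean events per report; the skew
mimics the heavy-tailed PT frequencies of real spontaneous data and
exercises the small-`a` criterion paths), and a planted multiplier for
(drug, pt) multiplies the *odds* of that PT on reports whose primary
suspect is that drug. Under this model the report-level odds ratio — the
ROR's estimand — equals the planted multiplier exactly, so the multiplier
is a clean oracle for recovery tests; under a categorical-terms scheme the
renormalisation across terms would distort the estimand by an amount that
depends on every other parameter. Reports that draw no event are discarded
(a spontaneous report without a reaction does not exist); this conditioning
cancels between cases and non-cases for the multiplied PT, leaving both the
null and the planted estimand exact.

What the generator does **not** emulate: real drug vocabularies and
misspellings beyond case/whitespace variants, country- or time-varying
reporting rates, correlated event clusters (syndromes), partial dates, and
dose/duration fields. Passing calibration on synthetic data therefore
demonstrates the statistics and plumbing, not robustness to real FAERS
name noise — the synonym list is the user's responsibility on real data.

The statistical suite runs two study-scale checks, sized so each completes
in minutes on one core: with no planted signal (four equal-share drugs,
30 PTs, 50,000 reports, 200 replicate seeds) the ROR 95% interval covers 1
for ~95% of drug–event pairs and the BCPNN bound flags essentially none;
with a planted five-fold multiplier (50,000 reports, 200 seeds) the ROR
interval covers the multiplier in well over 90% of replicates.

## Degenerate inputs and numerical choices

- Zero cells: by default `ROR`/`PRR` become `Inf` and such rows are
  excluded from ranked exports (with an excluded-count attribute), never
  from the underlying scores. The Haldane–Anscombe `+0.5` correction is
  available behind `zero_cell = "haldane"` and touches only tables that
  contain a zero.
- Cell counts are coerced to double before any margin product: the
  chi-square numerator overflows 32-bit integers already at moderate
  database sizes.
- Empty cohorts, outcome-free cohorts and zero-case runs return empty,
  well-typed tibbles (and, in the pipeline, a warning plus empty exports)
  rather than errors.
- Unmapped PTs map to an explicit `(unmapped)` SOC and are tallied.
- All randomness lives in `sim_config(seed = )`; a fixed seed makes
  generation, the written files and the whole pipeline byte-stable.

## Known limitations

Stratified (age/sex/period) disproportionality, multi-drug interaction
screens, and hierarchy levels between PT and SOC are out of scope. The
MGPS fit assumes a common prior across the screen's tables; screens with
fewer than ~10 tables fall back to the default prior. Disproportionality
quantifies reporting association, not causality or incidence — the usual
caveats of spontaneous data (under-reporting, confounding by indication,
stimulated reporting) apply to any interpretation of the flags.
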