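---
title: "Liver-chemistry surveillance methods for anti-VEGF cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liver-chemistry surveillance methods for anti-VEGF cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepatosafe)
```

## The estimand and the design

`hepatosafe` estimates, for adults with renal cell carcinoma newly started
on an anti-VEGF drug (pazopanib, sorafenib, sunitinib, bevacizumab), the
cumulative incidence and incidence rate of liver-chemistry (LC) elevations
defined as multiples of each lab's upper limit of normal (xULN), along
with the Hy's-law combination (ALT or AST ≥3x with total bilirubin ≥2x and
ALP <2x ULN) and a drug-induced liver injury (DILI) screen. The design is
a new-user cohort: entry at the first observed record of the index drug,
which avoids prevalent-user bias at the cost of treating any use invisible
to the database as absent. No minimum prior enrollment is required —
oncology patients are often new to a practice at treatment start — so
undetectable prior use is a documented limitation, not a checkable
criterion.

Cohort entry requires, at the drug start date: age ≥ 18; an RCC diagnosis
(ICD-9 189.0/189.1) on or before start; at least one ALT and one bilirubin
result in the inclusive baseline window `[start − 30 d, start]` (otherwise
baseline-to-follow-up comparison is impossible); and no other anti-VEGF
drug's treatment episode covering the start date. A patient may enter
under different drugs at different times. We require the RCC diagnosis *on
or before* start rather than allowing a short post-start grace period: a
code first appearing after initiation cannot confirm the indication at
baseline, and the synthetic generator always codes RCC before start, so
the stricter rule costs nothing here and is the conservative reading.

The concurrent-use check deliberately uses the *untruncated* episodes of
the other anti-VEGF drugs. Episode truncation (below) ends an episode the
day before an alternate drug starts; if the check used truncated episodes
the overlap would always have been erased and the exclusion could never
fire.

## Exposure model

Each drug record covers `[date, date + d − 1]`, with `d` the recorded days
supply when present and otherwise an imputed duration: 30 days for
pazopanib and sorafenib prescriptions, 28 days for sunitinib, and 14 days
per bevacizumab administration (the indicated infusion interval). A
treatment episode (drug era) merges consecutive intervals while the
uncovered gap — counted exclusively of both endpoints, so an interval
ending day `e` and the next starting day `s` leave a gap of `s − e − 1`
days — is at most 30 days; day 31 splits the course. Initiation of an
alternate RCC treatment at date `t` with no index-drug record on or after
`t` truncates exposure at `t − 1` (the start day belongs to the new
treatment) and ends episode building. "Initiation" means the alternate
drug's first record *after* the index start; records predating the index
start are prior therapy lines, not initiations.

These conventions are pinned by a brute-force oracle: a test marks every
covered day on a calendar bitmap, clears days from the truncation date,
extracts maximal runs allowing ≤30 unmarked days, and requires the
interval-merging implementation to agree exactly on 1000 random interval
sets.

## Outcome classification

The threshold catalog fixes the LC categories: ALT or AST ≥3x–4.99x,
≥5x–9.99x, ≥2x, ≥3x, ≥5x, ≥8x, ≥10x; ALP >1x, >2x, >3x, ≥2x–2.99x,
≥3x–4.99x, ≥5x; bilirubin >1x, ≥1.5x–1.99x, ≥2x–4.99x, ≥2x, ≥5x.
Aminotransferase categories use the higher of ALT and AST on a given day;
banded categories match only values inside the band (a 6.0x ALT is an
event for ≥5x–9.99x, not for ≥3x–4.99x).

Eligibility is per category: a patient whose baseline multiple already
reaches the category's lower threshold (at-or-above for `≥` bounds,
strictly above for `>` bounds) is removed from both numerator and
denominator — hence denominators vary across categories. The baseline
summary is the *maximum* in-window multiple, the conservative choice for
screening out prior elevation; the protocol requires only that a baseline
measurement exist, so any summary is a design decision, and the maximum
guarantees that nobody already elevated at baseline is counted as an
incident case. Labs dated on the start day are baseline only; follow-up
begins the next day.

Elevation detection is restricted to labs dated inside exposure episodes
of the index drug; labs falling in a >30-day treatment gap do not qualify.
By default events are counted in *all* episodes, consistent with summing
person-time across separate exposure periods; `first_episode_only = TRUE`
restricts to the first episode for sensitivity analyses, since protocol
language on later episodes is ambiguous.

Hy's-law concurrency defaults to same-calendar-day measurement of all
three analytes, with an unmeasured ALP defeating the combination (ALP <2x
cannot be verified). Both choices are exposed (`hys_law_window_days`,
`alp_required`) because laboratory panel practices differ; widening the
window or waiving ALP can only add events. The DILI screen deliberately
uses a different, wider window — earliest to latest anti-VEGF exposure
date across all four drugs plus 90 days — and flags same-day ALT >3x with
bilirubin >2x (strict inequalities, per the screening rule) or any listed
ICD-9 code, with `570` matching the whole `570.x` family. Screen flags
feed an external chart-review/adjudication process; the pipeline accepts
an adjudication table as input and never computes a DILI verdict itself.

## Incidence estimation

Cumulative incidence is `100·k/n` over evaluated patients, rounded half-up
to one decimal (matching table formatting; R's `round()` is half-even and
would print 3.45 % as 3.4). The CI is the exact Clopper–Pearson interval
from beta quantiles. The method choice is pinned by the printed-cell
checks: 7/151 gives (1.9, 9.3) under Clopper–Pearson where Wilson gives a
2.3 lower bound. Zero-case cells report the one-sided 97.5 % upper bound
`100·(1 − 0.025^{1/n})`, which is analytically the two-sided 95 %
Clopper–Pearson upper limit at zero cases — an identity the tests verify
through the independent beta-quantile route.

Person-time sums inclusive episode day counts across all episodes,
censored at the first event for the category (the event day counts),
divided by 365.25. Rates are `100·k/PY` with exact Poisson bounds from
chi-square quantiles (`qchisq(α/2, 2k)/2`, `qchisq(1−α/2, 2k+2)/2`)
scaled by person-time. Undefined cells (zero denominators) propagate as
`NA`, never as 0.

Stratified tables split by line of therapy at start: first line versus
second or higher. Line is 1 plus the number of distinct prior regimens,
where antineoplastic drug starts within 30 days of a regimen's first start
group into one regimen (combination partners count once). The grouping
window is a package invention — the protocol defines line only loosely
from prior chemotherapy exposure — so it is exposed as
`regimen_window_days` rather than hard-coded.

## The synthetic generator

`generate_dataset()` emulates the statistical structure the analysis
assumes: accrual uniform over the study window; ages 40–85; an RCC code
before start; prescriptions with refill gaps drawn from a truncated normal
plus occasional long gaps that split episodes; scheduled lab panels at a
fixed interval (default 30 days — real monitoring frequency is not
published, so this is an explicit placeholder); baseline and non-elevated
follow-up values i.i.d. log-normal with median 0.6x ULN, capped below 2x
so that with all hazards zero no follow-up value can reach a 2x category;
and constant per-drug, per-analyte hazards of a first threshold crossing
while exposed. Event times are exponential in *exposed* time; the
qualifying value is placed at the next scheduled lab at or after the event
time. That last choice reproduces measurement-limited detection — sparse
schedules detect late or miss transient elevations entirely — and is what
lets the tests quantify attenuation instead of assuming detection is
perfect.

Randomness is organized as one RNG substream per patient, seeded from the
global seed, with every schedule-independent draw (demographics,
prescriptions, true event times and magnitudes) taken before the
schedule-dependent noise draws. Two configurations differing only in the
lab schedule therefore share identical patient histories and true events
(common random numbers), making schedule comparisons paired and
structurally monotone: a sparser schedule can only detect fewer events and
accumulate more person-time per detected case.

What the generator does *not* model — and what passing tests therefore do
not demonstrate about real data: within-patient autocorrelation of lab
values, dose titration and adherence, informative lab ordering (sicker
patients measured more often), across-system data capture gaps, and
demographic margins of any particular health system. The recovery tests
show the pipeline is a consistent estimator under the stated model, not
that the model is true.

## Problem sizes and numerical checks

The acceptance checks run: the hazard-recovery study with 2000 patients,
one continuous exposure year each, true ALT ≥3x hazard 0.30 per
person-year and weekly labs (the estimate must fall within 3 Monte-Carlo
standard errors of 30 per 100 py, with MC SE taken as rate/√cases); the
same histories under 90-day monitoring (fewer detected cases, more
person-time, strictly lower rate — detection attenuation of roughly 1 per
100 py at these settings, matching the analytic delay inflation
λ·E[delay]); the 1000-case episode oracle; and 10,000-replicate
Clopper–Pearson coverage at n = 150, p = 0.05. These sizes were chosen to
make Monte-Carlo error small relative to the assertions while keeping the
default test run short.

Degenerate inputs are defined, not patched: empty datasets produce empty
tables; zero denominators produce `NA` cells; an event date outside all
episodes is a contract violation, not silent truncation; unsorted interval
input is rejected. Ties at thresholds follow the catalog's inclusivity
flags exactly (a baseline of exactly 3.0x is ineligible for every ≥3x
category and eligible for every ≥5x one).

## Known limitations

Imputed durations make person-time approximate for oral drugs; prior use
outside the data is undetectable under the new-user rule; same-day
Hy's-law concurrency is strict (panels drawn a day apart are missed unless
the window is widened); the per-day maximum for ALT-or-AST can mask a
banded match when two same-day values straddle a band boundary; and the
DILI verdict is external by design. The published zero-case upper bounds
for some cells are internally inconsistent with the stated one-sided
formula; this package implements the formula and documents the
discrepancy rather than reproducing those cells.
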