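# hepatosafe

Hepatotoxicity surveillance pipelines for anti-VEGF new-user cohorts in
renal cell carcinoma (RCC).

## The problem

Pazopanib carries a boxed warning for liver injury; sunitinib, sorafenib
and bevacizumab have related hepatic safety signals. Post-marketing
surveillance of these drugs in routine care asks a concrete statistical
question: among adults with RCC newly started on an anti-VEGF drug, how
often do liver-chemistry (LC) values cross clinically meaningful multiples
of the upper limit of normal (xULN) while exposed, and does the
lab-combination signal for serious hepatocellular injury (Hy's law: ALT or
AST ≥3x ULN with total bilirubin ≥2x ULN and ALP <2x ULN) ever appear?

`hepatosafe` implements that common protocol as a tested, reusable R
pipeline over four flat EMR tables (patients, diagnoses, drug records, lab
results):

1. **New-user cohort selection** — first observed record of each anti-VEGF
   drug inside the accrual window, an RCC diagnosis (ICD-9 189.0/189.1) on
   or before start, age ≥ 18, baseline ALT and bilirubin within
   `[start − 30 d, start]`, and no concurrent anti-VEGF exposure; every
   exclusion is logged with a reason code.
2. **Treatment-episode (drug-era) construction** — recorded days supply or
   imputed durations (30 d pazopanib/sorafenib, 28 d sunitinib, 14 d per
   bevacizumab infusion), refills merged across coverage gaps of ≤ 30 days,
   episodes truncated when an alternate RCC treatment is initiated with no
   later index-drug record.
3. **Outcome classification** — a fixed catalog of xULN threshold
   categories for ALT/AST, ALP and bilirubin (open-ended and banded);
   per-category eligibility that removes patients whose baseline already
   reaches the category's lower threshold; first-elevation detection
   restricted to follow-up labs inside exposure episodes; same-day Hy's-law
   detection; a DILI screen (same-day ALT >3x with bilirubin >2x, or ICD-9
   codes 277.4, 570.x, 572.8, 573.3, 573.8, 576.8, 782.4) over the full
   anti-VEGF exposure span plus 90 days.
4. **Incidence estimation** — cumulative incidence `100·k/n` with exact
   (Clopper–Pearson) binomial 95% CIs, the one-sided 97.5% upper bound
   `100·(1 − 0.025^(1/n))` for zero-case cells, and incidence rates per
   100 person-years with exact Poisson (chi-square) CIs, person-time summed
   across episodes and censored at each patient's first event for the
   category; stratified by line of therapy.

A seeded synthetic EMR generator (`generate_dataset()`) emulates the
data-generating setting — accrual, refill gaps, scheduled lab panels,
log-normal baseline levels near 0.6x ULN, and constant per-drug elevation
hazards realized at the next scheduled lab — so every stage is testable
without access to a healthcare database. A handcrafted 20-patient fixture
(`generate_worked_fixture()`) pins every boundary case.

## Worked example

```r
library(hepatosafe)

ds <- generate_worked_fixture()
report <- run_study(ds)
report
#> <study_report: worked fixture>
#>   candidates     21 rows
#>   cohort         16 rows
#>   excluded        5 rows
#>   episodes       17 rows
#>   events         26 rows
#>   dili_flags      3 rows

subset(report$incidence,
       drug == "pazopanib" & category == "ALT/AST >=3x" &
         stratum == "overall",
       c(n_cases, n_evaluated, person_years, cum_inc_pct,
         cum_inc_lo, cum_inc_hi, rate_per_100py))
#> # A tibble: 1 × 7
#>   n_cases n_evaluated person_years cum_inc_pct cum_inc_lo cum_inc_hi rate_per_100py
#>     <int>       <int>        <dbl>       <dbl>      <dbl>      <dbl>          <dbl>
#> 1       0           5        0.698           0          0       52.2             0
```

Five of the six eligible pazopanib users are evaluated for ALT/AST ≥3x
(the sixth has a baseline ALT of exactly 3.0x ULN and is excluded from
that denominator), none elevates, and the zero-case cell carries the
one-sided 97.5% upper bound. `render_tables(report, "out/")` writes the
baseline, incidence, time-to-event, DILI-flag and exclusion tables as CSV
(or compact markdown with `4.6 (1.9, 9.3)`-style cells).

Statistical primitives are exported directly:

```r
cumulative_incidence(7, 151)   # 4.6
exact_binomial_ci(7, 151)      # 1.9 9.3
zero_case_upper_bound(155)     # 2.351825
incidence_rate(2, 25)$rate     # 8
```

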