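# hcmburden

Quantifying the clinical and economic burden of **obstructive hypertrophic
cardiomyopathy (oHCM)** from linked primary-care (CPRD GOLD/Aurum-like) and
secondary-care (HES-like) electronic health records — as a tested, reusable
R pipeline.

It is written for epidemiologists and health-economics analysts who work
with flat-table EHR extracts and need the full chain: cohort construction,
severity classification, treatment-pattern analysis, incidence estimation
and costing, with every step testable without access to licensed data.

## What it computes

NYHA functional class (I–IV) is the severity axis of the analysis, but is
coded in only ~1% of primary-care records. The package's core is a **proxy
NYHA classifier**: a configurable decision tree over therapy exposure
(beta-blockers, non-dihydropyridine calcium-channel blockers, disopyramide,
loop diuretics), recorded symptoms, and heart-failure hospitalizations.
For patient *i* on day *t* the raw class is

    raw(i,t) = IV   if HF hospitalization within the last 90 days
             = III  if disopyramide or loop diuretic active, or ≥2 agents active
             = II   if exactly one agent active
             = I    otherwise
    + 1 class (capped at IV) if ≥2 distinct symptom concepts in the last 90 days

where "active" means prescription date + days' supply + 30-day grace. An
**asymptomatic-correction ratchet** blocks any II+→I transition unless an
intervention (SRT, device insertion, therapy initiation) occurred during
the symptomatic spell; recorded NYHA codes always win. The resulting
trajectory of half-open intervals tiles each patient's follow-up exactly
and drives three stratified analyses:

* **Treatment pathways** — prescription-episode construction (supply-gap
  merging), regimen labelling, and a mutually exclusive, exhaustive
  first-change taxonomy (no-treatment ≥90-day gap, augment,
  discontinuation, switch within/between class, switch with addition),
  plus Kaplan–Meier cumulative-risk curves.
* **Clinical outcomes** — first-occurrence and repeatable (30-day dedup)
  event rules; incidence per 100 patient-years per time-varying NYHA
  stratum with exact Poisson (Garwood) or clustered negative-binomial CIs.
* **Costing** — unit-cost tables for non-inpatient activity, HRG lookup
  for inpatient episodes, inflation uplift, and per-patient-year costs by
  NYHA stratum with exact additivity.

A seeded **synthetic EHR generator** with a latent Markov severity process
supplies ground truth: recovery tests verify that configured event rates
and the latent NYHA trajectory are recovered by the pipeline.

## Worked example

```r
library(hcmburden)

pl <- run_pipeline(gen_config(n_patients = 150), seed = 42)
glance(pl)
#> # A tibble: 1 × 5
#>   n_identified n_included n_obstructive person_years cost_per_py
#> 1          150        128            70         295.        4847
```

150 simulated patients are identified by an HCM code; 128 survive the
eligibility criteria and 70 form the obstructive cohort, contributing 295
person-years at a total cost of £4,847 per patient-year. Stroke incidence
rises with time-varying NYHA class:

```r
dplyr::filter(pl$incidence, event == "stroke")
#>   event  nyha_class events person_years  rate ci_low ci_high method
#> 1 stroke          1      1         19.4  5.14  0.130    28.7 poisson_exact
#> 2 stroke          2      3         80.5  3.73  0.768    10.9 poisson_exact
#> 3 stroke          3     11        127.   8.66  4.32     15.5 poisson_exact
#> 4 stroke          4     14         67.9 20.6  11.3      34.6 poisson_exact
```

(the generator's configured rates are 2/6/12/20 per 100 patient-years), and
costs per patient-year rise from £996 in class I to £12,498 in class IV:

```r
subset(pl$costs, component == "total")
#>   stratum component   total person_years cost_per_py
#> 1 I       total       19368         19.4         996
#> 2 II      total      159889         80.5        1986
#> 3 III     total      401316        127.         3158
#> 4 IV      total      849033         67.9       12498
#> 5 II+     total     1410238        276.         5118
#> 6 overall total     1429606        295.         4847
```

`autoplot(pl$incidence)`, `plot_nyha_distribution(pl$nyha_distribution)`
and `plot_cost_summary(pl$costs)` draw the corresponding figures, and each
stage (`build_cohort()`, `classify_nyha()`, `build_exposure_intervals()`,
`identify_events()`, `estimate_incidence()`, `stratified_costs()`,
`suppress_small_cells()`, ...) is exported for standalone use on your own
tables in the same schemas. The methods vignette
(`vignettes/ohcm-burden-methods.Rmd`) documents the model, its parameters
and its limitations.

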