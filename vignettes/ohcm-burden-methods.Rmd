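---
title: "Methods: quantifying the burden of obstructive HCM from linked EHRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the burden of obstructive HCM from linked EHRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcmburden)
library(dplyr)
```

# The problem

Obstructive hypertrophic cardiomyopathy (oHCM) is a progressive disease whose
clinical and economic burden rises with functional severity, conventionally
graded by the New York Heart Association (NYHA) classes I (asymptomatic) to
IV (symptoms at rest). Routine UK electronic health records — primary-care
extracts in the shape of CPRD GOLD/Aurum linked to Hospital Episode
Statistics (HES) — contain the raw material for a burden analysis (diagnosis
codes, prescriptions, consultations, admissions, deaths) but almost never a
coded NYHA class: recorded NYHA codes appear in roughly 1% of patients. The
central methodological device of this package is therefore a **proxy NYHA
classifier**: a configurable decision tree over medications, symptoms and
heart-failure hospitalizations, applied once at diagnosis and then daily over
follow-up, that supplies the time-varying severity axis along which treatment
patterns, clinical-event incidence and healthcare costs are stratified.

Because the licensed source data cannot be redistributed, the package ships a
seeded synthetic EHR generator with a latent severity process. Every
downstream stage is exercised, and its statistical behaviour verified,
against data whose ground truth is known.

# Cohort construction

Patients enter the analysis at their **index date**, the earliest HCM
diagnosis code (ICD-10 / Read / SNOMED / OPCS, via the codelist table) inside
the study window. Patients carrying any obstructive code form the obstructive
cohort, with the index at the earliest *obstructive* code even when a
non-obstructive code came first; codes that do not specify the subtype pool
with the non-obstructive cohort. Eligibility requires age 18+ at index, one
year of continuous pre-index registration, provider-determined research
quality and linkage eligibility (boolean input columns — they are not
computable from record content), no exclusion condition (hypertensive heart
disease, aortic stenosis, athlete's heart, storage disease, Takotsubo,
Anderson–Fabry, Pompe's, amyloidosis) anywhere in the study period, and an
index late enough that the two-year look-back fits inside the study window.
Follow-up runs to the earliest of study end, death, practice last collection
and deregistration.

Baseline characterization uses two windows, both inclusive of the index day:
conditions in the 2 years (730 days) before index, and "active"
prescriptions in the 6 weeks (42 days) before index. The age-adjusted
Charlson score sums classic condition weights over the flagged conditions
and adds one point per full decade of age over 40; the weight table is an
argument, and no cap is applied to the age term because none is imposed by
the reporting convention we follow.

# The proxy NYHA classifier

**Baseline.** A recorded NYHA code on or before index wins outright
(provenance `"recorded"`). Otherwise the default tree is:

* heart-failure hospitalization (a heart-failure code in the secondary-care
  setting) within the past 90 days → IV;
* disopyramide, a loop diuretic, or two or more distinct HCM-relevant
  products (beta-blockers, non-dihydropyridine calcium-channel blockers,
  disopyramide) prescribed in the day −2..+28 medication window → III;
* exactly one such agent → II; none → I;
* then one class is added (capped at IV) when at least two *distinct*
  symptom concepts (breathlessness, fatigue, oedema, palpitations,
  dizziness, syncope, chest pain, angina, pre-syncope, tachycardia) occur
  within the symptom look-back.

The published tree's internal branches are not public; this default
reproduces its qualitative ordering, and *every* branch — windows,
thresholds, the symptom step, the intervention set — is a parameter of
`nyha_ruleset()`. Correctness is established by configuration-driven
recovery tests (below), not by claiming the unpublished tree.

**Daily.** The same rules run conceptually on every follow-up day, with two
differences: a medication is "active" from its prescription date through
days' supply plus a 30-day grace period, and symptoms count within a 90-day
look-back. The implementation is event-wise — every input opens or closes a
dated half-open interval, and the class is evaluated on the induced
segmentation — which is exactly equivalent to a literal day loop; the test
suite replays random fixtures day by day with an independent oracle to prove
it. Recorded NYHA codes during follow-up override the proxy from their date
until the raw rule-driven class next changes.

**The ratchet (asymptomatic correction).** A symptomatic patient (II+)
cannot return to class I without an intervention. Walking each patient's
segments forward, a proxy drop to I is blocked — the previous class is
held — unless an intervention (septal reduction therapy, ICD or pacemaker
insertion, or initiation of a new HCM-relevant product; configurable)
occurred since the patient last entered the symptomatic spell. Recorded
segments are authoritative and exempt. Day 0 of the series carries the
baseline class, so a baseline-symptomatic patient stays II+ until released.

Maximal runs of equal class and provenance are compressed to half-open
intervals that tile follow-up exactly; person-time bookkeeping is in integer
days (reported as days/365.25 years), so conservation checks are exact.

# Treatment pathways

Prescriptions with positive days' supply become per-product exposure
intervals `[date, date + supply)`, merged when the gap to the next supply of
the same product is at most 30 days (the published analysis fixes only the
90-day *no-treatment* gap; the 30-day join is this package's choice and an
argument). Partitioning the timeline at every product boundary yields
regimen intervals labelled by therapy-class multiset ("BB monotherapy",
"BB + BB dual therapy", ...). The first departure from the initial regimen
is classified by a first-match decision order:

1. products strictly added → **augment**;
2. products strictly removed → **discontinuation**;
3. same class multiset, different products → **switch within class**;
4. more products after a replacement → **switch with addition**;
5. anything else → **switch between classes**;

with a ≥90-day supply gap (dated at the end of the last exposure — the
earliest detectable point) counted as **no treatment** and a composition
change occurring before a gap reaches 90 days taking precedence by strict
date order. Steps 4–5 complete the published taxonomy for transitions it
does not spell out (e.g. a shrinking non-subset change); an enumeration test
over all class multisets up to size three verifies the order is exhaustive
and single-valued. Time-to-first-change curves are one minus the
Kaplan–Meier product-limit estimate (via the survival package), checked
against a brute-force risk-set oracle.

# Clinical events and incidence

Chronic conditions (AF/flutter, cardiac dysrhythmias, conduction disorders,
heart failure, dilated cardiomyopathy, device insertions, all-cause
mortality) count at first in-study occurrence only, excluding patients with
a pre-index record. Acute events (MI, stroke, VT, SRT, DVT/PE, cardiac
arrest/VF) are repeatable, deduplicated by a greedy forward scan keeping a
code only when ≥30 days after the last *kept* code — the greedy reading is
deterministic and order-stable where "codes ≥30 days apart" is ambiguous.

Each event is attributed to the NYHA interval containing its date, and rates
are events per 100 patient-years of stratum person-time. The default
confidence interval is the exact Poisson (Garwood) chi-square form; a
negative-binomial alternative with patient-clustered robust variance
(`method = "nb_robust"`) is provided. A GEE with AR(1) working correlation
would not change the unadjusted point rates and is deliberately not
re-implemented; the variance method is the documented approximation
difference.

# Costing

Non-inpatient activity (GP, nurse and telephone consultations; outpatient,
A&E and critical-care attendances; OPCS/Read-coded tests and procedures) is
costed as count × unit cost × a single multiplicative inflation factor,
mirroring a National-Schedule-plus-PSSRU-uplift workflow. Out-of-hours
consultations are counted but never costed. Inpatient episodes (elective,
non-elective, day case) are costed per episode by HRG currency code, with a
configurable policy for unpriced codes. Each dated cost item is attributed
to the NYHA interval containing its date; a multi-day stay spanning a class
change attributes its full cost to the class at admission (simple, and the
alternative per-day split is not observable in the published convention).
Totals divide by the *same* person-years as the trajectory, are exactly
additive across strata and components before rounding, and are reported to
the nearest pound (half-up).

# Reporting and disclosure control

Published-table shapes carry UK-style statistical disclosure control:
primary suppression of counts 1–4, then, while any row or column with a
shown total has exactly one suppressed cell, secondary suppression of the
smallest remaining shown cell, iterated to a fixpoint (the exact published
secondary rule is unstated; this fixpoint rule is our documented choice).
Percentages are reported half-up at one decimal place (two for attrition,
whole pounds for costs).

# The synthetic generator and what the tests show

Each simulated patient has a registration window inside the 2007–2020 study
window, a diagnosis date biased early in registration (squared-uniform draw;
mean follow-up ≈ 3.5–5 years), and a latent NYHA class evolving on a 30-day
month grid by a row-stochastic transition matrix. Defaults are chosen once
as study conditions: the baseline class distribution (25.9 / 33.9 / 37.7 /
2.5%), 61.9% male, mean age 61 (SD 15.6), 57.9% obstructive coding, 1.26%
recorded-NYHA prevalence, and an upper-triangular (progression-only)
transition matrix with monthly progression probabilities of 0.5–2% —
spontaneous improvement is excluded to match the clinical premise behind the
ratchet. Observable rows are emitted with class-dependent rates; by default
emission is *rule-consistent*: prescribing tracks the latent class exactly
(none / one BB / BB+CCB), class IV emits a heart-failure admission on entry
and every 90 days, and symptom codes reuse a single concept so the
two-distinct-symptom adjustment never fires. One global seed streams
per-patient sub-seeds, so any patient regenerates identically regardless of
cohort size.

Under these conditions the recovery suite (n = 2000, three fixed seeds)
shows that configured event rates rising from 2 to 20 per 100 patient-years
across classes are re-estimated within their 95% confidence intervals and in
strictly increasing order, and that the proxy trajectory matches the latent
truth on more than 99% of person-days (the acceptance threshold is 95%,
covering window-edge effects at the index date). What this does *not* show
is performance on real data: real prescribing is not rule-consistent, real
symptoms are coded erratically, and the true decision tree's unpublished
edge cases may differ. The generator validates the *machinery* — windows,
interval algebra, ratchet, estimators, conservation — not the clinical
accuracy of the proxy.

Latent severity is simulated from registration start, so the class mix at
diagnosis is somewhat more severe than the configured baseline distribution
(progression accrues during the pre-diagnosis years); this is intentional
realism, not calibration drift.

# Numerical conventions and edge cases

* All intervals are half-open `[start, end)` on a day grid; the index day is
  day 0; an event on an interval boundary belongs to the interval opening
  that day.
* Person-time is summed in integer days and divided by 365.25.
* Ties: multiple HCM codes on one day resolve obstructive > non-obstructive
  > unspecified; the closest recorded NYHA code on/before index wins at
  baseline; secondary suppression picks the first of tied smallest cells.
* Degenerate inputs: zero-length registration windows produce empty paths;
  empty cohorts produce empty reports without division; zero person-time
  strata are omitted with a warning; negative days' supply is rejected with
  a warning, zero supply silently dropped.
* Problem sizes: the bundled tests run cohorts of 40–80 patients for
  pipeline checks and 2000 patients × 3 seeds for the recovery suite —
  sizes at which every binomial/Poisson tolerance in the tests is
  well-powered.

# Known limitations

* The proxy tree is a configurable stand-in for an unpublished algorithm;
  agreement with physician-assigned NYHA is untestable here.
* Dose changes are invisible: prescriptions carry no dose field, so
  within-product titration never registers as a treatment change.
* The "no treatment" gap is assessed across all HCM-specific classes
  jointly, not per class.
* Costing uses synthetic unit-cost and HRG tables in the correct shapes;
  absolute synthetic costs are illustrative.
* The generator's death process is off by default; with it enabled, deaths
  can precede diagnosis and such patients must be filtered upstream.

# A worked run

```{r pipeline}
pl <- run_pipeline(gen_config(n_patients = 150), seed = 42)
glance(pl)
pl$nyha_distribution
head(pl$incidence)
subset(pl$costs, component == "total")
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(pl$incidence)
plot_cost_summary(pl$costs)
```
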