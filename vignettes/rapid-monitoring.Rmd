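---
title: "Rapid monitoring of a biosimilar switching policy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rapid monitoring of a biosimilar switching policy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The monitoring problem

When a drug plan mandates a nonmedical switch — here, from originator to
biosimilar infliximab for patients with inflammatory bowel disease (IBD) —
regulators want early warning of unintended harm without waiting for a
powered hypothesis-testing study. `switchsignal` implements a rapid-cycle
design for that setting:

1. Identify prevalent originator-infliximab users with IBD in a 6-month
   identification window immediately before the policy (March 7 to
   September 4), indexed on the policy date (September 5), and follow them
   365 days. Day 1 of follow-up is the index date itself.
2. Build the same cohort in each of several pre-policy years; these
   historical cohorts estimate the expected trend absent the policy.
3. For each medication or health-service endpoint, track the daily
   cumulative incidence — the percentage of cohort members with the event on
   or before each day, over a fixed denominator (no censoring).
4. Flag a signal when the daily likelihood ratio comparing the policy cohort
   to the historical experience stays above `exp(1.96) ≈ 7.1` for at least
   30 consecutive days.

The likelihood ratio at day $t$ is the generalized two-sample binomial
statistic at the cumulative counts: with $x_1(t)$ events among $n_1$ policy
patients and $x_0(t)$ among $n_0$ pooled historical patients,

$$\log LR(t) = \ell(x_1; n_1, \hat p_1) + \ell(x_0; n_0, \hat p_0)
             - \ell(x_1; n_1, \hat p) - \ell(x_0; n_0, \hat p),$$

where $\ell$ is the binomial log-likelihood kernel, $\hat p_1, \hat p_0$ are
the per-group proportions and $\hat p$ the pooled proportion; zero-count
terms contribute nothing. The statistic is two-sided by construction and at
least 1, with equality exactly when the proportions coincide; twice its
logarithm is the $G^2$ statistic of the corresponding 2×2 table, which the
test suite verifies against an independent contingency-table oracle. The
7.1 threshold is an approximate analogue of a two-sided $\alpha = 0.05$; the
likelihood-ratio scale has the practical advantage that daily re-inspection
does not change its interpretation. A run above threshold that ends before
day 365 is classified *transient* (events occurred earlier without a net
excess); a run reaching day 365 is *sustained to the end*.

### Averaging vs pooling the historical cohorts

The displayed cumulative-incidence difference uses the *unweighted mean* of
the historical cohorts' percentages, treating each year as one realization
of the historical trend. The likelihood, however, needs counts, so it uses
the *pooled* historical events and denominators. When cohort sizes differ
the two weightings differ slightly; both quantities are carried in the
output (`ci_hist_mean` and the pooled counts behind `lr`) so the discrepancy
is visible rather than hidden.

### Other monitoring choices

* Threshold crossing is strict (`lr > 7.1`); runs are maximal consecutive-day
  sequences; both the threshold and the 30-day sustain length are arguments.
* Likelihood ratios are computed and compared on the log scale; values are
  clamped at $\log LR = 0$ to absorb floating-point noise around equality
  (the exact statistic cannot be negative).
* Denominators stay fixed at the cohort size for all 365 days. No censoring
  for death or disenrollment, no covariate adjustment, and no correction for
  the same patient appearing in several cohorts — the design accepts these
  simplifications for speed, which is why a signal is a trigger for further
  analysis, not a verdict.

## Cohort construction

Candidates need one originator-infliximab dispensation dated inside the
identification window plus any of three IBD markers: an infliximab
dispensation prescribed by a gastroenterologist (on or before index), at
least two gastroenterology outpatient visits in the 365 days before index,
or an IBD-flagged visit or hospital record in that year. Exclusions then
apply in a fixed order, each patient counted once at the first applicable
rule:

1. **Discontinuers** — the last in-window originator dispensation's days of
   supply plus a 30-day grace period ends before the index date.
2. **Switchers** — a biosimilar or other-biologic dispensation after the
   last originator dispensation and on or before index.
3. **Lack of enrollment** — no health-plan enrollment span covering index.
4. **No public coverage** — no payer-accepted in-window originator
   dispensation.

The exact ascertainment windows of the original administrative algorithms
are not observable in this data model, so the grace period (30 days), the
"frequent visits" threshold (2 per year) and the lookback length (365 days)
are explicit `cohort_params()` with those defaults; low compliance is folded
into the supply-coverage rule rather than a separate proportion-of-days
calculation. Patient-flow accounting is conservation-checked: the final size
always equals the IBD-user count minus the four exclusion counts.

## Endpoints

Sixteen endpoints are monitored. Medication endpoints: the 1st–4th
infliximab dispensation (either product; same-day records collapse to one
event), first dose escalation, first switch to a different biologic, first
IBD-related antibiotic dispensation, and first *new* prednisone use — a
prednisone dispensation with no systemic-corticosteroid supply interval
touching the 183 days before it ("6 months" is fixed as 183 days).
Health-service endpoints: 1st–4th outpatient visit to a physician or nurse
practitioner, first gastroenterologist visit, first emergency-department
visit, first hospital discharge (the event day is the discharge date, so a
stay straddling index counts), and first emergency admission (event day is
the admission date).

Dose escalation is a dispensation whose daily dose — total mg dispensed that
day divided by days of supply, summed over same-day records — is at least
1.25 times the mean daily dose of all earlier dispensations on record,
pre-index included (a configurable lookback window can restrict the
baseline). The ratio test is inclusive and applied with a $10^{-9}$ relative
tolerance so that an exact 25% increase counts regardless of floating-point
representation. A patient whose first-ever dispensation falls inside
follow-up has no baseline and cannot escalate at that dispensation. The
product in use at the first escalation (originator vs biosimilar) is
recorded alongside the event day.

## The synthetic-claims generator

The real monitoring data are restricted provincial administrative holdings,
so the package ships a seeded generator whose output has the structure the
analysis assumes, with every parameter surfaced in `scenario_config()`.
**All defaults are stand-ins**: the source setting publishes no generative
parameters, so defaults were chosen once, up front, to reproduce its
published cohort structure — final cohorts of roughly 1,800–2,000 from 2,400
simulated users per year, ages 4–90 with mean ≈ 43 (SD 17), 54% male, an
8-weekly (56 ± 7 days, floored at 28) dispensation cadence at 300–500 mg per
cycle, a rising no-coverage exclusion across years, ~92% switch uptake
uniform over a 182-day transition, and a 0.7% switch-back rate.

Endpoint events are independent constant-hazard (exponential) processes per
patient, with the policy year's hazards multiplied by configurable hazard
ratios. This is the simplest structure that makes the pipeline analytically
checkable: for a constant daily hazard $h$ the cumulative incidence must be
$100\,(1 - e^{-ht})$, which `expected_cumulative_incidence()` returns and
the test suite compares against the full simulate→cohort→ascertain→count
path within three binomial standard errors at 5,000 patients per cohort.
Default baseline hazards put the historical year-365 incidences near 46%
(dose escalation), 60% (first gastroenterologist visit), 20% (emergency
department), 12–13% (antibiotics, new prednisone) and 7% (emergency
admission); the outpatient-visit process runs at 0.05/day so prior-year
visit counts land near the published 18–31 per patient. The default policy
effects (1.58 for dose escalation, 1.95 for gastroenterologist visits, 0.6
for emergency admissions, 0.8 for antibiotics and prednisone) reproduce the
published maximal cumulative-incidence differences of roughly +16, +24, −3
and −2 percentage points. Visit and admission endpoints are thinned Poisson
processes, so n-th-event and discharge endpoints have no closed form —
`expected_cumulative_incidence()` refuses them rather than approximating.

What the generator deliberately does **not** emulate, and what passing tests
therefore cannot show about real data:

* **Multi-year persistence.** Each year's users are drawn fresh and their
  enrollment ends with their follow-up, so a wave resurfaces as next-year
  candidates only to be removed by the enrollment criterion; real patients
  persist on therapy and appear as members of several cohorts. Multi-cohort
  membership itself is supported and unit-tested on fixtures.
* **Time-varying hazards.** Real dose escalation accelerated from month 3;
  constant-hazard injection makes effects visible from day 1, so simulated
  onset days are earlier than published ones.
* **Concurrent shocks.** No pandemic-style disruption of visits and
  dispensations, no stockpiling, no pediatric transition extension.
* **Clinical texture.** No comorbidity, costs, procedure codes, Crohn's vs
  ulcerative-colitis split (diagnosis is abstracted to a boolean IBD flag),
  and no pre-index endpoint history beyond visits and stays.

## Numerical and degenerate-input conventions

Dates serialize as ISO-8601 in comma-separated tables; reading is total —
every invariant violation is reported with table, row and reason, and an
unparseable date names its line. Percentages in rendered tables round half
away from zero to one decimal. A month with no infliximab dispensations
reports a missing share, never 0. Single-patient cohorts report a missing
SD. Zero-candidate cohorts short-circuit with zeroed flow. Empty bundles
round-trip as four headered files.

## Problem sizes in the test suite

The suite exercises the statistical properties at sizes chosen to make
Monte-Carlo conclusions stable: generator fidelity at 5,000 patients per
cohort; effect recovery over 50 seeded replicates at the study's scale
(policy ≈ 1,800 vs pooled ≈ 6,600); null calibration over 100 seeded
replicates at 500 users per year, where the sustained-signal frequency must
fall strictly as the threshold rises through 3, 7.1 and 20. All seeds are
fixed, so the assertions are deterministic.
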