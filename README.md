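# switchsignal

Rapid signal monitoring of a mandatory biosimilar switching policy from
administrative-claims-shaped data.

When British Columbia's drug plan required patients with inflammatory bowel
disease (IBD) on originator infliximab to switch to a biosimilar, the
question for pharmacoepidemiologists was not "is the biosimilar
non-inferior?" but "is anything going wrong, fast?". `switchsignal`
implements that rapid-monitoring design end to end for analysts working with
claims-shaped tables (enrollment spans, pharmacy dispensations,
outpatient/ED visits, hospital stays):

* **Cohorts** — a policy cohort of prevalent originator-infliximab users
  with IBD identified in the 6 months before the policy (March 7 –
  September 4, index September 5, 365-day follow-up), plus the same cohort
  built in earlier years as the expected-trend comparator, with full
  patient-flow accounting (discontinuers, switchers, enrollment, public
  coverage).
* **Endpoints** — 16 medication and health-service endpoints per cohort
  member: 1st–4th infliximab dispensation, dose escalation (daily dose ≥
  1.25× the mean of all earlier dispensations), switch to another biologic,
  IBD-related antibiotics, new prednisone use (183-day corticosteroid
  washout), 1st–4th physician/nurse-practitioner visit, gastroenterologist
  visit, emergency-department visit, hospital discharge, emergency
  admission.
* **Monitoring** — daily cumulative incidence with fixed denominators; the
  cumulative-incidence difference against the unweighted mean of the
  historical cohorts; and a daily two-sample binomial likelihood ratio
  against the pooled historical counts,

  log LR(t) = x₁ log(p̂₁/p̂) + (n₁−x₁) log((1−p̂₁)/(1−p̂))
            + x₀ log(p̂₀/p̂) + (n₀−x₀) log((1−p̂₀)/(1−p̂)),

  with a signal declared when LR stays above exp(1.96) ≈ 7.1 for ≥ 30
  consecutive days (transient if the run ends before day 365, sustained
  otherwise). 2·log LR equals the G² statistic of the corresponding 2×2
  table.
* **Synthetic claims** — a seeded generator (`scenario_config()`,
  `simulate_claims()`) with constant-hazard endpoint processes and
  configurable policy effects, so the whole pipeline is testable without
  access to restricted health data. Constant hazards make the simulated
  pipeline analytically checkable against `100·(1−exp(−h·day))`.

## Worked example

The `analysis/` scripts run the full study on the default synthetic
scenario; each stage writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # claims tables -> results/claims/
Rscript analysis/02_build_cohorts.R  # patient flow + characteristics
Rscript analysis/03_switch_uptake.R  # monthly share + switch curve
Rscript analysis/04_monitor.R        # comparison series + signal report
Rscript analysis/05_report.R         # per-endpoint panels
```

With the default seed the cohorts come out at 2,002 / 1,940 / 1,877
historical and 1,873 policy members, mean age ≈ 43, ~55% male. Stage 3
prints:

```
Adult biosimilar share Aug 2018 - Aug 2019 (pre-policy): 9.1-15.5%
Adult biosimilar share in Aug 2020: 93.2%
Policy-cohort switch uptake by day 365: 93.0%
Switch-back to originator among switchers: 0.7%
```

and stage 4 summarizes the signals, e.g.:

```
dose_escalation            sustained-to-end   onset    1  max cid  +16.0 pp (day 359)
gastroenterologist_visit   sustained-to-end   onset    4  max cid  +24.8 pp (day 268)
new_prednisone             sustained-to-end   onset   30  max cid   -3.9 pp (day 344)
emergency_admission        sustained-to-end   onset   85  max cid   -2.5 pp (day 364)
ed_visit                   no signal          onset    -  max cid   +1.1 pp (day 330)
```

Read: under the injected scenario, dose escalation rises ~16 percentage
points above the historical average by the end of follow-up and the
likelihood ratio stays above 7.1 from day 1 (the generator injects effects
from day 1; in real data onset came later), gastroenterologist visits rise
~24 points, emergency admissions fall, and emergency-department visits show
no signal. The signal classification, onset day, maximal difference and
above-threshold intervals per endpoint are in `results/signal_report.json`.

## Scope

The package abstracts drugs to a closed `drug_class` vocabulary and
diagnoses to a boolean IBD flag; it does not parse real provincial extracts
or procedure codes, model concurrent shocks (e.g. pandemic disruption), or
perform covariate-adjusted inference — the monitoring statistic is a trigger
for further analysis, not a hypothesis test. See
`vignettes/rapid-monitoring.Rmd` for the model, parameter rationale and
limitations.
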