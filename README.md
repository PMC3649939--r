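# npccdb

Longitudinal clinical modelling of Niemann-Pick disease type C (NP-C)
cohorts.

NP-C is a rare, progressive lysosomal storage disorder whose neurological,
cognitive, psychiatric and visceral signs arise at widely varying ages and
in varying order; diagnosis is typically delayed by years. Natural-history
registries reconstruct, per patient, the age at which each sign first
manifested. `npccdb` is the analysis layer for such records, for
biostatisticians and clinical researchers working with rare-disease
registry data:

* **Data model & IO** — validated per-patient symptom-onset histories,
  read/written as a CSV pair (`patients.csv` + long-format `events.csv`,
  with optional `oxysterols.csv` / `risk_answers.csv`) or a single nested
  JSON document; symptom catalogs and screening rubrics as YAML/JSON
  configuration.
* **NPC-cdb score** — the cumulative severity-weighted outcome scale
  `S(t) = Σ w_j · 1[symptom j manifested by t]`, each symptom contributing
  once, at first manifestation, and persisting; plus a seizure-"cleaned"
  variant that excludes seizure-domain score points.
* **Censored Kaplan-Meier time-to-symptom curves** normalized to
  neurological onset (`Ŝ(t) = Π (1 − d_i/n_i)`), hand-implemented with
  Greenwood variance, log-log pointwise bounds, Brookmeyer–Crowley median
  confidence intervals, and symptom ranking by median onset.
* **Progression typology** — steady / fulminant (all annual scores strictly
  above the cohort mean) / accelerated (continuous two-segment changepoint
  fit with post/pre slope ratio ≥ 2 and an F criterion), with exhaustive
  breakpoint search.
* **Exact association tests** — a two-sided Fisher exact test by full
  hypergeometric enumeration, applied to seizure-linked acceleration (with
  seizure-cleaned score increments ±2 y around the first seizure) and to
  screening-index sensitivity vs. disease duration; oxysterol–score linear
  correlation with screening cut-offs (24.5 / 47.5 ng/mL).
* **Synthetic cohorts** — a seeded generator calibrated to published cohort
  statistics (onset 7.9 ± 6.9 y; diagnostic delay 5.7 ± 7.6 y; progression
  mix 24/37, 7/37, 6/37 with ~2.9-fold acceleration 6.7 ± 2.5 y after
  onset; 35% seizure prevalence with seizures preceding the decline), with
  latent truths recorded for parameter-recovery testing.

Everything is tibble-in / tibble-out with `tidy()`, `glance()` and
`autoplot()` methods, so results compose with dplyr and ggplot2.

## Worked example

```r
library(npccdb)
library(dplyr)

co <- generate_cohort(generator_config(n_patients = 200, seed = 1))
co
#> <npc_cohort> 200 patients (189 with neurological onset), 4027 events
#>   provenance: npccdb::generate_cohort

glance(symptom_onset_curve(co, "cognitive_impairment"))
#> # A tibble: 1 × 7
#>       n events median median_lower median_upper rmean rmean_tmax
#>   <int>  <int>  <dbl>        <dbl>        <dbl> <dbl>      <dbl>
#> 1   189    153    3.6          3.2            4  6.45       27.8
```

189 of 200 synthetic patients have a neurological onset; 153 manifest
cognitive impairment within follow-up, and the Kaplan-Meier median onset is
3.6 y (95% CI 3.2–4.0) after neurological onset — recovering the configured
3.4 y within Monte-Carlo error and mirroring the published estimate for the
real cohort.

```r
glance(cohort_trend(score_trajectories(co)))
#> # A tibble: 1 × 4
#>   slope intercept r_squared n_times
#>   <dbl>     <dbl>     <dbl>   <int>
#> 1  1.92      8.20     0.953      50

classify_cohort(co) |> count(label)
#> # A tibble: 4 × 2
#>   label                 n
#>   <chr>             <int>
#> 1 accelerated          41
#> 2 fulminant            13
#> 3 insufficient_data    25
#> 4 steady              110
```

The cohort mean score rises near-linearly (1.92 points/y, R² = 0.95), while
individual courses split into the three clinical archetypes.

```r
seizure_association(co, match_seed = 1)
#> <npc_assoc> Fisher exact p = 0.01408
#>              accelerated not_accelerated
#> seizure               23              31
#> seizure_free          19              66
```

Patients whose first seizure is followed within two years by a doubling of
their seizure-cleaned score increment are over-represented relative to
matched seizure-free comparators (p = 0.014 at n = 200; the association
strengthens with cohort size).

See `vignette("npccdb-methods")` for the model, its assumptions, and every
calibration decision.

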