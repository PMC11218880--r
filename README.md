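# rarwatch

Surveillance and association analysis of **wrong-patient retract-and-reorder
(RAR) events** in computerized provider order entry (CPOE) logs.

Wrong-patient order entry — a provider intending to order for one patient but
signing the order on another — is rare, dangerous, and hard to observe
directly. The RAR measure is the field's validated near-miss proxy: an order
**retracted within 10 minutes** of placement and re-placed by the **same
provider** as the **same order** on a **different patient within 10 minutes**
of the retraction. `rarwatch` implements the measure and the full
session-level epidemiological analysis around it, for informaticists and
patient-safety researchers who want to evaluate interventions (such as
attaching patient photographs to the chart) against audit-log data.

## What the package does

* **Detect** — `detect_rar_events()` scans a time-stamped order log for RAR
  signatures with one-to-one, greedy earliest-first matching; windows are
  open at 0 s and closed at 600 s, both configurable. A quadratic brute-force
  oracle in the test suite guarantees exact equivalence.
* **Sessionize** — `build_sessions()` groups orders into *order sessions*
  (all orders one provider signs for one patient at one sign time), the unit
  of analysis: if one order of a session is on the wrong patient, all of them
  are. `build_analysis_table()` attaches the exposure (a patient photo on
  file *strictly before* the session sign time) and all covariates;
  `rar_rate()` reports events per 100 000 sessions.
* **Analyze** — cross-product odds ratios with Wald intervals
  (`contingency_or()`), one-vs-rest contrasts (`one_vs_rest_tables()`),
  Pearson chi-square and equal-proportion tests (no continuity correction),
  Welch t-tests from summary statistics, a P < .1 univariable screen, the
  multivariable logistic model with one-vs-rest race indicators
  (`fit_logistic()`), a patient/provider random-intercept sensitivity fit
  (`fit_logistic_mixed()`, via lme4), and a photo-uptake predictor model.
* **Simulate** — `generator_config()` + `generate_cohort()` +
  `generate_order_log()` emulate a pediatric inpatient order log
  (~30 RAR events per 100 000 sessions, ~17% photo exposure under a staged
  rollout, covariate-dependent risk with photo OR 0.6 and cardiac/ICU
  OR ≈ 2) and emit a ground-truth ledger of every injected signature, so the
  whole pipeline is testable without hospital data.
* **Report** — `trend_series()` bins monthly rates stratified by photo
  status; `run_pipeline()` orchestrates generate → detect → sessionize →
  analyze → report with a manifest of row counts at every stage. A thin CLI
  lives at `inst/cli/rar.R`.

The model behind both the generator and the analysis is ordinary logistic
regression on the session level,

    logit P(RAR) = β₀ + β_photo·photo + β_age·age + β'·context ,

with odds ratios `exp(β)` reported with 95% Wald intervals.

## Worked example

Feeding the published session-characteristic counts of a large pediatric
inpatient cohort (3 414 770 order sessions, 944 RAR sessions) through the
contingency machinery:

```r
library(rarwatch)
counts <- reference_session_counts()
contingency_or(counts_pair_table(counts, "photo", "Yes", "No"))
#> OR 0.522 (95% CI 0.420-0.649), p = 4.57e-09  [wald]
```

A photo in the chart before the session sign time is associated with roughly
half the odds of a RAR event. And end-to-end on synthetic data:

```r
cfg <- generator_config(n_patients = 4000, n_providers = 4,
                        sessions_per_patient_mean = 12.5,
                        base_wpoe_rate = 2e-3, seed = 99)
cohort <- generate_cohort(cfg)
log <- generate_order_log(cfg, cohort$patients, cohort$providers)
events <- detect_rar_events(log$orders)
sessions <- build_sessions(log$orders, rar_order_ids(events))
rows <- build_analysis_table(sessions, cohort$patients, cohort$providers)
rar_rate(rows)
#> # A tibble: 1 × 3
#>   events sessions  rate
#>    <int>    <int> <dbl>
#> 1     68    50155  136.
```

68 of 50 155 synthetic sessions were flagged (136 per 100 000 — the inflated
`base_wpoe_rate` makes the signal visible at this small scale). The
multivariable fit then recovers the generator's risk structure:

```r
fit <- fit_logistic(rows)
dplyr::filter(fit$coefficients, variable %in% c("photo", "care_group"))
#>   variable   level         aor ci_low ci_high p_value
#> 1 photo      Yes         0.830  0.423    1.63 0.587
#> 2 care_group Cardiac     1.22   0.473    3.15 0.680
#> 3 care_group ICU         2.41   1.30     4.47 0.00522
#> 4 care_group GeneralCare 1.19   0.587    2.41 0.631
```

The ICU effect (generator truth 2.05) is already significant at this size;
the photo interval is wide but covers the truth of 0.6. The methods vignette
(`vignettes/rar-surveillance.Rmd`) documents the model, the generator's
assumptions, and every numerical convention.

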