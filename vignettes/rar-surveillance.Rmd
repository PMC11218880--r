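---
title: "Methods: the retract-and-reorder near-miss measure and its analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the retract-and-reorder near-miss measure and its analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarwatch)
```

## The measure

Wrong-patient order entry (WPOE) is an order intended for one patient but
signed on another. Because harmful WPOE is rare, surveillance uses the
*retract-and-reorder* (RAR) near miss: an order retracted within 10 minutes
of placement and re-placed by the same provider, as the same order, on a
different patient within 10 minutes of the retraction. Near misses share the
causal pathway of the completed error, so interventions that lower the RAR
rate are expected to lower WPOE.

`detect_rar_events()` implements the measure with these conventions, chosen
where the verbal definition is silent and declared rather than inferred:

* **"Same order" means the same orderable** — identical `order_code`,
  ignoring dose or frequency. The orderable identifier is what retract-and-
  reorder queries key on in practice.
* **One actor.** The retraction and the reorder must come from the same
  provider; cross-provider pairs never match.
* **Window boundaries** are open at 0 s and closed at 600 s. "Within 10
  minutes" is read inclusively; zero-latency pairs are record artifacts, not
  human corrections.
* **Greedy one-to-one matching.** Retractions are processed in retraction-
  time order (ties by order id) and each claims the earliest compatible
  unconsumed reorder. This prevents one retraction from spawning several
  events, and makes the output invariant to input row order.
* **A retraction is a non-null `retract_time`.** Orders discontinued after
  execution are outside the data model; the feed must pre-filter to true
  retractions.

The test suite holds the detector to exact equivalence with a quadratic
brute-force oracle (enumerate all candidate pairs, apply the same greedy
rule) on hundreds of randomized dense logs, plus boundary, permutation and
window-monotonicity properties.

## Order sessions, exposure and covariates

The unit of analysis is the **order session**: all orders one provider signs
for one patient at one sign time. If one order of a session is on the wrong
patient, all of them are, so counting orders would inflate the rate and any
apparent intervention benefit. A session is a *RAR session* if any of its
orders is a detected (retracted) RAR order. Conventions:

* **Session key** is exact equality of `(patient_id, provider_id,
  sign_time)`. CPOE signing actions stamp one time on every order they sign;
  by the same convention `sign_time = placed_time` on each order.
* **Photo exposure is strict**: the patient's photo-acquisition time must be
  *before* the session sign time. A photo landing at exactly the sign time
  does not count.
* **Age** is fractional years at sign time (`days / 365.25`).
* **Shift**: Day is 07:00–19:00 local (the standard 12-hour hospital shift);
  the boundary instants 07:00:00 and 19:00:00 belong to Day and Night
  respectively.
* **Rollout periods** partition the study: Pre before the pilot start
  (2020-09-16), Pilot up to the full go-live (2021-03-11), Full afterwards;
  both instants open their own period.

## Statistical dialects

All of these are deliberate, documented choices; each has alternatives that
would change third-decimal results.

* **Odds ratios** are the 2×2 cross-product `(ad)/(bc)` with Wald 95%
  intervals `exp(log OR ± z·√(1/a+1/b+1/c+1/d))`; identical to a saturated
  one-predictor logistic fit (a tested identity). Zero cells raise an error;
  the Haldane–Anscombe +0.5 correction is available but never silent.
* **Race is one-vs-rest** — each named race level contrasted against all
  remaining sessions pooled — both in the univariable tables and as four
  indicator columns in the multivariable model. This is the encoding under
  which published per-level race odds ratios are reproducible, and it is
  identifiable in the multivariable model only because a small unlabeled
  remainder of sessions carries no named race; the synthetic cohort
  therefore includes an `Unknown` race level (~3%).
* **Ethnicity** enters as a Hispanic indicator with non-Hispanic (and the
  small unknown remainder) as reference. The pairwise Hispanic vs
  non-Hispanic table excludes unknowns.
* **Reference levels**: photo No, sex Female, ethnicity Non-Hispanic, care
  group Other, shift Night, provider Attending, insurance Private.
* **Small-cell exclusions** before the multivariable fit: sessions with
  unknown sex and with self-pay insurance are dropped and tallied.
* **Model selection** keeps covariates whose single-predictor
  likelihood-ratio P is below 0.1; a covariate carrying no signal (the
  complex-chronic-condition count in the emulated setting) drops out.
* Pearson chi-square and the two-sample proportion test use **no continuity
  correction**; the t-test is **Welch** from summary statistics; intervals
  are **Wald**, not profile; **no multiple-testing adjustment** anywhere.
* **Separation** policy: a constant outcome or a fit driven to the boundary
  raises an error by default (`on_separation = "error"`); pipelines may ask
  for a flagged, non-converged result instead. GLM convergence tolerance is
  1e-12 so the saturated-model identity holds to near machine precision.
* The **mixed-effects sensitivity fit** adds random intercepts for patient
  and provider via `lme4::glmer` (`nAGQ = 0`, the fast adaptive-free
  approximation — adequate for checking that clustering leaves the fixed
  effects essentially unchanged, which is its only role).

## The synthetic order-log generator

The generator emulates the study conditions of a large pediatric inpatient
system observed 2020-01-01 to 2022-07-01: ~85 000 patients, ~40 sessions per
patient (≈3.4 million sessions), a photo pilot on 2020-09-16 and system-wide
go-live on 2021-03-11, and a detected RAR rate in the low 30s per 100 000
sessions before rollout.

* **Demographic and context marginals** match the published session margins
  (male 52.6%, Black 45.6%, Hispanic 14.9%, public insurance 61.5%, ICU
  27.6%, day shift 73.3%, provider mix 42.9/7.5/18.9/25.8/4.9%).
* **Age** is gamma with mean 7.19 and SD 6.70 years at the study midpoint —
  the simplest positive distribution matching the published moments.
* **Wrong-patient risk** is logistic in the session covariates with true
  effects mirroring the published adjusted odds ratios (photo 0.60, cardiac
  2.12, ICU 2.05, general care 1.13, resident 1.37, day 0.881, Hispanic
  0.80, age 0.985/year). The intercept is calibrated analytically
  (`calibrate_intercept()`): under the rare-event approximation the marginal
  rate factorizes into the intercept times the mean covariate risk
  multiplier, computed in closed form from the category marginals and the
  gamma/Poisson moment-generating functions.
* **Catch-and-correct**: a wrong-patient signing is noticed and corrected
  within both windows with probability `p_catch = 0.8`. Only caught errors
  leave the RAR signature; the published literature gives the measure's
  positive predictive value, not a capture rate, so this is a modeling
  choice, exposed in the configuration. Latencies are Uniform(0, 600 s] —
  the simplest distribution consistent with the windows.
* **The wrong/intended patient pair** is drawn from the provider's same-day
  census (patients with a session for that provider on the same calendar
  day), because WPOE requires a plausibly open second chart. An empty census
  when a counterpart is needed is a hard generation error; realistic
  configurations keep roughly 10+ sessions per provider-day.
* **Photo acquisition** happens with probability 0.02 in the pilot window
  (one day-surgery unit) and 0.60 after go-live, at a uniform time in the
  respective window; patients younger than 6 months at the opportunity never
  receive a photo, and an opt-out is representable by lowering the capture
  probabilities (no claim of a realistic opt-out rate is made). These values
  were chosen analytically so that ~17% of sessions are photo-exposed.
* **Decoys**: benign no-reorder retractions (0.5% of orders) and
  same-patient retract-reorders (0.1%) exercise the detector's negative
  space. A ground-truth ledger of every injected signature is emitted
  separately and is never read by the detector.

What the generator does **not** emulate: realistic order catalogs, dosing or
pharmacy workflow (order codes are opaque tokens); seasonal or weekday
census structure; provider-level behavioral clustering beyond what the
random census induces; correlated demographics (covariates are drawn
independently, so the difference between univariable and adjusted effects is
smaller than in real data); and photo uptake that depends on demographics
(except when configured for the photo-predictor recovery tests). Passing
tests therefore demonstrate correctness of the *measure and machinery*, not
fidelity of any particular hospital's data-generating process.

## Problem sizes and determinism

Every random quantity flows from a single integer seed; identical
configuration and seed give byte-identical CSV output, which the pipeline
tests assert with checksums at fifty thousand sessions. The parameter-
recovery checks run twenty replicates of 200 000 sessions with the base
wrong-patient rate inflated to 200 per 100 000 (so each replicate carries
~400 events) over a one-year window with 40 providers, and require the
multivariable interval to cover the generator truth for the photo, cardiac,
ICU and resident coefficients in at least 18 of 20 replicates. The
acceptance script simulates one million sessions at the default (uninflated)
conditions to report the detected rate, and pools five 200 000-session
replicates by inverse variance for the recovered photo effect. These sizes
were chosen as the smallest at which the checked quantities are statistically
stable.

## Known limitations

* The published univariable odds ratios for ICU and general care appear
  transposed relative to their own counts; the package asserts nothing about
  those two rows and recovers the (internally consistent) adjusted values
  instead.
* Period-specific rates from the emulated setting (31.9/30.2/24.3 per
  100 000) are not reproducible from printed information alone — the
  per-period denominators are unpublished — so they are checked only as a
  simulated direction (post-go-live below pre-rollout) and an order of
  magnitude.
* The multivariable race encoding in the emulated analysis is not fully
  specified by its source; the one-vs-rest choice here is documented, not
  inferred.
* Session keys tolerate no timestamp jitter (exact-equality grouping). Feeds
  whose signing actions stamp slightly different times per order need
  pre-rounding.
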