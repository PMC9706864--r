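---
title: "Evaluating dynamic RRT-initiation regimes by cloning, censoring and weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating dynamic RRT-initiation regimes by cloning, censoring and weighting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icudtr)
```

## The estimand and the design

We compare threshold-based dynamic treatment regimes (DTRs) for
initiating renal replacement therapy (RRT) in ICU patients from the
moment they reach KDIGO acute-kidney-injury stage ≥ 2.  A regime is a
4-tuple of thresholds (x_pH and x_K, separately for patients who have
and have not met the oliguric stage-2 criterion); every regime also
initiates on the KDIGO stage-3 oliguria criterion.  The primary
estimand is the cumulative incidence of ICU death within 30 days of
inclusion under sustained compliance with a regime, treating live ICU
discharge as a competing event (not censoring); the secondary estimand
is the expected number of patients initiated on RRT.

The observational analogue of the target trial proceeds by *cloning*
(one copy of each patient per regime), *censoring* (a clone leaves its
arm on the first day observed care deviates from the regime's
prescription) and *weighting* (inverse probability of remaining
concordant, from a pooled logistic model of daily initiation), followed
by the IPC-weighted Aalen–Johansen estimator.

### Identification assumptions

* **No unmeasured confounding** of daily initiation decisions given the
  measured baseline and time-varying covariates.  The synthetic
  generator satisfies this by construction: its initiation model uses
  only covariates the weight model sees.
* **Positivity**: every prescribed action has non-zero daily
  probability under observed care.  Logistic observed-care models make
  this hold in principle; in small cohorts it fails *practically* —
  when few patients start RRT on their first prescribed day, whole
  outcome strata are carried by a handful of large weights.  This is
  visible in our own experiments: at roughly 700 analysed patients
  (≈ 40 observed initiations) the weighted estimator is materially
  biased for aggressive regimes, while at ≈ 2000 analysed patients it
  tracks the oracle within Monte Carlo tolerance.  The acceptance
  criteria therefore fix the *analysed* cohort size.
* **No interference** between patients: dialysis capacity is assumed
  never to be binding.

## Time conventions

Decisions and events live on a daily grid.  Follow-up day `f` denotes
the interval `[f, f+1)` from inclusion (day 0 = the day stage ≥ 2 is
first met); within a day the order is fixed: covariate update → KDIGO
staging → treatment decision → competing event draw.  Decisions are
taken at `f = 0..29`; an event during interval `f` appears in the
cumulative incidence at grid time `f + 1`, so 30-day mortality
accumulates exactly 30 daily hazards (a constant daily death
probability `p` gives `1 − (1−p)^30`).

KDIGO staging on daily means cannot resolve sub-day windows.  We use:
creatinine stage from the ratio to the first recorded ICU value (1.5×,
2×, 3× or absolute ≥ 4 mg/dl); urine-output stage 2 = one day below
0.5 ml/kg/h; stage 3 = two consecutive days below 0.3 ml/kg/h, i.e.
the "24 h below 0.3" criterion is confirmed 24–36 h after oliguria
onset.  Oliguric status for threshold selection is absorbing
(ever-met-by-decision-day).

### Same-day deviation and event

When a clone's first deviation day carries the patient's event, the
default keeps the event (`same_day = "event"`, configurable to
`"censor"`).  The within-day ordering argues for censor-first — the
deviating decision precedes the event — so the kept clone contributes
**no** inverse-probability factor for that day: it did not "pass" the
day's censoring decision, and charging it 1/p̂ would inject
occasional very-large-weight events.  The residual bias of the
convention is a product of two small same-day probabilities and is far
inside the acceptance tolerance; both conventions are unit-tested.

## The weight model

One pooled logistic model for daily initiation is fitted on the
original (un-cloned) person-days at risk and shared by all 81 regimes:
every regime's censoring mechanism is a deterministic function of the
single observed initiation process.  Defaults: main effects of age,
sex, weight, admission SOFA (baseline) and creatinine, potassium, pH,
urine output, SOFA, the persisting-oliguria indicator (time-varying),
plus a natural spline in follow-up time (4 df; per-day indicators
optional).  Probabilities are clipped to [1e−6, 1 − 1e−6] as a
positivity guard; weight truncation at a pooled percentile is available
but **off** by default, since the emulated analysis defines weights as
exact reciprocals.  Weight stabilisation by a numerator model is
likewise not default.  The diagnostic `weight_calibration()` checks the
identity E[W(t)·1{concordant through t}] = 1 — note this is *not* the
mean weight among at-risk clones, which exceeds 1 mechanically for
unstabilised weights.

Separation is detected by non-convergence/boundary/NA coefficients and
falls back to a small ridge penalty; large spline coefficients alone
are *not* treated as separation (an earlier heuristic that did so
corrupted the weights).

## Variance

The infinitesimal jackknife treats the weights as fixed and aggregates
influence at patient level (all of a patient's clones move together):
with hazards ĥₖ(f) = Dₖ(f)/Y(f), the case-weight derivative for
patient *i* is propagated through S and CIF exactly; the variance is
the sum of squared influences.  With unit weights and a single event
type this reproduces Greenwood's formula (unit-tested to 10%, observed
to agree to machine precision on censoring-free data).  The
patient-level bootstrap (default B = 500; resampling via multinomial
counts over per-patient component matrices) additionally captures
nothing of the weight-estimation step either — both condition on the
fitted weights, as the standard implementations do — but is used for the
risk-difference CI, where the two arms share patients and must be
resampled jointly.  Expected initiations use the same machinery with
initiation as the event and death/discharge competing, scaled to the
cohort size (bootstrap CI, B = 500 as in the emulated analysis).

## Cross-validation benchmark

Patients are split into k = 5 folds.  Per fold: select the
mortality-minimising regime on the training folds (weights refit on
training data), then estimate that regime's mortality on the held-out
fold with weights refit there (refitting is the default; reusing the
training model is an option; published descriptions of this benchmark
leave the choice open).  The benchmark is the patient-count-weighted average of held-out
estimates; folds in which estimation is infeasible (e.g. no observed
initiations) are flagged and excluded with a warning.  Selection on the
full data is overoptimistic, so on average the benchmark lies at or
above the full-data optimal estimate — the property the acceptance
suite checks across 100 replicates.

## The synthetic world

The emulated analysis is observational, so no true data-generating
mechanism is available; all generator coefficients are artifact
choices, frozen in `scenario_params()` and version-controlled.  The
generator simulates, per ICU day: mean-reverting covariate processes —
log-creatinine drifting toward a patient-specific severity attractor,
urine output falling and potassium rising with the creatinine ratio,
pH falling with severity and oliguria, SOFA tracking severity — with
physiological clamps (K 2–9 mEq/l, pH 6.6–7.7, urine ≥ 0, creatinine
≥ 0.2 mg/dl, SOFA 0–24); then a confounded logistic initiation
decision (drivers: potassium, pH, urine output, oliguria, SOFA);
then competing logistic death/discharge draws.  RRT is absorbing,
lowers the potassium attractor and raises the pH attractor
(treatment–confounder feedback), and its death-hazard effect is
+0.8 logits without an absolute indication and net −0.7 with one
(indication: persisting oliguria, K ≥ 7, oliguric pH < 7.2, or
pH < 7.0).  That sign structure makes aggressive potassium thresholds
harmful and an interior regime optimal, mirroring the qualitative
shape of the published regime comparison.

Calibration was performed once, before any acceptance outcome was
inspected, to the rates reported for real stage ≥ 2 ICU cohorts of
this kind:
~37% of admissions reach stage ≥ 2 within 30 days, and among them
30-day ICU mortality ≈ 12–13% and RRT initiation ≈ 8%.  The frozen
bands (mortality 10–15%, initiation 7–10% at n = 5000) are asserted in
the test suite.  Initiation is gated on inclusion (nobody starts RRT
before stage ≥ 2), which keeps the inclusion time treatment-free and
the oracle's conditioning regime-independent.

The **oracle** replays the same engine with initiation forced to the
regime's prescription and reports empirical incidence among eligible,
included patients with Monte Carlo standard errors.  Because generator
and oracle share one code path, a green counterfactual-recovery test
establishes that the *estimation pipeline* undoes the confounding the
generator injects — it does not establish realism of the world beyond
that confounding structure (no missing data by default, a minimal
covariate set, single-centre-like homogeneity, no RRT discontinuation,
no modality differences).

## What the defaults are and why

| parameter | default | why |
|---|---|---|
| threshold grids | pH {7.0, 7.1, 7.2}, K {6.0, 6.5, 7.0} mEq/l | the published 81-regime grid |
| potassium trigger | ≥ threshold | threshold attainment initiates (abstract wording); `<` strictly for pH |
| decision cadence | every 24 h, days 0–29 from inclusion | source protocol |
| follow-up horizon | 30 days | primary outcome window |
| grace window | 0 days | deviation = same-day discordance; g-day grace available |
| time effect in weight model | natural spline, 4 df | "main effects of … time" with unstated form |
| weight truncation | off (percentile 1.0) | weights defined as exact reciprocals; 0.995 available |
| variance | infinitesimal jackknife; bootstrap B = 500 | follows the emulated analysis |
| CV folds | 5, refit weights per fold | source's internal validation |

## Known limitations

* The IJ and bootstrap intervals condition on the fitted weights; at
  the default sizes their coverage is ≈ 95% empirically, but with very
  few initiations both under-cover because single large-weight clones
  dominate.
* Finite-sample positivity: regimes far from observed practice (low
  potassium thresholds) are supported by few concordant initiations;
  their estimates are noisy and, below ≈ 1000 analysed patients,
  biased toward the uncensored (healthier) clones.
* The eligibility module implements standard KDIGO thresholds on a
  daily grid; broader published operationalizations (e.g.
  back-calculated baseline creatinine) are not reproduced — we use
  the first recorded ICU value as baseline.
* Chronic-kidney-disease history is generated and flagged but is not
  an exclusion by default; apply `ckd_flag` as a filter for the
  stricter screen that also removes pre-existing CKD.
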