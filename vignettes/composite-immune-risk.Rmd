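---
title: "Composite immune risk scoring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite immune risk scoring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cirs)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, the numerical conventions, and the limits of
what the synthetic-cohort tests can demonstrate.

## The clinical problem

Immune reconstitution after hematopoietic stem cell transplantation (HSCT)
is highly variable between patients and strongly prognostic, but there is no
consensus summary of a patient's *multivariate* immune recovery. The package
operationalises one answer: embed every blood draw's 20-feature immune
profile into a common 2-D "phase space", find the region of that space
where presence during a given post-transplant window predicts death, and
compress membership in that region into a linear score — the Composite
Immune Risk Score (CIRS) — that a clinic can compute from one lab report.

## Data model

An immune profile is 20 features: six CBC counts (10⁹/L), two fractions of
nucleated cells, six flow-cytometry fractions of lymphocytes, and six
derived subset counts defined as lymphocyte count × subset fraction
(`derive_counts()` enforces this identity; validation rejects rows with
negative counts or fractions outside [0, 1] and warns when lymphocytes
exceed the white count, which can occur through rounding in real exports).
Day 1 is the first day post-transplant and all period intervals are closed:
"days 91–180" includes both endpoints. The four canonical screening periods
are days 1–90, 91–180, 181–270 and 271–360.

## Phase-space construction

Features are min–max rescaled to [0, 1] **on the full profile set being
analysed** and the map is then frozen; later profiles are clipped into
[0, 1]. Fitting the scaler before any split mirrors treating the rescaling
as a fixed units convention rather than a learned transformation; clipping
keeps out-of-range values from distorting the embedding input.

The 2-D embedding is Barnes–Hut t-SNE (via `Rtsne`) with perplexity 30,
1000 iterations, PCA initialisation and a fixed seed — these
hyperparameters are not dictated by the method, so the package fixes
reproducible defaults and exposes all of them (`embed_profiles()`).
Coordinates are centred per axis so grid geometry is reproducible. Exact
reproduction of any particular published phase-space geometry is not
attempted: t-SNE layouts are run-specific, which is precisely why the
downstream analysis is validated on held-out outcome data rather than on
the geometry itself. There is no out-of-sample projection; new data are
embedded by re-running on the union, or assessed through the score alone.

Feature gradients are summarised per feature by ordinary least squares
φ(x, y) = c + αx + βy + ε (`fit_axis_gradients()`), and cohort kinetics by
`average_trajectory()`: at time *t* the estimate pools all profiles in the
closed window [t − δt/2, t + δt/2], with δt = 30 d for 0 < t ≤ 90, 90 d for
90 < t ≤ 360, and 180 d beyond (wider windows where sampling is sparser);
the point estimate is the mean of means over 100 bootstrap resamples.
In-window rows are put in a canonical sort order before resampling so the
estimate is invariant to how the input table was sorted.
`variance_over_time()` reports, per evaluation day, the between-patient
variance of mean patient location — **population variance (divide by n) per
axis, summed over the two axes**; this convention is fixed and documented
because reasonable alternatives (sample variance) scale results by
n/(n − 1).

## Anchor discovery

A 121 × 121 grid spans the bounding box of the embedded coordinates. For a
period and each grid point, patients with at least one in-window profile
are labelled *near* (any profile within the nearness radius, boundary
inclusive) or *far*, and a univariate Cox proportional-hazards model (Efron
ties) of all-cause death on that label is fitted. Three conventions are the
package's own, because the method leaves them open; all are arguments of
`scan_anchor_points()`:

* **Nearness radius** — two grid steps, i.e. 2/120 of each axis span, with
  distances computed on span-normalised axes (the neighbourhood is
  elliptical in raw units). Coupling the radius to grid resolution keeps
  the neighbourhood scale-free; this is an artifact choice, stated
  prominently, not part of the published method.
* **Landmark convention** — the survival clock restarts at the period's end
  day (day 180 for days 91–180) and patients who died or were censored on
  or before the landmark are excluded, avoiding immortal-time bias.
* **Minimum group size** — a grid point is testable only when both near and
  far groups have ≥ 5 patients (p is set to 1 otherwise), preventing
  degenerate fits from dominating the anchor map.

Grid points with p < .01 are anchors; the p-value surface is deliberately
**uncorrected** for the 14,641 tests. The honest safeguard is structural:
anchors and the score are computed on the training split only (enforced by
a leakage guard that raises if a discovery stage receives non-training
outcomes), and prognostic value is demonstrated on held-out splits.
Candidate periods are screened by ten-fold cross-validation within the
training split (`cross_validate_period()`): anchors are re-discovered on
k − 1 folds, held-out patients are labelled, and the pooled held-out labels
are tested by one landmark Cox model.

## The risk score

`fit_score_model()` distils a signature into a linear score by
forward-and-backward stepwise logistic regression starting from the empty
model. The stepping criterion is AIC — the entry/exit rule is otherwise
open, and AIC stepping is deterministic given candidate order, whereas
p-value stepping is threshold-sensitive. Candidates default to all 20
profile features (window means per patient). The reported score is the
intercept-free linear predictor, for interface parity with the published
formula (which prints no intercept); its decision threshold is placed where
Youden's J against the training signature labels is maximal. Separation is
detected by a coefficient cap (|β| > 20) and handled by a ridge-stabilised
refit with a warning.

The published model is shipped verbatim (`cirs_published()`): eight
features, the printed coefficients, no intercept, and the 2.50 cutoff
applied **strictly** (a score of exactly 2.50 is low-risk). Fraction inputs
must be proportions (0.35, not 35); percentages are rejected rather than
silently rescaled, because a silently mis-scaled fraction changes the score
by an order of magnitude. Patient-level scoring over a period
(`score_patient_period()`) averages profile scores within the window and
then thresholds; the mean (rather than first- or any-profile) is the
documented default since the method does not specify one. Re-deriving the
published model's exact coefficients is a non-goal: that requires the
original restricted training data.

## Survival validation

`km_by_group()` (Kaplan–Meier, Greenwood variance, two-sided log-rank),
`cox_fit()` (landmark multivariate Cox, Efron ties, Wald 95% CIs),
`competing_risks()` (Aalen–Johansen cumulative incidence per cause;
Fine–Gray subdistribution hazard ratios via the IPCW-weighted Cox
formulation implemented in `cmprsk::crr`), and
`high_score_risk_factors()` (multivariable logistic odds ratios for
carrying a high score: severe acute GVHD in days 1–90, infection episodes
in days 1–90, age, plus configured covariates). Cumulative incidences and
overall survival partition unity at every time point — this conservation
identity is asserted in the test suite at 10⁻⁹.

## The synthetic cohort generator

`simulate_cohort()` generates the statistical structure the analysis
assumes, with exported ground truth:

* **Recovery kinetics.** Each lineage count follows
  mean(t) = plateau × (1 − exp(−t/rise)) with multiplicative log-normal
  noise. Defaults (see `default_lineage_params()`) make CD8⁺ T cells the
  fastest-rising lymphocytes (rise 60 d) and CD4⁺ T/B cells the slowest
  (150–180 d), with neutrophils recovering within weeks — the qualitative
  ordering seen in post-transplant practice. Plateaus are typical adult
  recovered counts in 10⁹/L.
* **Between-patient heterogeneity.** A per-patient, per-lineage log-normal
  plateau effect (sd 0.30) and a per-patient recovery-speed multiplier on
  all rise times (log-sd 0.50). Speed heterogeneity spreads patients along
  the trajectory at intermediate follow-up and lets them converge at
  plateau; note that the planted derailed subgroup (below) keeps late
  between-patient variance elevated, so variance-over-time on these cohorts
  rises after the first weeks but does not necessarily decline late the way
  a cohort without a persistent derailed subgroup would.
* **Derailment.** With probability `derail_fraction` (default 0.15) a
  patient is latently derailed: lymphoid plateaus are multiplied by
  exp(−1.5) ≈ 0.22 while myeloid lineages are untouched, placing their
  profiles in a distinct phase-space region, and their all-cause hazard is
  multiplied by exp(`derail_log_hr`) (default HR 3).
* **Survival.** Exponential event times at baseline hazard 3 × 10⁻⁴/day
  (≈ 10% first-year mortality for non-derailed patients, in the range of
  modern allo-HSCT cohorts), administrative censoring at day 1095, and
  death causes drawn from {relapse 0.40, infection-NRM 0.35, other-NRM
  0.25} independently of event time — the simplest competing-risks
  structure that supports Fine–Gray testing.
* **Visits.** Nominal profiling days 30, 60, 90, 135, 180, 270, 360 with
  Gaussian jitter (sd 3 d), truncated at the patient's event/censoring day.

Subset structure holds by construction (lymphocytes = NK + T + B + other;
CD4 + CD8 within T; Tregs within CD4; WBC is the sum of its components), so
every validation invariant is satisfied exactly. Identical configurations
give byte-identical tables.

**What passing tests do and do not show.** The generator plants exactly the
structure the pipeline looks for: a geometrically compact high-risk
subgroup with proportional-hazards mortality and independent cause
assignment. Recovery of the planted subgroup (sensitivity and specificity
≥ 0.8 at n = 2000) demonstrates that the pipeline's machinery — scaling,
embedding, grid scan, landmark Cox, signature assignment — is wired
correctly and calibrated under the null (permuted outcomes yield ≤ 5%
anchor rates). It does **not** demonstrate that real post-transplant
cohorts contain such a region, nor how the score generalises across
centers, stem-cell sources, or pediatric populations; those are empirical
questions requiring real cohorts. The generator also omits GVHD/infection
causal feedback, center batch effects, and any mechanistic immunology.

## Problem sizes and numerical choices

The test suite exercises the full pipeline at n = 700 patients with a
61 × 61 grid and the planted-recovery check at n = 2000 with the full
121 × 121 grid — sizes chosen so the complete suite documents the method's
behaviour in minutes on a laptop while the key check still runs at the
grid resolution the method specifies. Boundary conventions: windows and the
nearness radius are inclusive; δt at t = 90 is 30 d and at t = 360 is 90 d
(the interval rule is read literally); AIC ties in stepwise selection
resolve by candidate order; empty windows and untestable grid points are
reported, never imputed. Degenerate inputs (constant features, zero-extent
bounding boxes, single-class labels, no post-landmark deaths) raise errors
or warnings naming the culprit rather than returning silent results.

## Known limitations

* t-SNE geometry is seed- and implementation-specific; analyses should
  treat coordinates as an internal representation, not as transferable
  measurements.
* The nearness radius, landmark rule and minimum group size are package
  conventions where the method is silent; sensitivity to them should be
  checked on real data (all are exposed as arguments).
* The anchor scan tests 14,641 correlated hypotheses without correction by
  design; interpretation must rest on the held-out validation, never on the
  training-set p-value surface.
* The fitted score's Youden threshold is optimised against the training
  signature, not against survival; the published 2.50 cutoff applies only
  to the published coefficients.
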