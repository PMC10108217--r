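# cirs

Quantitative assessment of immune reconstitution after hematopoietic stem
cell transplantation (HSCT), built around the **Composite Immune Risk Score
(CIRS)** — an eight-feature linear score of routine blood immune profiles
during days 91–180 post-transplant that stratifies patients by risk of early
mortality.

## Who this is for

Transplant clinicians and biostatisticians who collect longitudinal immune
profiles (complete blood counts plus flow-cytometry lymphocyte subsets) and
want to (a) apply the fixed published score as a calculator, or (b) re-run
the full discovery pipeline — phase-space embedding, anchor-point scanning,
score distillation, and survival validation — on their own cohort or on
synthetic cohorts with planted ground truth.

## The method

An *immune profile* is one blood draw summarised by 20 features: six CBC
counts (WBC, neutrophils, eosinophils, basophils, monocytes, lymphocytes, in
10⁹/L), monocyte and lymphocyte fractions of nucleated cells, six
flow-cytometry fractions of lymphocytes (NK, T, CD4⁺ T, CD8⁺ T, Treg, B),
and the six derived subset counts (lymphocyte count × fraction).

1. **Phase space.** All profiles are min–max rescaled per feature to [0, 1]
   and embedded in 2-D with t-SNE. Feature gradients across the plane are
   summarised by least-squares fits φ(x, y) = c + αx + βy + ε, and cohort
   kinetics by bootstrap average trajectories over widening time windows
   (δt = 30 d up to day 90, 90 d up to day 360, 180 d after).
2. **Anchor discovery.** A 121 × 121 grid is overlaid on the phase space.
   For each grid point, patients with in-window profiles are labelled
   near/far (any profile within the nearness radius) and a univariate Cox
   model of post-landmark all-cause death is fitted on that label; grid
   points with p < .01 are *anchor points*. A patient near any anchor
   carries the *high-risk composite immune signature*. Candidate periods
   (days 1–90, 91–180, 181–270, 271–360) are screened by ten-fold
   cross-validation within the training split.
3. **Score distillation.** The signature is simplified by
   forward-and-backward stepwise logistic regression (AIC) into a linear
   score. The published days-91–180 model is

   ```
   CIRS = 0.7304·WBC − 0.4745·neutrophils − 16.7825·lymph%nucleated
        − 1.7612·lymphocytes − 7.9450·NK%lymph + 10.2955·T%lymph
        − 7.9703·CD4%lymph − 15.7887·B%lymph
   ```

   with counts in 10⁹/L, fractions as proportions, no intercept, and
   *high-risk* defined by CIRS > 2.50 (strict).
4. **Validation.** Kaplan–Meier stratification with log-rank tests,
   landmark multivariate Cox models (Efron ties, Wald CIs), Fine–Gray
   subdistribution hazards with Aalen–Johansen cumulative incidence for
   competing death causes, and logistic models for the risk factors of a
   high score.

A synthetic cohort generator (`simulate_cohort()`) produces visit-scheduled
multivariate immune recovery with a latent "derailed" subgroup occupying a
distinct feature-space region at elevated hazard, with competing death
causes and exported ground truth — so every pipeline stage can be tested
against planted truth.

## Worked example

Score one patient from their day-91–180 averages (the calculator mode):

```r
library(cirs)
x <- c(wbc = 6.2, neut = 4.1, lymph_frac_nuc = 0.22, lymph = 1.4,
       nk_frac = 0.18, t_frac = 0.62, cd4_frac = 0.20, b_frac = 0.02)
run_score_only(x)
#>       score risk
#> 1 -0.531524  low
```

The score is the plain weighted sum (here −0.53, far below the 2.50
cutoff), so this patient is low-risk.

Run the full discovery pipeline on a synthetic cohort (700 patients, a 61 ×
61 grid to match the smaller cohort):

```r
cfg <- run_config(sim = sim_config(n_patients = 700, seed = 3),
                  n_per_axis = 61, seed = 3)
run <- run_discovery(cfg)
run
#> <cirs_run>
#> <cirs_anchors> days 91-180: 20 anchor(s) among 676 testable of 3721 grid points
#>   radius 0.03333 (normalised), alpha 0.01, landmark day 180, 338 patients / 97 events
#> <cirs_model> (fitted) 3 features, threshold > -2.588
#> treg_count    t_count       mono
#>    45.6969    -4.0908    -1.2622
#> split verification (landmark Cox, high vs low):
#>       split       hr           p   n events n_high
#>    training 1.962744 0.001086474 338     97    152
#>  validation 1.340456 0.351859220 144     41     55
#>        test 1.217603 0.442569819 178     61     78
```

Anchors and the score model are fitted on the training split only (a
leakage guard raises if a discovery stage ever sees validation or test
outcomes); the table then reports the landmark hazard ratio of the fitted
high/low classification in each split. In this small example the training
association is strong (HR ≈ 2, p ≈ .001) and the validation/test hazard
ratios stay above 1 but are not individually significant — at this cohort
size that is the expected behaviour of an honestly held-out check.
`coef(run)`, `predict(run, new_profiles)`, and `summary(run)` give the
fitted coefficients, scores for new profile rows, and the screening table.

## Documentation

The methods vignette (`vignettes/composite-immune-risk.Rmd`) describes the
model assumptions, the synthetic-data generator and what it does and does
not emulate, all tunable parameters with their defaults, numerical
conventions, and known limitations.
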