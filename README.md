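# rjmcr — robust joint models for longitudinal biomarkers and competing risks

`rjmcr` is an R package for jointly modelling a longitudinal biomarker —
prototypically serum albumin (g/L) measured at dialysis follow-up visits —
and time-to-event outcomes with competing risks (death, transfer to
haemodialysis, kidney transplantation). It is aimed at biostatisticians
building dynamic prognostic models from trial or registry data in which the
biomarker series contains outliers and the terminal event competes with
other outcomes.

## The model

The longitudinal sub-model is a linear mixed model for subject *i*:

```
y_ij = m_i(t_ij) + e_ij,    m_i(t) = (β0 + b_i0) + (β_t + b_i1) t + x_i'β_x
```

Six distributional variants describe the random effects `b_i` and residuals
`e_ij`: the standard Gaussian model (`nor-nor`) and five robust variants in
which either or both are heavy-tailed Student-t, represented as Gamma scale
mixtures of normals. A subject-level mixing weight captures *b-outliers*
(whole trajectories off the population curve); observation-level weights
capture *e-outliers* (single aberrant measurements). `mod1` ties both to one
degrees-of-freedom parameter γ, `mod2` uses separate φ (subjects) and δ
(one weight per subject's residual vector, making residuals dependent), and
`mod3` gives every observation its own weight.

Each event cause *k* has a Weibull proportional-hazards cause-specific
hazard linked to the *current* model-implied biomarker value:

```
h_ik(t) = k_k λ_k t^(k_k − 1) exp(ζ_k' w_i + α_k m_i(t))
```

so `exp(−α_death)` is the hazard ratio per 1 g/L biomarker *decrease*. With
`competing_risks = FALSE` the competing events are censored; otherwise all
three causes are modelled and predictions use the cumulative-incidence
formulation. The 6 × 2 combinations give twelve model variants.

Estimation is fully Bayesian via a blocked Metropolis-within-Gibbs sampler
that exploits the conditional conjugacy of the scale mixture (see the
methods vignette in `vignettes/robust-joint-models.Rmd`). Model comparison
uses WAIC (smaller is better, differences ≥ 5 treated as important).
Landmark dynamic predictions, time-dependent AUC and Brier score with IPCW,
decile calibration against Kaplan–Meier, and baseline/time-varying Cox
comparators complete the pipeline, and a synthetic cohort generator makes
the whole workflow testable without access-restricted trial data.

## Worked example

```r
library(rjmcr)

sc     <- jm_scenario(n_subjects = 150, seed = 42)   # t-t-mod3-cr truth, HR 1.25/g/L
cohort <- generate_cohort(sc, 1)
split  <- split_train_test(cohort, ratio = 0.75, seed = 42)

spec <- jm_model_spec("t-t-mod3", competing_risks = TRUE,
  longitudinal_covariates = c("age_std", "sex"),
  survival_covariates = list(death = c("age_std", "sex"),
                             hd = "age_std", ktx = "age_std"),
  control = jm_control(chains = 2, warmup = 1000, iter = 1000, seed = 1))
fit <- jm_fit(spec, split$train)
fit
#> Joint model fit: t-t-mod3-cr
#>   2 chain(s) x 1000 retained iterations; 112 subjects
#>   max split R-hat: 1.273; min ESS: 18

waic(fit)$waic
#> [1] 4938.527

hr_table(fit)[1:3, ]
#>   cause                           term        hr      lo95     hi95
#> 1 death biomarker (per 1 g/L decrease) 1.2153065 1.1051951 1.329069
#> 2 death                        age_std 1.3534360 0.9820437 1.885030
#> 3 death                            sex 0.8519982 0.4735715 1.467130
```

The recovered hazard ratio of 1.22 (95% CrI 1.11–1.33) per 1 g/L albumin
decrease brackets the generating value 1.25; the df parameters mix slowest
(hence the R-hat warning at this chain length — lengthen chains when they
matter). Landmark prediction for a test-set subject event-free at one year:

```r
id <- split$test$survival$subject_id[split$test$survival$event_time > 1][1]
predict_death(fit, split$test, id, s = 1, u = c(0.5, 1), thin = 10)
#>   subject_id s   u   p_death       lo95      hi95
#> 1      S0011 1 0.5 0.1174664 0.06247369 0.2033581
#> 2      S0011 1 1.0 0.2204984 0.12149219 0.3753343
```

This subject's predicted probability of death within the next year, given
their albumin history to year 1 and accounting for the competing events, is
about 22%. The bedside arithmetic for a sustained albumin shift uses the
proportional-hazards risk transform:

```r
risk_transform_ph(0.09, hr_per_unit = 1.22, delta_units = 4)
#> [1] 0.1885477   # a 9% one-year risk at 38 g/L becomes ~19% at 34 g/L
```

Thin command-line wrappers over these functions (`simulate.R`,
`predict.R`, `evaluate.R`) live in `inst/cli/`.

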