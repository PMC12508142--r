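---
title: "Robust joint models for longitudinal albumin and competing risks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust joint models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Serum albumin is routinely measured at dialysis follow-up visits and declines
in the months before death, while staying roughly stable in patients who are
censored or experience a competing event (transfer to haemodialysis, kidney
transplantation). Two features of such data break the standard modelling
toolkit:

* **Outliers.** Albumin series contain both *b-outliers* — subjects whose
  whole trajectory sits persistently above or below the population curve —
  and *e-outliers* — single aberrant measurements (often brief downward
  spikes) inside an otherwise typical trajectory. A Gaussian mixed model
  absorbs both into inflated variance components.
* **Competing risks.** Death competes with transfer to haemodialysis and
  transplantation; ignoring the competing events overstates the probability
  of death.

`rjmcr` implements a family of joint models that addresses both, together
with the machinery needed to use them for individual dynamic prediction and
to evaluate that prediction honestly.

# The model family

## Longitudinal sub-model

For subject $i$ with measurements $y_{ij}$ at times $t_{ij}$ (years since
dialysis start),

$$y_{ij} = m_i(t_{ij}) + \varepsilon_{ij}, \qquad
  m_i(t) = (\beta_0 + b_{i0}) + (\beta_t + b_{i1})\,t + \mathbf{x}_i^\top\boldsymbol\beta_x ,$$

a linear time trend with random intercept and slope
$\mathbf{b}_i = (b_{i0}, b_{i1})^\top$ and optional baseline covariates.
Residual diagnostics of albumin series support a linear trend; splines and
nonlinear trajectories are deliberately out of scope.

The six outlier structures differ only in the distributions of
$\mathbf{b}_i$ and $\boldsymbol\varepsilon_i$, written throughout as Gamma
scale mixtures of Gaussians: a Student-$t_\nu$ variable is a normal divided
by $\sqrt{w}$ with $w \sim \Gamma(\nu/2, \nu/2)$, and the posterior of
$1/w$ is an interpretable outlier-inflation factor.

| variant | random effects | residuals |
|---|---|---|
| `nor-nor` | normal | normal |
| `t-t-mod1` | joint multivariate $t_\gamma$ with the residuals (one shared weight per subject) | |
| `t-t-mod2` | $t_\phi$ (subject weight) | multivariate $t_\delta$: one weight shared by all of a subject's residuals, making them dependent |
| `nor-t-mod2` | normal | as mod2 |
| `t-t-mod3` | $t_\phi$ | independent $t_\delta$ per observation |
| `nor-t-mod3` | normal | as mod3 |

mod2's single subject-level residual weight is exactly what induces
dependence between a subject's residuals; mod3 removes that dependence by
giving every observation its own weight, which is also what lets it flag
individual e-outliers.

Degrees of freedom are supported on $(2, 100]$: below 2 the variance does
not exist, and above 100 the $t$ is numerically indistinguishable from the
normal (the package's normal-limit tests verify agreement to $10^{-4}$ at
$\nu = 10^6$). The prior is a shifted Gamma, $\nu = 2 + \eta$,
$\eta \sim \Gamma(2, 0.2)$, which keeps mass over the genuinely
heavy-tailed region without excluding near-normal fits. All priors are
user-configurable (`jm_priors()`).

## Survival sub-model

Each cause $k$ (death; transfer to HD; transplantation) gets a Weibull
proportional-hazards cause-specific hazard with a *current-value* link:

$$h_{ik}(t) = k_k \lambda_k t^{k_k - 1}
  \exp\{\boldsymbol\zeta_k^\top \mathbf{w}_i + \alpha_k\, m_i(t)\}.$$

The cumulative baseline hazard is $H_{0k}(t) = \lambda_k t^{k_k}$ — the
parameterization is stated once here and used consistently, since the two
common Weibull conventions differ by a factor. Hazard ratios for the
biomarker are reported per 1 g/L **decrease**, i.e. $\exp(-\alpha_k)$,
matching the clinical convention for albumin decline. The association for
the competing causes is estimated, not pinned to zero.

In single-cause mode the competing event codes are treated as censoring; in
competing-risks mode a censored subject contributes $-\sum_k H_k(T)$ and a
subject with event $k$ adds $\log h_k(T)$. Because $m_i(t)$ is time-varying
there is no closed form for $H_k$; a fixed 15-point Gauss–Legendre rule per
integral is used, the convention in joint-model software. For integer
Weibull shapes the rule is essentially exact ($<10^{-8}$); for fractional
shapes the $t^{k-1}$ kink at zero limits accuracy to roughly $10^{-4}$
relative, which is far below the posterior uncertainty at these sample
sizes. When $\alpha_k = 0$ the closed Weibull form is used directly.

Inside the hazard the biomarker is centred at the training mean
(`m_ref`, stored in the fit): $\alpha_k (m_i(t) - \bar m)$. This is a pure
reparameterization of $\lambda_k$ that leaves hazard ratios and predictions
unchanged but removes the severe posterior correlation between
$\log\lambda_k$ and $\alpha_k$ that arises when $m \approx 38$ g/L is far
from zero.

# Estimation

The posterior is explored by a blocked Metropolis-within-Gibbs sampler
(`jm_fit()`), designed around the conditional conjugacy of the scale
mixture:

* mixing weights $w$, the random-effects covariance $\Sigma$
  (inverse-Wishart) and the residual variance $\sigma^2$ (inverse-Gamma)
  are exact Gibbs draws;
* the fixed effects $\boldsymbol\beta$ and each subject's $\mathbf{b}_i$
  are proposed from their *exact longitudinal-conditional Gaussians* and
  accepted with the survival likelihood ratio — an independence Metropolis
  step whose acceptance rate is high (typically 0.8–0.95) because the
  longitudinal data dominate these conditionals;
* the Weibull/association block of each cause and the degrees-of-freedom
  parameters use adaptive random-walk Metropolis (empirical-covariance
  proposals, Robbins–Monro scale tuning toward 0.25 acceptance), frozen
  after warmup;
* random effects are updated subject-wise but fully vectorized, so a
  236-subject competing-risks fit with 2 chains of 500 + 500 iterations
  takes a few seconds.

A gradient-based (HMC/NUTS) sampler was considered and rejected: the
conditional structure above gives exact draws for most of the parameter
space, mixes well for this model family, and avoids the cost of
re-evaluating gradient quadratures at every leapfrog step. Parameter
recovery on simulated cohorts (see below) is the acceptance gate for this
choice.

Defaults are 2 chains × 500 warmup + 500 retained iterations with a
mandatory seed; fits are bit-reproducible given the seed. Split R-hat and
effective sample sizes are reported for every scalar parameter, with a
warning above R-hat 1.01. The slowest-mixing parameters are typically
$\log\lambda$ and the df parameters; chains should be lengthened when their
R-hat matters for the question at hand.

Initialization uses least-squares estimates for the longitudinal block with
small jitter, exponential-rate starts for the hazards, and zero association
— close enough to the bulk of the posterior that warmup adaptation is spent
tuning, not travelling.

## WAIC

`waic()` computes $-2(\mathrm{lppd} - p_\mathrm{WAIC})$ from the pointwise
draw-by-subject log-likelihood. The pointwise unit is the **subject** — the
product of that subject's longitudinal and survival contributions,
conditional on the subject's sampled random effects and mixing weights.
Subjects are the exchangeable unit of a joint model; note that WAIC
magnitudes (though rarely rankings) depend on this choice, so cross-package
comparisons of absolute WAIC values are not meaningful. Differences of at
least 5 points are treated as important.

# Dynamic prediction

For a new subject, event-free at landmark $s$ with measurements up to $s$,
`predict_death()` and `predict_biomarker()` average over posterior draws;
for each draw the subject's random effects are sampled from
$p(\mathbf{b}, w \mid Y(s), T > s, \theta)$ by a short warm-started
Metropolis-within-Gibbs chain (default 25–50 steps): weights are
Gibbs-exact, $\mathbf{b}$ is proposed from the longitudinal conditional and
accepted with the survival-to-$s$ ratio. A brute-force 2-D grid integration
oracle validates this chain in the test suite.

Conditional death probabilities are

* without competing risks: $1 - S(s+u \mid \mathbf{b})/S(s \mid \mathbf{b})$;
* with competing risks:
  $\int_s^{s+u} h_\text{death}(t)\, S_\text{overall}(t)/S_\text{overall}(s)\,dt$,

the latter never exceeding the former — ignoring competing events
systematically overestimates death risk, and the package's tests assert
this dominance analytically. Landmark defaults follow the usual evaluation
design: $s \in \{1, 1.5, 2\}$ years, $u \in \{0.5, 1\}$, extendable on a
6-month grid to 5 years. Subjects whose last measurement precedes $s$ by
more than a year are still predicted, with a staleness warning.

`risk_transform_ph()` exposes the bedside arithmetic: a fixed-horizon risk
$r$ under a sustained biomarker shift of $d$ units maps to
$1 - (1-r)^{\mathrm{HR}^d}$.

# Evaluation

`timedep_auc()` and `brier_score()` are cumulative/dynamic IPCW estimators:
cases are deaths in $(s, s+u]$ weighted by $1/\hat G(T^-)$, controls are
survivors past $s+u$ weighted by $1/\hat G(s+u)$, with $\hat G$ the
Kaplan–Meier estimator of the censoring distribution on the landmark risk
set. Subjects with a competing event inside the window are **controls** for
death discrimination by default (the cumulative-incidence definition of a
case); a `competing = "censor"` flag implements the alternative, since
published analyses are not always explicit about this choice.
`calibration_deciles()` groups subjects by sample quantiles of predicted
risk (ties collapsed with a warning) and compares mean predicted risk with
$1 - S_{KM}(s+u)$ within each group, competing events censored.

The Cox comparators are the two standard benchmarks: baseline-albumin Cox
("Cox-1") and the extended Cox with albumin as a time-varying covariate via
last-value-carried-forward intervals ("Cox-2"), both with Breslow ties and
the Breslow baseline (the tie convention is fixed so that coefficient tests
are exact). Cox-2's risk predictions freeze the last albumin value at the
landmark over the whole horizon — precisely the LVCF limitation the joint
model is meant to overcome. Partial-likelihood maximization is delegated to
`survival::coxph()`; a brute-force one-dimensional maximization oracle
checks it in the tests. Constant (flat-likelihood) covariates get a zero
coefficient with a warning rather than an error.

# The synthetic cohort generator

`jm_scenario()`/`generate_cohort()` replace the access-restricted trial
data as the test bed. The default scenario emulates the *structure* of a
peritoneal-dialysis trial cohort:

* 236 subjects per cohort; 200 replicate cohorts (47,200 trajectories) at
  the reference simulation scale; 140 independent test patients via
  `generate_test_patients()`;
* visits every 0.25 years to year 3, then every 0.5 years to year 8, with
  a baseline visit at $t = 0$ so every subject has at least one
  measurement;
* albumin around 38 g/L, population slope −0.5 g/L/year, random-effect
  SDs 3 g/L (intercept) and 0.5 g/L/yr (slope), residual SD 2.5 g/L —
  values chosen once as clinically plausible magnitudes;
* a death association calibrated to a hazard ratio of 1.25 per 1 g/L
  decrease (inside the reported 1.22–1.28 band), no albumin association
  for the competing causes;
* one standardized continuous covariate (age) and one binary (sex);
* independent exponential dropout (0.05/yr) and administrative censoring
  at 8 years.

Event times are drawn by inverting the total cumulative hazard along the
subject's own trajectory (bisection on $S(t) = U$, tolerance $10^{-9}$),
with the cause drawn proportionally to the cause-specific hazards at the
event time; a Kaplan–Meier comparison against the closed-form Weibull
survival is part of the tests. Contamination is explicit and separate from
the model's own $t$ tails: a configurable fraction of subjects has its
random effects scaled (b-outliers), and a configurable fraction of
residuals is scaled (e-outliers); both default to zero.

What the generator does **not** emulate: the joint distribution of real
baseline covariates, comorbidity scores, informative dropout, assay
artefacts, or visit-time irregularity. Passing tests therefore demonstrate
correctness of the estimation and prediction machinery under the stated
generating mechanisms — not clinical validity on real dialysis data, which
requires external cohorts.

# Test and simulation scale

The test suite runs everything at sizes chosen to keep the full suite in a
few minutes while leaving the assertions meaningful: parameter recovery
uses 10 replicate cohorts of 236 subjects with 2 chains × 500 + 500
iterations (mean recovered death HR within [1.15, 1.35] of the true 1.25;
at least 15 of 20 single-parameter 95% intervals covering truth); the WAIC
ordering check uses 10 cohorts of 200 subjects with 5% e-contamination at
8 residual SDs (the observation-level $t$ model must beat the standard
joint model by ≥ 5 points in a majority); oracle comparisons (closed-form
Weibull quantities, brute-force AUC/Brier/Cox, $t$ normal limits) are
exact-tolerance and instantaneous.

# Known limitations and open choices

* A subject who switches modality and dies shortly after cannot be
  represented: the data model has a single terminal event per subject, so
  any "count deaths within three months of switch as dialysis deaths"
  recoding must happen upstream during data preparation.
* No left truncation, interval censoring, multiple biomarkers, skew
  distributions, spline baselines, or Fine–Gray sub-distribution hazards.
* Only the current-value association is implemented; slope and cumulative
  links are future work.
* The df upper bound of 100 is a numerical-equivalence cutoff, not a
  substantive prior belief; fits pinned at the bound simply indicate
  effectively normal tails.
* WAIC values are conditional on sampled effects and weights; model
  rankings are stable under this choice but absolute values are not
  comparable across different pointwise definitions.
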