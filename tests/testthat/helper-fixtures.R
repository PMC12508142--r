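# Shared fixtures: small scenarios and cached model fits so that several
# test files can reuse one MCMC run.

small_scenario <- function(variant = "nor-nor", competing_risks = FALSE,
                           n = 100, seed = 7, ...) {
  jm_scenario(n_subjects = n, variant = variant,
              competing_risks = competing_risks, seed = seed, ...)
}

toy_dataset <- function() {
  long <- data.frame(
    subject_id = c("A", "A", "B", "B", "B"),
    time = c(0, 1, 0, 0.5, 1.5),
    value = c(38, 37, 41, 40, 39))
  surv <- data.frame(
    subject_id = c("A", "B"), event_time = c(2, 3),
    event_code = c(1L, 0L), age_std = c(0.5, -0.2))
  jm_data(long, surv)
}

.fit_cache <- new.env(parent = emptyenv())

cached_fit <- function(key) {
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  f <- switch(key,
    # nor-nor, single cause, moderate size: the workhorse for prediction
    nor = {
      d <- generate_cohort(small_scenario("nor-nor", FALSE, n = 100, seed = 7), 1)
      spec <- jm_model_spec("nor-nor", FALSE,
        longitudinal_covariates = c("age_std", "sex"),
        survival_covariates = c("age_std", "sex"),
        control = jm_control(chains = 2, warmup = 250, iter = 250, seed = 21))
      suppressWarnings(jm_fit(spec, d))
    },
    cr = {
      d <- generate_cohort(small_scenario("t-t-mod3", TRUE, n = 100, seed = 9), 1)
      spec <- jm_model_spec("t-t-mod3", TRUE,
        longitudinal_covariates = c("age_std", "sex"),
        survival_covariates = list(death = c("age_std", "sex"),
                                   hd = "age_std", ktx = "age_std"),
        control = jm_control(chains = 2, warmup = 250, iter = 250, seed = 22))
      suppressWarnings(jm_fit(spec, d))
    },
    stop("unknown fit key"))
  .fit_cache[[key]] <- f
  f
}

cached_data <- function(key) cached_fit(key)$model_data

# default true longitudinal parameters of the synthetic scenario
scn_truth <- function(sc) sc$long_params
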