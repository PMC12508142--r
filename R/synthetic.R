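#' Define a synthetic dialysis-cohort simulation scenario
#'
#' The default scenario emulates the structure of a peritoneal-dialysis
#' trial cohort: 236 subjects per cohort, 3-monthly biomarker visits during
#' the first 3 years and 6-monthly visits thereafter up to 8 years of
#' administrative follow-up, serum-albumin trajectories around 38 g/L with
#' a slow decline, a current-value association with death calibrated to a
#' hazard ratio of 1.25 per 1 g/L decrease, and two competing events
#' (transfer to haemodialysis, transplantation) with no biomarker
#' association. 200 cohorts of 236 trajectories replicate the scale of the
#' reference simulation design (47,200 trajectories).
#'
#' @param n_subjects subjects per cohort (default 236).
#' @param n_cohorts number of replicate cohorts the scenario describes
#'   (default 200).
#' @param visit_times biomarker visit schedule in years, strictly
#'   increasing.
#' @param variant generating longitudinal outlier structure.
#' @param competing_risks generate the two competing events as well.
#' @param long_params true longitudinal parameters: \code{beta} (named:
#'   intercept, time, then covariates), \code{Sigma}, \code{sigma}, and df
#'   fields as required by the variant.
#' @param causes named list of true [cause_params()] (only \code{death}
#'   is used when \code{competing_risks = FALSE}).
#' @param contamination list: \code{b_frac}/\code{b_scale} scale the random
#'   effects of a random subject fraction (persistent trajectory shifts,
#'   b-outliers); \code{e_frac}/\code{e_scale} scale a random fraction of
#'   residuals (single aberrant measurements, e-outliers).
#' @param admin_censor administrative censoring time, years.
#' @param dropout_rate independent exponential dropout rate (1/years).
#' @param seed base seed; cohort c uses a seed derived from it.
#' @return object of class \code{jm_scenario}.
#' @export
jm_scenario <- function(
    n_subjects = 236, n_cohorts = 200,
    visit_times = c(seq(0, 3, by = 0.25), seq(3.5, 8, by = 0.5)),
    variant = "t-t-mod3", competing_risks = TRUE,
    long_params = list(
      beta = c("(Intercept)" = 38, time = -0.5, age_std = -0.5, sex = 0.3),
      Sigma = matrix(c(9, -0.3, -0.3, 0.25), 2, 2),
      sigma = 2.5, phi = 8, delta = 8, gamma_df = 8),
    causes = list(
      death = cause_params(1.3, 0.12, c(age_std = 0.4, sex = 0),
                           alpha = -log(1.25), m_ref = 38),
      hd  = cause_params(1.0, 0.10, c(age_std = 0.1, sex = 0), 0, 38),
      ktx = cause_params(1.0, 0.07, c(age_std = -0.3, sex = 0), 0, 38)),
    contamination = list(b_frac = 0, b_scale = 4, e_frac = 0, e_scale = 8),
    admin_censor = 8, dropout_rate = 0.05, seed = 1L) {
  stopifnot(all(diff(visit_times) > 0), n_subjects >= 0,
            contamination$b_frac >= 0, contamination$b_frac <= 1,
            contamination$e_frac >= 0, contamination$e_frac <= 1,
            long_params$sigma > 0, admin_censor > 0, dropout_rate >= 0)
  variant <- match.arg(variant, JM_VARIANTS)
  structure(list(n_subjects = n_subjects, n_cohorts = n_cohorts,
                 visit_times = visit_times, variant = variant,
                 competing_risks = competing_risks,
                 long_params = long_params, causes = causes,
                 contamination = contamination,
                 admin_censor = admin_censor, dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "jm_scenario")
}

#' Simulate one event time and cause by inverting the cumulative hazard
#'
#' Draws the overall event time T by solving H_total(T) = -log(U) with
#' bisection (U uniform), where H_total sums the cause-specific cumulative
#' hazards along the subject's biomarker trajectory; the cause is then
#' drawn with probability h_k(T) / sum_k h_k(T). Times beyond \code{t_max}
#' are administratively censored (cause 0).
#'
#' @param effects list with \code{b} (subject random effects).
#' @param long_covariates,surv_covariates covariate vectors (the latter a
#'   list per cause).
#' @param causes named list of [cause_params()].
#' @param long_params true longitudinal parameters.
#' @param t_max administrative horizon, years.
#' @param u optional uniform variate (for reproducible single draws);
#'   defaults to \code{runif(1)}.
#' @param u_cause optional uniform variate for the cause draw.
#' @return list with \code{time} and \code{cause} (0 = censored at t_max;
#'   otherwise the index into \code{causes}).
#' @export
simulate_event_time <- function(effects, long_covariates = numeric(),
                                surv_covariates = list(numeric()),
                                causes, long_params, t_max = 8,
                                u = NULL, u_cause = NULL) {
  if (is.null(u)) u <- stats::runif(1)
  E <- -log(u)
  covs <- function(k) {
    if (length(surv_covariates) >= k) surv_covariates[[k]]
    else surv_covariates[[1]]
  }
  H_tot <- function(t) {
    sum(vapply(seq_along(causes), function(k)
      cumulative_hazard(causes[[k]], t, covs(k), long_params, effects,
                        long_covariates), numeric(1)))
  }
  if (H_tot(t_max) < E) return(list(time = t_max, cause = 0L))
  Tt <- stats::uniroot(function(t) H_tot(t) - E, c(1e-9, t_max),
                       tol = 1e-9)$root
  m_T <- trajectory_value(long_params, effects, long_covariates, Tt)
  h <- vapply(seq_along(causes), function(k) {
    cp <- causes[[k]]
    weib_hazard(cp, Tt, covs(k), m_T)
  }, numeric(1))
  if (is.null(u_cause)) u_cause <- stats::runif(1)
  cause <- findInterval(u_cause, cumsum(h / sum(h))) + 1L
  list(time = Tt, cause = min(cause, length(causes)))
}

sim_covariates <- function(n) {
  data.frame(age_std = stats::rnorm(n), sex = stats::rbinom(n, 1, 0.5))
}

#' Generate one synthetic cohort
#'
#' Simulates baseline covariates, random effects and residuals under the
#' scenario's outlier structure, event times from the cause-specific
#' hazards (current-value link), independent exponential dropout and
#' administrative censoring, and biomarker visits truncated at the observed
#' follow-up time. Deterministic given the scenario seed and cohort index.
#'
#' @param scenario a [jm_scenario()].
#' @param cohort cohort index (1 .. n_cohorts), varied to obtain replicate
#'   cohorts from one scenario.
#' @param id_prefix prefix for subject ids.
#' @return a validated \code{jm_data}; the true subject effects are
#'   attached as attribute \code{"true_effects"}.
#' @export
generate_cohort <- function(scenario, cohort = 1, id_prefix = "S") {
  stopifnot(inherits(scenario, "jm_scenario"))
  set.seed((scenario$seed + 7919L * as.integer(cohort)) %% 2147483647L)
  n <- scenario$n_subjects
  lp <- scenario$long_params
  st <- variant_structure(scenario$variant)
  causes <- if (scenario$competing_risks) scenario$causes else
    scenario$causes["death"]
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  if (n == 0) {
    return(jm_data(
      data.frame(subject_id = character(), time = numeric(),
                 value = numeric()),
      data.frame(subject_id = character(), event_time = numeric(),
                 event_code = integer(), age_std = numeric(),
                 sex = numeric())))
  }
  cov <- sim_covariates(n)
  cov_names <- names(lp$beta)[-(1:2)]
  Xc <- as.matrix(cov[, cov_names, drop = FALSE])

  # random effects under the scenario's outlier structure
  w_b <- if (st$shared) stats::rgamma(n, lp$gamma_df / 2, lp$gamma_df / 2)
    else if (st$b_t) stats::rgamma(n, lp$phi / 2, lp$phi / 2)
    else rep(1, n)
  L <- chol(lp$Sigma)
  b <- (matrix(stats::rnorm(2 * n), n, 2) %*% L) / sqrt(w_b)
  ct <- scenario$contamination
  n_bout <- round(ct$b_frac * n)
  b_out <- sample(n, n_bout)
  if (n_bout) b[b_out, ] <- b[b_out, ] * ct$b_scale

  long <- vector("list", n)
  surv <- data.frame(subject_id = ids, event_time = NA_real_,
                     event_code = NA_integer_, cov)
  for (i in seq_len(n)) {
    eff <- list(b = b[i, ])
    ev <- simulate_event_time(eff, Xc[i, ],
                              lapply(causes, function(cp)
                                Xc[i, names(cp$zeta), drop = TRUE]),
                              causes, lp, t_max = scenario$admin_censor)
    drop_t <- if (scenario$dropout_rate > 0)
      stats::rexp(1, scenario$dropout_rate) else Inf
    T_obs <- min(ev$time, drop_t)
    code <- if (drop_t < ev$time || ev$cause == 0L) 0L else {
      if (scenario$competing_risks) c(1L, 2L, 3L)[ev$cause] else 1L
    }
    vt <- scenario$visit_times[scenario$visit_times < T_obs]
    if (!length(vt))
      stop("subject ", ids[i], " has no visit before its event time ",
           signif(T_obs, 3), "; include time 0 in the visit schedule")
    m <- trajectory_value(lp, eff, Xc[i, ], vt)
    nv <- length(vt)
    w_e <- if (st$shared) rep(w_b[i], nv)
      else if (!st$e_t) rep(1, nv)
      else if (st$e_level == "obs")
        stats::rgamma(nv, lp$delta / 2, lp$delta / 2)
      else rep(stats::rgamma(1, lp$delta / 2, lp$delta / 2), nv)
    e <- stats::rnorm(nv, 0, lp$sigma / sqrt(w_e))
    n_eout <- round(ct$e_frac * nv)
    if (n_eout) {
      j <- sample(nv, n_eout)
      e[j] <- e[j] * ct$e_scale
    }
    long[[i]] <- data.frame(subject_id = ids[i], time = vt, value = m + e)
    surv$event_time[i] <- T_obs
    surv$event_code[i] <- code
  }
  out <- jm_data(do.call(rbind, long), surv)
  attr(out, "true_effects") <- list(b = b, w_b = w_b, b_outliers = ids[b_out])
  out
}

#' Generate independent test patients for prediction evaluation
#'
#' Draws subjects from the same scenario with a disjoint random stream and
#' distinct ids, never to be used for fitting (default 140, the size of
#' the reference prediction-validation set).
#'
#' @param scenario a [jm_scenario()].
#' @param n number of test subjects.
#' @return a \code{jm_data} with ids prefixed \code{"T"}.
#' @export
generate_test_patients <- function(scenario, n = 140) {
  sc <- scenario
  sc$n_subjects <- n
  sc$seed <- (scenario$seed + 104729L) %% 2147483647L
  generate_cohort(sc, cohort = scenario$n_cohorts + 1L, id_prefix = "T")
}
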