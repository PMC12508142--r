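pars <- function(beta = c(38, -1), Sigma = diag(c(4, 0.25)), sigma = 2,
                 ...) {
  c(list(beta = beta, Sigma = Sigma, sigma = sigma), list(...))
}

test_that("trajectory is the linear mixed mean", {
  p0 <- pars(beta = c(0, 0))
  expect_equal(trajectory_value(p0, list(b = c(0, 0)), t = c(0, 1, 7)),
               c(0, 0, 0))
  # hand arithmetic: 38 + 2 + (-1 + 0.5)*2 = 39
  expect_equal(
    trajectory_value(pars(beta = c(38, -1)), list(b = c(2, 0.5)), t = 2),
    39.0)
  # at t = 0 the slope is irrelevant
  p <- pars(beta = c(40, -3))
  expect_equal(trajectory_value(p, list(b = c(1.5, 99)), t = 0), 41.5)
  expect_error(trajectory_value(p, covariates = c(1, 2), t = 1),
               "does not match")
  expect_error(trajectory_value(p, t = -1), ">= 0")
})

test_that("conditional log-likelihood matches the Gaussian form", {
  p <- pars(sigma = 1.7)
  # single observation exactly at the mean
  expect_equal(
    longitudinal_loglik("nor-nor", y = 38, times = 0, p),
    -0.5 * log(2 * pi * 1.7^2))
  # weights scale the residual variance
  e <- list(b = c(0, 0), w_b = 1, w_e = 4)
  expect_equal(
    longitudinal_loglik("t-t-mod2", y = 39, times = 0,
                        pars(sigma = 2, delta = 5), e),
    dnorm(1, 0, 2 / sqrt(4), log = TRUE))
})

test_that("t variants approach the normal limit as df grows", {
  set.seed(1)
  y <- rnorm(8, 37, 2); tt <- seq(0, 3.5, by = 0.5)
  p_nor <- pars()
  ll_nor <- longitudinal_loglik("nor-nor", y, tt, p_nor,
                                marginalize_weights = TRUE)
  for (v in c("t-t-mod2", "t-t-mod3")) {
    p_t <- pars(phi = 1e6, delta = 1e6)
    expect_equal(
      longitudinal_loglik(v, y, tt, p_t, marginalize_weights = TRUE),
      ll_nor, tolerance = 1e-4)
  }
  p_m1 <- pars(gamma_df = 1e6)
  expect_equal(
    longitudinal_loglik("t-t-mod1", y, tt, p_m1, marginalize_weights = TRUE,
                        include_ranef = TRUE),
    longitudinal_loglik("nor-nor", y, tt, p_nor, include_ranef = TRUE),
    tolerance = 1e-4)
})

test_that("marginal t density equals quadrature over the Gamma mixing law", {
  # single standardized residual, mod3: univariate Student-t
  p <- pars(sigma = 2, delta = 6)
  r <- 1.3
  ll <- longitudinal_loglik("t-t-mod3", y = 38 + r, times = 0, p,
                            marginalize_weights = TRUE)
  num <- integrate(function(w)
    dnorm(r, 0, 2 / sqrt(w)) * dgamma(w, 3, 3), 0, Inf,
    rel.tol = 1e-10)$value
  expect_equal(ll, log(num), tolerance = 1e-7)
  expect_equal(ll, dt(r / 2, df = 6, log = TRUE) - log(2), tolerance = 1e-12)

  # mod2: a subject's residual vector is jointly multivariate t
  p <- pars(beta = c(38, 0), sigma = 2, delta = 6)  # flat mean trajectory
  y <- c(39, 36.5, 38.2); tt <- c(0, 1, 2)
  ll2 <- longitudinal_loglik("t-t-mod2", y, tt, p, marginalize_weights = TRUE)
  r2 <- y - 38
  num2 <- integrate(function(w) {
    sapply(w, function(wi)
      prod(dnorm(r2, 0, 2 / sqrt(wi))) * dgamma(wi, 3, 3))
  }, 0, Inf, rel.tol = 1e-10)$value
  expect_equal(ll2, log(num2), tolerance = 1e-7)
})

test_that("mod1 equals mod2 with tied weights; scale mixture matches t law", {
  y <- c(37, 39, 40); tt <- c(0, 0.5, 1.2)
  e1 <- list(b = c(1, -0.3), w_b = 1.7, w_e = 1.7)
  p1 <- pars(gamma_df = 5); p2 <- pars(phi = 5, delta = 5)
  expect_equal(
    longitudinal_loglik("t-t-mod1", y, tt, p1, e1, include_ranef = TRUE),
    longitudinal_loglik("t-t-mod2", y, tt, p2, e1, include_ranef = TRUE))

  # Monte-Carlo scale mixture vs closed-form Student-t (KS distance)
  set.seed(42)
  nu <- 5
  w <- rgamma(1e5, nu / 2, nu / 2)
  x <- rnorm(1e5) / sqrt(w)
  ks <- suppressWarnings(ks.test(x, pt, df = nu))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("conditional residuals diagnose normality and heavy tails", {
  sc <- small_scenario("nor-nor", FALSE, n = 150, seed = 11,
                       dropout_rate = 0)
  d <- generate_cohort(sc, 1)
  eff <- attr(d, "true_effects")
  effects <- setNames(lapply(seq_len(nrow(eff$b)), function(i)
    list(b = eff$b[i, ])), d$survival$subject_id)
  cr <- conditional_residuals(d, sc$long_params, effects,
                              covariate_names = c("age_std", "sex"))
  expect_gt(nrow(cr$residuals), 1500)
  fitq <- lm(sample_q ~ theoretical_q, data = cr$qq)
  expect_equal(unname(coef(fitq)[2]), 1, tolerance = 0.05)
  expect_equal(unname(coef(fitq)[1]), 0, tolerance = 0.05)

  # perfect fit: residuals exactly zero
  d0 <- d
  idx <- match(d0$longitudinal$subject_id, d0$survival$subject_id)
  X <- as.matrix(d0$survival[idx, c("age_std", "sex")])
  bmat <- eff$b[idx, ]
  d0$longitudinal$value <-
    (sc$long_params$beta[1] + bmat[, 1]) +
    (sc$long_params$beta[2] + bmat[, 2]) * d0$longitudinal$time +
    drop(X %*% sc$long_params$beta[3:4])
  cr0 <- conditional_residuals(d0, sc$long_params, effects,
                               covariate_names = c("age_std", "sex"))
  expect_equal(max(abs(cr0$residuals$residual)), 0, tolerance = 1e-10)

  # 5% e-outliers at 10 sigma produce positive excess kurtosis
  sc2 <- small_scenario("nor-nor", FALSE, n = 150, seed = 11,
                        dropout_rate = 0,
                        contamination = list(b_frac = 0, b_scale = 1,
                                             e_frac = 0.05, e_scale = 10))
  d2 <- generate_cohort(sc2, 1)
  eff2 <- attr(d2, "true_effects")
  effects2 <- setNames(lapply(seq_len(nrow(eff2$b)), function(i)
    list(b = eff2$b[i, ])), d2$survival$subject_id)
  r2 <- conditional_residuals(d2, sc2$long_params, effects2,
                              covariate_names = c("age_std", "sex"))$residuals$residual
  exkurt <- mean((r2 - mean(r2))^4) / var(r2)^2 - 3
  expect_gt(exkurt, 0)
})

test_that("posterior mixing weights flag injected b- and e-outliers", {
  sc <- small_scenario("nor-nor", FALSE, n = 80, seed = 13, dropout_rate = 0)
  d <- generate_cohort(sc, 1)
  ids <- d$survival$subject_id
  long <- d$longitudinal
  # b-outlier: shift one subject's whole trajectory by +6 random-intercept SD
  shift_id <- ids[5]
  long$value[long$subject_id == shift_id] <-
    long$value[long$subject_id == shift_id] + 6 * sqrt(sc$long_params$Sigma[1, 1])
  # e-outlier: one single observation at -8 residual SD
  cand <- names(which(table(long$subject_id) >= 5))
  spike_id <- setdiff(cand, shift_id)[1]
  spike_rows <- which(long$subject_id == spike_id)
  spike_row <- spike_rows[3]
  long$value[spike_row] <- long$value[spike_row] - 8 * sc$long_params$sigma
  d2 <- jm_data(long, d$survival)

  spec <- jm_model_spec("t-t-mod3", FALSE,
    longitudinal_covariates = c("age_std", "sex"),
    survival_covariates = c("age_std", "sex"),
    control = jm_control(chains = 2, warmup = 250, iter = 250, seed = 31))
  f <- suppressWarnings(jm_fit(spec, d2))
  ow <- outlier_weight_summary(f)

  rk <- ow$subjects$rank[ow$subjects$subject_id == shift_id]
  expect_lte(rk, ceiling(0.05 * n_subjects(d2)))

  obs <- ow$observations[ow$observations$subject_id == spike_id, ]
  spike_time <- long$time[spike_row]
  expect_equal(obs$time[which.max(obs$e_inflation)], spike_time)

  expect_error(outlier_weight_summary(cached_fit("nor")), "Student-t")
})

test_that("on clean normal data the median inflation stays near 1", {
  d <- generate_cohort(small_scenario("nor-nor", FALSE, n = 80, seed = 13), 1)
  spec <- jm_model_spec("t-t-mod3", FALSE,
    control = jm_control(chains = 2, warmup = 250, iter = 250, seed = 33))
  f <- suppressWarnings(jm_fit(spec, d))
  ow <- outlier_weight_summary(f)
  expect_equal(median(ow$observations$e_inflation), 1, tolerance = 0.1)
  expect_equal(median(ow$subjects$b_inflation), 1, tolerance = 0.25)
})
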