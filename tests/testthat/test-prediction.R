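mvtnorm_log2 <- function(b, S) {
  -log(2 * pi) - 0.5 * as.numeric(determinant(S)$modulus) -
    0.5 * drop(crossprod(b, solve(S, b)))
}

test_that("risk transform reproduces the worked albumin example", {
  # 9% twelve-month risk at 38 g/L; HR 1.22 per 1 g/L decrease
  expect_equal(round(100 * risk_transform_ph(0.09, 1.22, 4)), 19)
  expect_equal(round(100 * risk_transform_ph(0.09, 1.22, 8)), 37)
  expect_equal(risk_transform_ph(0.09, 1.22, 0), 0.09)
  expect_error(risk_transform_ph(1.2, 1.22, 1), "between 0 and 1")
  expect_error(risk_transform_ph(0.5, -1, 1), "> 0")
})

test_that("conditional effects shrink toward the grid-integration oracle", {
  f <- cached_fit("nor")
  sc <- small_scenario("nor-nor", FALSE, n = 100, seed = 7)
  # a new subject observed 2 g/L above the population line, 30 visits to s
  s <- 2
  tt <- seq(0, s, length.out = 30)
  row <- data.frame(subject_id = "NEW", event_time = 10, event_code = 0L,
                    age_std = 0, sex = 0)
  nd <- jm_data(data.frame(subject_id = "NEW", time = tt,
                           value = 38 - 0.5 * tt + 2),
                row)
  set.seed(99)
  bs <- conditional_effects_sample(f, nd, "NEW", s = s, n_steps = 40,
                                   thin = 4)
  js <- attr(bs, "draw")

  # oracle: per parameter draw, 2-D grid integration of p(b | y, T>s),
  # written from scratch (vectorized Gauss-Legendre for the survival term)
  grid <- expand.grid(b0 = seq(-4, 6, length.out = 61),
                      b1 = seq(-2, 2, length.out = 41))
  rule <- pracma::gaussLegendre(15, 0, s)
  yy <- nd$longitudinal$value
  oracle <- vapply(js, function(j) {
    dr <- rjmcr:::get_draw(f, j)
    lp <- dr$long
    sv <- dr$surv$death
    mu0 <- lp$beta[1] + lp$beta[2] * tt   # covariates are zero for NEW
    ll_long <- vapply(seq_len(nrow(grid)), function(g)
      sum(dnorm(yy, mu0 + grid$b0[g] + grid$b1[g] * tt, lp$sigma,
                log = TRUE)) +
        mvtnorm_log2(c(grid$b0[g], grid$b1[g]), lp$Sigma),
      numeric(1))
    # H(s | b) on the grid: m(u) = beta0 + b0 + (beta_t + b1) u
    m_nodes <- outer(grid$b0, rep(1, 15)) + lp$beta[1] +
      outer(lp$beta[2] + grid$b1, rule$x)
    hz <- exp(sv$logk + sv$loglam) * exp(sv$logk - sv$logk) *
      exp(sv$alpha * (m_nodes - f$m_ref))
    hz <- exp(sv$logk + sv$loglam) *
      matrix(rule$x^(exp(sv$logk) - 1), nrow(grid), 15, byrow = TRUE) *
      exp(sv$alpha * (m_nodes - f$m_ref)) * exp(sv$logk)
    hz <- hz / exp(sv$logk) # shape factor applied once below
    H <- exp(sv$logk) * drop(hz %*% rule$w)
    ll <- ll_long - H
    w <- exp(ll - max(ll))
    sum(w * grid$b0) / sum(w)
  }, numeric(1))
  expect_equal(mean(bs[, 1]), mean(oracle), tolerance = 0.15)
  # the offset subject is recognised: posterior b0 near +2
  expect_equal(mean(bs[, 1]), 2, tolerance = 0.5)
})

test_that("with no data and a null landmark the conditional is the prior", {
  f <- cached_fit("nor")
  nd <- jm_data(
    data.frame(subject_id = "X", time = 0, value = 38),
    data.frame(subject_id = "X", event_time = 10, event_code = 0L,
               age_std = 0, sex = 0))
  nd$longitudinal <- nd$longitudinal[0, ]
  set.seed(7)
  bs <- do.call(rbind, lapply(1:6, function(i)
    conditional_effects_sample(f, nd, "X", s = 0, n_steps = 5,
                               require_data = FALSE)))
  # matched prior draws from the same posterior parameter draws
  set.seed(8)
  prior <- unlist(lapply(1:6, function(i)
    vapply(seq_len(rjmcr:::n_draws(f)), function(j) {
      S <- rjmcr:::get_draw(f, j)$long$Sigma
      rnorm(1, 0, sqrt(S[1, 1]))
    }, numeric(1))))
  ks <- suppressWarnings(ks.test(bs[, 1], prior))
  expect_lt(unname(ks$statistic), 0.05)
  expect_error(conditional_effects_sample(f, nd, "X", s = 1), "no measurements")
})

test_that("death predictions match closed forms and are monotone in u", {
  f <- cached_fit("nor")
  # constant-hazard construction: overwrite the survival draws
  f2 <- f
  f2$chains <- lapply(f$chains, function(ch) {
    m <- ch$draws$surv[[1]]
    m[, "logshape"] <- 0
    m[, "lograte"] <- log(0.3)
    m[, grep("zeta", colnames(m))] <- 0
    m[, "alpha"] <- 0
    ch$draws$surv[[1]] <- m
    ch
  })
  nd <- jm_data(
    data.frame(subject_id = "X", time = c(0, 0.5, 1), value = c(38, 37, 38)),
    data.frame(subject_id = "X", event_time = 10, event_code = 0L,
               age_std = 0, sex = 0))
  p <- predict_death(f2, nd, "X", s = 1, u = c(0, 0.5, 1), thin = 10)
  expect_equal(p$p_death[1], 0)
  expect_equal(p$p_death[2], 1 - exp(-0.3 * 0.5), tolerance = 1e-8)
  expect_equal(p$p_death[3], 1 - exp(-0.3 * 1), tolerance = 1e-8)
  expect_true(all(diff(p$p_death) >= 0))
  expect_true(all(p$lo95 <= p$p_death & p$p_death <= p$hi95))
  expect_error(predict_death(f2, nd, "X", s = 1, u = -1), "u must be")
})

test_that("competing-risks prediction is dominated by the censoring-based one", {
  f <- cached_fit("cr")
  nd <- generate_test_patients(small_scenario("t-t-mod3", TRUE, n = 100,
                                              seed = 9), n = 8)
  ids <- nd$survival$subject_id[nd$survival$event_time > 1][1:3]
  set.seed(3)
  p_cr <- predict_death(f, nd, ids, s = 1, u = 1, competing_risks = TRUE,
                        thin = 25)
  set.seed(3)
  p_cens <- predict_death(f, nd, ids, s = 1, u = 1, competing_risks = FALSE,
                          thin = 25)
  expect_true(all(p_cr$p_death <= p_cens$p_death + 1e-10))
})

test_that("biomarker prediction tracks the trajectory", {
  f <- cached_fit("nor")
  s <- 2
  tt <- seq(0, s, by = 0.25)
  nd <- jm_data(
    data.frame(subject_id = "X", time = tt, value = 38 - 0.5 * tt),
    data.frame(subject_id = "X", event_time = 10, event_code = 0L,
               age_std = 0, sex = 0))
  set.seed(5)
  pb <- predict_biomarker(f, nd, "X", s = s, u = c(0, 1), thin = 2)
  # dense data on the population line: u = 0 prediction near the current value
  expect_equal(pb$biomarker_pred[1], 38 - 0.5 * s, tolerance = 0.5)
  # linearity: one year ahead moves by about the population slope
  slope <- mean(f$scalars[, "time"])
  expect_equal(pb$biomarker_pred[2] - pb$biomarker_pred[1], slope,
               tolerance = 0.35)
  expect_true(all(pb$lo95 <= pb$biomarker_pred &
                    pb$biomarker_pred <= pb$hi95))
})

test_that("prediction at u1+u2 is consistent with chained conditioning", {
  f <- cached_fit("nor")
  tt <- seq(0, 1, by = 0.25)
  nd <- jm_data(
    data.frame(subject_id = "X", time = tt, value = 38 - 0.5 * tt),
    data.frame(subject_id = "X", event_time = 10, event_code = 0L,
               age_std = 0, sex = 0))
  set.seed(11)
  p_full <- predict_death(f, nd, "X", s = 1, u = 1, thin = 2)$p_death
  set.seed(12)
  p1 <- predict_death(f, nd, "X", s = 1, u = 0.5, thin = 2)$p_death
  set.seed(13)
  p2 <- predict_death(f, nd, "X", s = 1.5, u = 0.5, thin = 2)$p_death
  chained <- 1 - (1 - p1) * (1 - p2)
  expect_equal(p_full, chained, tolerance = 0.03)
})
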