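test_that("default scenario reproduces the reference cohort dimensions", {
  sc <- jm_scenario()
  expect_equal(sc$n_subjects, 236)
  expect_equal(sc$n_cohorts, 200)
  expect_equal(sc$n_subjects * sc$n_cohorts, 47200)
  expect_equal(sc$visit_times[1:3], c(0, 0.25, 0.5))
  expect_equal(max(sc$visit_times), 8)
  # 3-monthly to 3 years, 6-monthly thereafter
  expect_true(all(diff(sc$visit_times[sc$visit_times <= 3]) == 0.25))
  expect_true(all(diff(sc$visit_times[sc$visit_times >= 3]) == 0.5))
  d <- generate_cohort(jm_scenario(seed = 12), 1)
  expect_equal(n_subjects(d), 236)
  # hazard-ratio calibration of the truth: exp(-alpha) in the 1.22-1.28 band
  expect_gt(exp(-sc$causes$death$alpha), 1.22)
  expect_lt(exp(-sc$causes$death$alpha), 1.28)
})

test_that("generation is deterministic and produces valid byte-identical CSVs", {
  sc <- small_scenario(n = 25, seed = 40)
  d1 <- generate_cohort(sc, 2)
  d2 <- generate_cohort(sc, 2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  s1 <- withr::local_tempfile(fileext = ".csv")
  s2 <- withr::local_tempfile(fileext = ".csv")
  write_jm_data(d1, f1, s1)
  write_jm_data(d2, f2, s2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(s1), readLines(s2))
  # different cohort index gives different data
  expect_false(identical(generate_cohort(sc, 3)$survival$event_time,
                         d1$survival$event_time))
})

test_that("event-time inversion matches closed forms", {
  lp <- list(beta = c(38, 0), sigma = 1)
  # single cause, constant hazard 0.5: T = -log(U)/0.5; U = exp(-0.5) -> T = 1
  ev <- simulate_event_time(list(b = c(0, 0)), causes =
    list(death = cause_params(1, 0.5)), long_params = lp, t_max = 50,
    u = exp(-0.5))
  expect_equal(ev$time, 1.0, tolerance = 1e-6)
  expect_equal(ev$cause, 1L)
  # beyond the horizon: administratively censored
  ev2 <- simulate_event_time(list(b = c(0, 0)), causes =
    list(death = cause_params(1, 0.5)), long_params = lp, t_max = 0.5,
    u = exp(-0.5))
  expect_equal(ev2$time, 0.5)
  expect_equal(ev2$cause, 0L)

  # two constant hazards 0.1 and 0.3: cause-2 fraction 0.75
  set.seed(50)
  causes2 <- list(a = cause_params(1, 0.1), b = cause_params(1, 0.3))
  cs <- replicate(4000, simulate_event_time(list(b = c(0, 0)),
    causes = causes2, long_params = lp, t_max = 1000)$cause)
  expect_equal(mean(cs == 2), 0.75, tolerance = 3 * sqrt(0.25 * 0.75 / 4000) + 0.005)

  # KM of simulated single-cause Weibull times matches lambda t^k
  set.seed(51)
  k <- 1.4; lam <- 0.3
  tt <- replicate(3000, simulate_event_time(list(b = c(0, 0)),
    causes = list(d = cause_params(k, lam)), long_params = lp,
    t_max = 100)$time)
  sf <- survival::survfit(survival::Surv(tt, rep(1, 3000)) ~ 1)
  sup <- max(abs(sf$surv - exp(-lam * sf$time^k)))
  expect_lt(sup, 0.02)
})

test_that("clean normal cohorts have normal residuals; contamination fattens tails", {
  sc <- small_scenario("nor-nor", FALSE, n = 150, seed = 61, dropout_rate = 0)
  d <- generate_cohort(sc, 1)
  eff <- attr(d, "true_effects")
  idx <- match(d$longitudinal$subject_id, d$survival$subject_id)
  X <- as.matrix(d$survival[idx, c("age_std", "sex")])
  mu <- (sc$long_params$beta[1] + eff$b[idx, 1]) +
    (sc$long_params$beta[2] + eff$b[idx, 2]) * d$longitudinal$time +
    drop(X %*% sc$long_params$beta[3:4])
  r <- (d$longitudinal$value - mu) / sc$long_params$sigma
  expect_gt(nrow(d$longitudinal), 1000)
  expect_gt(shapiro.test(sample(r, min(2000, length(r))))$p.value, 0.01)

  sc2 <- small_scenario("nor-nor", FALSE, n = 150, seed = 61, dropout_rate = 0,
    contamination = list(b_frac = 0, b_scale = 1, e_frac = 0.05, e_scale = 8))
  d2 <- generate_cohort(sc2, 1)
  eff2 <- attr(d2, "true_effects")
  idx2 <- match(d2$longitudinal$subject_id, d2$survival$subject_id)
  X2 <- as.matrix(d2$survival[idx2, c("age_std", "sex")])
  mu2 <- (sc2$long_params$beta[1] + eff2$b[idx2, 1]) +
    (sc2$long_params$beta[2] + eff2$b[idx2, 2]) * d2$longitudinal$time +
    drop(X2 %*% sc2$long_params$beta[3:4])
  r2 <- (d2$longitudinal$value - mu2) / sc2$long_params$sigma
  exkurt <- mean((r2 - mean(r2))^4) / var(r2)^2 - 3
  expect_gt(exkurt, 1)
})

test_that("albumin declines before death under the negative association", {
  d <- generate_cohort(jm_scenario(n_subjects = 400, seed = 71,
                                   dropout_rate = 0), 1)
  sv <- d$survival
  deaths <- sv$subject_id[sv$event_code == 1 & sv$event_time > 2]
  long <- d$longitudinal[d$longitudinal$subject_id %in% deaths, ]
  Tt <- sv$event_time[match(long$subject_id, sv$subject_id)]
  rev_t <- Tt - long$time
  final_year <- mean(long$value[rev_t <= 1])
  earlier <- mean(long$value[rev_t > 1])
  expect_lt(final_year, earlier)
})

test_that("independent test patients are disjoint and event-rate consistent", {
  sc <- small_scenario(n = 120, seed = 81)
  d <- generate_cohort(sc, 1)
  tp <- generate_test_patients(sc, n = 140)
  expect_equal(n_subjects(tp), 140)
  expect_length(intersect(tp$survival$subject_id, d$survival$subject_id), 0)
  # event rate within 3 binomial SEs of the training cohort's
  p_train <- mean(d$survival$event_code > 0)
  p_test <- mean(tp$survival$event_code > 0)
  se <- sqrt(p_train * (1 - p_train) * (1 / 120 + 1 / 140))
  expect_lt(abs(p_test - p_train), 3 * se)
  # n = 0 gives an empty, still-valid dataset
  empty <- generate_test_patients(sc, n = 0)
  expect_equal(n_subjects(empty), 0)
  expect_s3_class(empty, "jm_data")
})
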