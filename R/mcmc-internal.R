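# Internal machinery for the blocked Metropolis-within-Gibbs sampler.
#
# The Gamma scale-mixture representation of the Student-t makes most of the
# longitudinal hierarchy conditionally conjugate: mixing weights, the
# random-effects covariance and the residual variance are Gibbs steps.
# Fixed effects and random effects are proposed from their exact
# longitudinal-conditional Gaussians and accepted with the survival
# likelihood ratio (an independence Metropolis step that is exact for the
# joint target). Weibull/association blocks and degrees of freedom use
# adaptive random-walk Metropolis tuned during warmup.

make_model_data <- function(spec, data, order = 15) {
  sv <- data$survival
  long <- data$longitudinal
  ids <- sv$subject_id
  N <- length(ids)
  subj <- match(long$subject_id, ids)
  y <- long$value
  tim <- long$time
  pc <- spec$longitudinal_covariates
  missing_cov <- setdiff(unlist(c(pc, spec$survival_covariates)),
                         data$covariate_names)
  if (length(missing_cov))
    stop("covariates not in dataset: ", paste(missing_cov, collapse = ", "))
  Xl_subj <- if (length(pc)) as.matrix(sv[, pc, drop = FALSE]) else
    matrix(0, N, 0)
  X <- cbind(`(Intercept)` = 1, time = tim, Xl_subj[subj, , drop = FALSE])
  colnames(X) <- c("(Intercept)", "time", pc)

  Tt <- sv$event_time
  code <- sv$event_code
  if (spec$competing_risks) {
    cause_of <- ifelse(code == 0, 0L, code) # 1 death, 2 hd, 3 ktx
  } else {
    cause_of <- ifelse(code == 1, 1L, 0L)
  }
  K <- length(spec$causes)
  W <- lapply(spec$causes, function(cz) {
    cn <- spec$survival_covariates[[cz]]
    if (length(cn)) as.matrix(sv[, cn, drop = FALSE]) else matrix(0, N, 0)
  })
  names(W) <- spec$causes

  rule <- gl_rule(order)
  Tn <- outer(Tt, rule$x)          # N x Q node times
  Qw <- outer(Tt, rule$w)          # N x Q node weights (include T factor)
  logTn <- log(Tn)
  logT <- log(Tt)

  list(N = N, ids = ids, subj = subj, y = y, tim = tim, X = X,
       Xl_subj = Xl_subj, n_i = tabulate(subj, N),
       Tt = Tt, logT = logT, cause_of = cause_of, K = K, W = W,
       Tn = Tn, Qw = Qw, logTn = logTn,
       m_ref = mean(y), long = long, sv = sv)
}

# survival log-likelihood contributions, vectorized over subjects.
# a, s: subject-level trajectory intercept/slope (fixed + random + covars).
# sp: list over causes of list(logk, loglam, zeta, alpha).
# cause = 0 -> all causes; otherwise terms involving that cause only.
surv_ll_subjects <- function(md, sp, a, s, cause = 0L) {
  ll <- numeric(md$N)
  a_c <- a - md$m_ref
  kk <- if (cause == 0L) seq_len(md$K) else cause
  for (k in kk) {
    p <- sp[[k]]
    shape <- exp(p$logk)
    eta <- if (ncol(md$W[[k]])) drop(md$W[[k]] %*% p$zeta) else 0
    if (p$alpha != 0) {
      Ik <- rowSums(md$Qw * exp((shape - 1) * md$logTn +
                                  (p$alpha * s) * md$Tn))
      H <- shape * exp(p$loglam) * exp(eta + p$alpha * a_c) * Ik
    } else {
      H <- exp(p$loglam + eta) * md$Tt^shape
    }
    ll <- ll - H
    ev <- md$cause_of == k
    if (any(ev)) {
      lh <- p$logk + p$loglam + (shape - 1) * md$logT[ev] +
        (if (length(eta) > 1) eta[ev] else eta) +
        p$alpha * (a_c[ev] + s[ev] * md$Tt[ev])
      ll[ev] <- ll[ev] + lh
    }
  }
  ll
}

# longitudinal conditional log-likelihood per subject given b and weights
long_ll_subjects <- function(md, r, sigma2, w_e_obs) {
  ll_obs <- -0.5 * (log(2 * pi * sigma2) - log(w_e_obs) +
                      w_e_obs * r^2 / sigma2)
  as.numeric(rowsum(ll_obs, md$subj, reorder = TRUE))
}

chol2_sample <- function(m1, m2, v11, v12, v22, z1, z2) {
  # sample from N(m, V) for many 2x2 covariance matrices at once
  l11 <- sqrt(v11)
  l21 <- v12 / l11
  l22 <- sqrt(pmax(v22 - l21^2, 1e-12))
  cbind(m1 + l11 * z1, m2 + l21 * z1 + l22 * z2)
}

df_logtarget <- function(nu, w, prior) {
  if (nu <= 2 || nu > 100) return(-Inf)
  n <- length(w)
  h <- nu / 2
  n * (h * log(h) - lgamma(h)) + (h - 1) * sum(log(w)) - h * sum(w) +
    stats::dgamma(nu - 2, shape = prior$df_shape, rate = prior$df_rate,
                  log = TRUE)
}

run_jm_chain <- function(md, spec, chain_seed, warmup, iter) {
  set.seed(chain_seed)
  st <- variant_structure(spec$variant)
  pr <- spec$priors
  N <- md$N; n_obs <- length(md$y); K <- md$K
  p_beta <- ncol(md$X)

  # --- initial values: least squares + mild jitter ---------------------
  fit0 <- stats::lm.fit(md$X, md$y)
  beta <- fit0$coefficients + stats::rnorm(p_beta, 0, 0.05)
  beta[is.na(beta)] <- 0
  sigma2 <- max(stats::var(fit0$residuals) * 0.8, 1e-4)
  Sigma <- diag(c(max(stats::var(fit0$residuals) * 0.4, 0.5), 0.05))
  b <- matrix(0, N, 2)
  w_b <- rep(1, N)
  w_e_obs <- rep(1, n_obs)        # per-observation expansion
  phi <- delta <- gamma_df <- 10
  sp <- lapply(seq_len(K), function(k) {
    nev <- sum(md$cause_of == k)
    list(logk = 0,
         loglam = log(max(nev, 0.5) / sum(md$Tt)),
         zeta = rep(0, ncol(md$W[[k]])),
         alpha = 0)
  })

  subj_fixed <- function(beta) {
    xb <- drop(md$X %*% beta)                        # obs-level fixed part
    a <- beta[1] + (if (ncol(md$Xl_subj))
      drop(md$Xl_subj %*% beta[-(1:2)]) else 0)      # subject-level at t=0
    list(xb = xb, a = a)
  }
  sf <- subj_fixed(beta)
  a_subj <- sf$a + b[, 1]
  s_subj <- beta[2] + b[, 2]

  ll_surv <- surv_ll_subjects(md, sp, a_subj, s_subj)
  if (!all(is.finite(ll_surv))) stop("non-finite initial log-posterior")

  # --- adaptation state ------------------------------------------------
  theta_dim <- vapply(sp, function(p) 2L + length(p$zeta) + 1L, 1L)
  ad <- lapply(seq_len(K), function(k) list(
    mean = numeric(theta_dim[k]), cov = diag(theta_dim[k]) * 0,
    n = 0, lsc = log(0.1 / sqrt(theta_dim[k])), acc = 0, try = 0))
  df_ad <- list(phi = list(lsc = log(0.5), acc = 0, try = 0),
                delta = list(lsc = log(0.5), acc = 0, try = 0),
                gamma = list(lsc = log(0.5), acc = 0, try = 0))

  n_keep <- iter
  total <- warmup + iter
  draws <- list(
    beta = matrix(NA_real_, n_keep, p_beta,
                  dimnames = list(NULL, colnames(md$X))),
    sigma = numeric(n_keep),
    Sigma = matrix(NA_real_, n_keep, 3,
                   dimnames = list(NULL, c("S11", "S22", "S12"))),
    df = matrix(NA_real_, n_keep, 3,
                dimnames = list(NULL, c("phi", "delta", "gamma_df"))),
    surv = lapply(seq_len(K), function(k)
      matrix(NA_real_, n_keep, theta_dim[k],
             dimnames = list(NULL, c("logshape", "lograte",
                                     if (length(spec$survival_covariates[[k]]))
                                       paste0("zeta_", spec$survival_covariates[[k]]),
                                     "alpha")))),
    b = array(NA_real_, c(n_keep, N, 2)),
    ll = matrix(NA_real_, n_keep, N))
  inv_wb_sum <- numeric(N)
  inv_we_sum <- numeric(if (st$e_level == "obs") n_obs else N)
  acc <- c(beta = 0, b = 0)

  theta_get <- function(k) c(sp[[k]]$logk, sp[[k]]$loglam, sp[[k]]$zeta,
                             sp[[k]]$alpha)
  theta_set <- function(k, th) {
    q <- length(sp[[k]]$zeta)
    list(logk = th[1], loglam = th[2],
         zeta = if (q) th[2 + seq_len(q)] else numeric(),
         alpha = th[length(th)])
  }
  theta_lprior <- function(th) {
    q <- length(th) - 3L
    stats::dnorm(th[1], 0, pr$logshape_sd, log = TRUE) +
      stats::dnorm(th[2], 0, pr$lograte_sd, log = TRUE) +
      (if (q) sum(stats::dnorm(th[2 + seq_len(q)], 0, pr$zeta_sd, log = TRUE)) else 0) +
      stats::dnorm(th[length(th)], 0, pr$alpha_sd, log = TRUE)
  }

  S0 <- pr$Sigma_scale
  nu0 <- pr$Sigma_df

  for (it in seq_len(total)) {
    in_warmup <- it <= warmup

    ## residuals given current state
    xb <- sf$xb
    r <- md$y - xb - b[md$subj, 1] - b[md$subj, 2] * md$tim

    ## 1. mixing weights (Gibbs, exact)
    if (st$b_t || st$e_t) {
      Sinv <- solve(Sigma)
      qb <- rowSums((b %*% Sinv) * b)
      sse <- as.numeric(rowsum(r^2, md$subj, reorder = TRUE))
      if (st$shared) {
        w <- stats::rgamma(N, (gamma_df + 2 + md$n_i) / 2,
                           (gamma_df + qb + sse / sigma2) / 2)
        w_b <- w
        w_e_obs <- w[md$subj]
      } else {
        if (st$b_t)
          w_b <- stats::rgamma(N, (phi + 2) / 2, (phi + qb) / 2)
        if (st$e_t) {
          if (st$e_level == "obs") {
            w_e_obs <- stats::rgamma(n_obs, (delta + 1) / 2,
                                     (delta + r^2 / sigma2) / 2)
          } else {
            w_sub <- stats::rgamma(N, (delta + md$n_i) / 2,
                                   (delta + sse / sigma2) / 2)
            w_e_obs <- w_sub[md$subj]
          }
        }
      }
    }

    ## 2. degrees of freedom (adaptive RW on log(nu - 2))
    upd_df <- function(nu, w, slot) {
      a1 <- df_ad[[slot]]
      thc <- log(nu - 2)
      thp <- thc + stats::rnorm(1, 0, exp(a1$lsc))
      nup <- 2 + exp(thp)
      lr <- df_logtarget(nup, w, pr) - df_logtarget(nu, w, pr) + thp - thc
      a1$try <- a1$try + 1
      ok <- is.finite(lr) && log(stats::runif(1)) < lr
      if (ok) { nu <- nup; a1$acc <- a1$acc + 1 }
      if (in_warmup)
        a1$lsc <- a1$lsc + (min(1, exp(min(lr, 0))) - 0.35) / sqrt(it)
      df_ad[[slot]] <<- a1
      nu
    }
    if (st$shared) {
      gamma_df <- upd_df(gamma_df, w_b, "gamma")
    } else {
      if (st$b_t) phi <- upd_df(phi, w_b, "phi")
      if (st$e_t) {
        w_for_delta <- if (st$e_level == "obs") w_e_obs else
          w_e_obs[match(seq_len(N), md$subj)]
        delta <- upd_df(delta, w_for_delta, "delta")
      }
    }

    ## 3. random-effects covariance (inverse-Wishart Gibbs)
    Sb <- crossprod(b * sqrt(w_b))
    Wdraw <- stats::rWishart(1, nu0 + N, solve(S0 + Sb))[, , 1]
    Sigma <- solve(Wdraw)
    Sigma <- (Sigma + t(Sigma)) / 2

    ## 4. residual variance (inverse-Gamma Gibbs)
    sigma2 <- 1 / stats::rgamma(1, pr$sigma_a + n_obs / 2,
                                pr$sigma_b + sum(w_e_obs * r^2) / 2)

    ## 5. fixed effects: longitudinal-conditional proposal, survival MH
    yt <- md$y - b[md$subj, 1] - b[md$subj, 2] * md$tim
    Xw <- md$X * (w_e_obs / sigma2)
    P <- crossprod(md$X, Xw) + diag(p_beta) / pr$beta_sd^2
    mb <- solve(P, crossprod(Xw, yt))
    U <- chol(solve(P))
    beta_p <- drop(mb + t(U) %*% stats::rnorm(p_beta))
    sf_p <- subj_fixed(beta_p)
    a_p <- sf_p$a + b[, 1]
    s_p <- beta_p[2] + b[, 2]
    ll_surv_p <- surv_ll_subjects(md, sp, a_p, s_p)
    lr <- sum(ll_surv_p) - sum(ll_surv)
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      beta <- beta_p; sf <- sf_p
      a_subj <- a_p; s_subj <- s_p; ll_surv <- ll_surv_p
      acc["beta"] <- acc["beta"] + 1
    } else {
      a_subj <- sf$a + b[, 1]
      s_subj <- beta[2] + b[, 2]
    }

    ## 6. random effects: per-subject independence MH, vectorized
    r0 <- md$y - sf$xb
    wz <- w_e_obs / sigma2
    Sw   <- as.numeric(rowsum(wz, md$subj, reorder = TRUE))
    Swt  <- as.numeric(rowsum(wz * md$tim, md$subj, reorder = TRUE))
    Swt2 <- as.numeric(rowsum(wz * md$tim^2, md$subj, reorder = TRUE))
    Sr   <- as.numeric(rowsum(wz * r0, md$subj, reorder = TRUE))
    Srt  <- as.numeric(rowsum(wz * r0 * md$tim, md$subj, reorder = TRUE))
    Sinv <- solve(Sigma)
    p11 <- Sw + w_b * Sinv[1, 1]
    p12 <- Swt + w_b * Sinv[1, 2]
    p22 <- Swt2 + w_b * Sinv[2, 2]
    det <- p11 * p22 - p12^2
    v11 <- p22 / det; v22 <- p11 / det; v12 <- -p12 / det
    m1 <- v11 * Sr + v12 * Srt
    m2 <- v12 * Sr + v22 * Srt
    b_p <- chol2_sample(m1, m2, v11, v12, v22,
                        stats::rnorm(N), stats::rnorm(N))
    a_p <- sf$a + b_p[, 1]
    s_p <- beta[2] + b_p[, 2]
    ll_surv_p <- surv_ll_subjects(md, sp, a_p, s_p)
    u <- log(stats::runif(N))
    take <- is.finite(ll_surv_p) & (u < ll_surv_p - ll_surv)
    b[take, ] <- b_p[take, ]
    ll_surv[take] <- ll_surv_p[take]
    a_subj <- sf$a + b[, 1]
    s_subj <- beta[2] + b[, 2]
    acc["b"] <- acc["b"] + mean(take)

    ## 7. survival blocks: adaptive Metropolis per cause
    for (k in seq_len(K)) {
      a1 <- ad[[k]]
      d <- theta_dim[k]
      thc <- theta_get(k)
      Sprop <- if (a1$n > 10 * d) {
        2.38^2 / d * (a1$cov + diag(d) * 1e-8) * exp(a1$lsc)
      } else diag(d) * exp(2 * a1$lsc)
      eps <- drop(stats::rnorm(d) %*% chol(Sprop))
      thp <- thc + eps
      spp <- sp
      spp[[k]] <- theta_set(k, thp)
      llc <- surv_ll_subjects(md, sp,  a_subj, s_subj, cause = k)
      llp <- surv_ll_subjects(md, spp, a_subj, s_subj, cause = k)
      lr <- sum(llp) - sum(llc) + theta_lprior(thp) - theta_lprior(thc)
      a1$try <- a1$try + 1
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        sp <- spp
        ll_surv <- ll_surv - llc + llp
        a1$acc <- a1$acc + 1
      }
      if (in_warmup) {
        a1$lsc <- a1$lsc + (min(1, exp(min(lr, 0, na.rm = TRUE))) - 0.25) /
          sqrt(it)
        thn <- theta_get(k)
        a1$n <- a1$n + 1
        dlt <- thn - a1$mean
        a1$mean <- a1$mean + dlt / a1$n
        a1$cov <- a1$cov * (a1$n - 1) / a1$n + tcrossprod(dlt) / a1$n
      }
      ad[[k]] <- a1
    }

    ## store
    if (!in_warmup) {
      j <- it - warmup
      draws$beta[j, ] <- beta
      draws$sigma[j] <- sqrt(sigma2)
      draws$Sigma[j, ] <- c(Sigma[1, 1], Sigma[2, 2], Sigma[1, 2])
      draws$df[j, ] <- c(if (st$b_t && !st$shared) phi else NA,
                         if (st$e_t && !st$shared) delta else NA,
                         if (st$shared) gamma_df else NA)
      for (k in seq_len(K)) draws$surv[[k]][j, ] <- theta_get(k)
      draws$b[j, , ] <- b
      r <- md$y - sf$xb - b[md$subj, 1] - b[md$subj, 2] * md$tim
      draws$ll[j, ] <- long_ll_subjects(md, r, sigma2, w_e_obs) + ll_surv
      inv_wb_sum <- inv_wb_sum + 1 / w_b
      inv_we_sum <- inv_we_sum + if (st$e_level == "obs") 1 / w_e_obs else
        1 / w_e_obs[match(seq_len(N), md$subj)]
    }
  }

  list(draws = draws, accept = acc / total,
       inv_wb = inv_wb_sum / n_keep, inv_we = inv_we_sum / n_keep)
}
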