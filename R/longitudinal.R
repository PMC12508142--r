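#' Model-implied biomarker trajectory
#'
#' The linear mixed sub-model implies, for subject i,
#' m_i(t) = (beta0 + b0) + (beta_t + b1) t + x_i' beta_x,
#' the smooth biomarker value entering the hazard through the current-value
#' link.
#'
#' @param params longitudinal parameter list with element \code{beta}
#'   (fixed effects: intercept, time slope, then covariate effects).
#' @param effects list with element \code{b}, the subject's 2-vector of
#'   random intercept and slope deviations (default zero).
#' @param covariates numeric vector of the subject's baseline covariates
#'   (same order and length as \code{params$beta[-(1:2)]}).
#' @param t time(s) in years, >= 0.
#' @return fitted biomarker value(s), g/L.
#' @export
trajectory_value <- function(params, effects = list(b = c(0, 0)),
                             covariates = numeric(), t) {
  beta <- params$beta
  if (any(t < 0)) stop("t must be >= 0")
  p_cov <- length(beta) - 2L
  if (length(covariates) != p_cov)
    stop("covariate vector length ", length(covariates),
         " does not match beta (expects ", p_cov, ")")
  b <- effects$b
  cc <- if (p_cov) sum(beta[-(1:2)] * covariates) else 0
  (beta[[1]] + b[[1]]) + (beta[[2]] + b[[2]]) * t + cc
}

# log density of a d-dim multivariate t_nu(0, S), S = scale * I_d
mvt_logdens_iso <- function(x, nu, scale2) {
  d <- length(x)
  q <- sum(x^2) / scale2
  lgamma((nu + d) / 2) - lgamma(nu / 2) - d / 2 * log(nu * pi) -
    d / 2 * log(scale2) - (nu + d) / 2 * log1p(q / nu)
}

#' Longitudinal log-likelihood under the six outlier structures
#'
#' Conditional on the latent mixing weights, every variant is Gaussian:
#' residual variance sigma^2 / w_e (per-observation weights for the mod3
#' variants, a single subject-level weight for mod1/mod2) and random-effects
#' covariance Sigma / w_b. With \code{marginalize_weights = TRUE} the
#' residual weights are integrated over their Gamma(df/2, df/2) mixing law,
#' recovering the Student-t error densities: independent univariate t for
#' mod3, a jointly multivariate t for mod2 (which is what makes a subject's
#' residuals dependent), and for mod1 the t obtained from the weight shared
#' with the random effects.
#'
#' @param variant one of the six variant names, see [jm_model_spec()].
#' @param y,times the subject's measurements and times.
#' @param params longitudinal parameters: \code{beta}, \code{Sigma},
#'   \code{sigma}, and the df fields used by the variant (\code{phi},
#'   \code{delta}, or \code{gamma_df} for mod1).
#' @param effects list with \code{b} (2-vector), \code{w_b} (scalar weight),
#'   \code{w_e} (scalar for mod1/mod2, per-observation vector for mod3);
#'   weights default to 1.
#' @param covariates subject baseline covariates for the fixed effects.
#' @param marginalize_weights integrate the residual mixing weights out
#'   analytically instead of conditioning on them.
#' @param include_ranef add the log density of \code{b} (conditional on
#'   \code{w_b}, or marginalized jointly for mod1).
#' @return scalar log density.
#' @export
longitudinal_loglik <- function(variant, y, times, params,
                                effects = list(b = c(0, 0), w_b = 1, w_e = 1),
                                covariates = numeric(),
                                marginalize_weights = FALSE,
                                include_ranef = FALSE) {
  st <- variant_structure(variant)
  n <- length(y)
  stopifnot(length(times) == n)
  mu <- trajectory_value(params, effects, covariates, times)
  r <- y - mu
  sigma2 <- params$sigma^2
  Sigma <- params$Sigma
  if (!is.null(Sigma)) {
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("Sigma must be positive definite")
  }
  b <- effects$b
  w_b <- if (is.null(effects$w_b)) 1 else effects$w_b
  w_e <- if (is.null(effects$w_e)) 1 else effects$w_e

  ll_b <- 0
  if (include_ranef) {
    Sb <- Sigma / w_b
    ll_b <- -log(2 * pi) - 0.5 * determinant(Sb, logarithm = TRUE)$modulus -
      0.5 * drop(crossprod(b, solve(Sb, b)))
    ll_b <- as.numeric(ll_b)
  }

  if (!marginalize_weights || !st$e_t) {
    if (st$e_level == "obs" && length(w_e) == 1L) w_e <- rep(w_e, n)
    ll <- sum(stats::dnorm(r, 0, sqrt(sigma2 / w_e), log = TRUE))
    return(ll + ll_b)
  }

  # marginal over the residual mixing law
  if (st$shared) { # mod1: weight shared with the random effects
    g <- params$gamma_df
    if (include_ranef) {
      # joint (b, r) is multivariate t_g with block-diagonal scale
      d <- n + 2L
      qf <- drop(crossprod(b, solve(Sigma, b))) + sum(r^2) / sigma2
      ldet <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
        n * log(sigma2)
      return(lgamma((g + d) / 2) - lgamma(g / 2) - d / 2 * log(g * pi) -
               0.5 * ldet - (g + d) / 2 * log1p(qf / g))
    }
    # r | b after integrating the shared weight given b:
    # w | b ~ Gamma((g+2)/2, (g + b' Sigma^-1 b)/2)
    qb <- drop(crossprod(b, solve(Sigma, b)))
    nu <- g + 2
    s2 <- sigma2 * (g + qb) / nu
    return(mvt_logdens_iso(r, nu, s2))
  }
  dlt <- params$delta
  ll <- if (st$e_level == "obs") {
    sum(stats::dt(r / params$sigma, df = dlt, log = TRUE) - log(params$sigma))
  } else {
    mvt_logdens_iso(r, dlt, sigma2)
  }
  ll + ll_b
}

#' Standardized conditional residuals and Q-Q coordinates
#'
#' Residuals (y - fitted)/sigma conditional on the supplied (fitted or true)
#' random effects, with theoretical normal quantiles for a Q-Q plot of the
#' kind used to diagnose heavy-tailed albumin errors.
#'
#' @param data a \code{jm_data} object.
#' @param params longitudinal parameters (\code{beta}, \code{sigma}).
#' @param effects_per_subject named list (by subject id) of effects lists,
#'   or a 2-column matrix with rownames; entries default to zero effects.
#' @param covariate_names columns of \code{data$survival} entering the fixed
#'   effects, in the order of \code{params$beta[-(1:2)]}.
#' @return list with \code{residuals} (data.frame subject_id, time, value,
#'   fitted, residual) and \code{qq} (data.frame theoretical_q, sample_q).
#' @export
conditional_residuals <- function(data, params, effects_per_subject = NULL,
                                  covariate_names = character()) {
  stopifnot(inherits(data, "jm_data"))
  long <- data$longitudinal
  sv <- data$survival
  idx <- match(long$subject_id, sv$subject_id)
  X <- if (length(covariate_names))
    as.matrix(sv[idx, covariate_names, drop = FALSE]) else
    matrix(0, nrow(long), 0)
  get_b <- function(id) {
    if (is.null(effects_per_subject)) return(c(0, 0))
    e <- effects_per_subject[[id]]
    if (is.null(e)) c(0, 0) else if (is.list(e)) e$b else as.numeric(e)
  }
  bmat <- t(vapply(long$subject_id, get_b, numeric(2)))
  cc <- if (ncol(X)) drop(X %*% params$beta[-(1:2)]) else 0
  fitted <- (params$beta[[1]] + bmat[, 1]) +
    (params$beta[[2]] + bmat[, 2]) * long$time + cc
  res <- (long$value - fitted) / params$sigma
  n <- length(res)
  qq <- data.frame(theoretical_q = stats::qnorm(stats::ppoints(n)),
                   sample_q = sort(res))
  list(residuals = data.frame(subject_id = long$subject_id, time = long$time,
                              value = long$value, fitted = fitted,
                              residual = res),
       qq = qq)
}

#' Posterior outlier-inflation summaries from the mixing weights
#'
#' For the Student-t variants the posterior mean of 1/w is an outlier
#' inflation factor: values well above 1 flag b-outliers (subject level) or
#' e-outliers (observation level, mod3 variants).
#'
#' @param fit a \code{jm_fit} from a t variant.
#' @return list with \code{subjects} (subject_id, b_inflation, rank;
#'   \code{NULL} when the variant has normal random effects) and
#'   \code{observations} (subject_id, time, e_inflation, rank; per
#'   observation for mod3, per subject otherwise).
#' @export
outlier_weight_summary <- function(fit) {
  stopifnot(inherits(fit, "jm_fit"))
  st <- variant_structure(fit$spec$variant)
  if (!st$b_t && !st$e_t)
    stop("outlier weights are only defined for the Student-t variants, not '",
         fit$spec$variant, "'")
  out <- list(subjects = NULL, observations = NULL)
  if (st$b_t) {
    d <- data.frame(subject_id = fit$subject_ids,
                    b_inflation = fit$w_inflation$b)
    d <- d[order(-d$b_inflation), ]
    d$rank <- seq_len(nrow(d))
    rownames(d) <- NULL
    out$subjects <- d
  }
  if (st$e_t) {
    if (st$e_level == "obs") {
      d <- data.frame(subject_id = fit$model_data$long$subject_id,
                      time = fit$model_data$long$time,
                      e_inflation = fit$w_inflation$e)
    } else {
      d <- data.frame(subject_id = fit$subject_ids, time = NA_real_,
                      e_inflation = fit$w_inflation$e)
    }
    d <- d[order(-d$e_inflation), ]
    d$rank <- seq_len(nrow(d))
    rownames(d) <- NULL
    out$observations <- d
  }
  out
}
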