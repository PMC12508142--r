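#' Cause-specific Weibull parameters
#'
#' Baseline hazard h0(t) = shape * rate * t^(shape-1), cumulative
#' H0(t) = rate * t^shape. The full hazard multiplies h0 by
#' exp(zeta' w + alpha * (m(t) - m_ref)): proportional hazards in the
#' baseline covariates and a current-value association with the biomarker.
#' \code{m_ref} is a fixed centering constant (g/L); it rescales
#' \code{rate} without changing hazard ratios.
#'
#' @param shape Weibull shape k > 0.
#' @param rate Weibull rate lambda > 0 (H0(t) = rate * t^shape).
#' @param zeta named numeric vector of log-hazard coefficients.
#' @param alpha association coefficient per g/L of current biomarker value;
#'   the hazard ratio per 1 g/L biomarker decrease is exp(-alpha).
#' @param m_ref biomarker centering constant (default 0 = uncentered).
#' @export
cause_params <- function(shape, rate, zeta = numeric(), alpha = 0, m_ref = 0) {
  stopifnot(shape > 0, rate > 0, is.finite(alpha))
  list(shape = shape, rate = rate, zeta = zeta, alpha = alpha, m_ref = m_ref)
}

#' Cause-specific hazard at time t
#'
#' @param cp a [cause_params()] list.
#' @param t time(s), strictly positive.
#' @param covariates named/ordered numeric vector matching \code{cp$zeta}.
#' @param m_t current biomarker value(s) m(t), g/L (scalar or same length
#'   as t).
#' @return hazard rate(s), 1/years.
#' @export
weib_hazard <- function(cp, t, covariates = numeric(), m_t = 0) {
  if (any(t <= 0)) stop("hazard requires t > 0")
  eta <- if (length(cp$zeta)) sum(cp$zeta * covariates) else 0
  cp$shape * cp$rate * t^(cp$shape - 1) *
    exp(eta + cp$alpha * (m_t - cp$m_ref))
}

gl_rule <- function(order) {
  if (order < 2) stop("quadrature order must be >= 2")
  pracma::gaussLegendre(order, 0, 1)
}

#' Cumulative cause-specific hazard by Gauss-Legendre quadrature
#'
#' H(t) = integral of the hazard on [0, t]. With a current-value link the
#' integrand involves the subject's biomarker trajectory, so no closed form
#' exists for alpha != 0; a fixed-order Gauss-Legendre rule is used (15
#' points by default, the convention in joint-model software).
#'
#' @inheritParams weib_hazard
#' @param long_params,effects,long_covariates trajectory inputs for
#'   [trajectory_value()]; may be omitted when \code{alpha = 0}.
#' @param order quadrature order (>= 2).
#' @return H(t), dimensionless; 0 at t = 0.
#' @export
cumulative_hazard <- function(cp, t, covariates = numeric(),
                              long_params = NULL, effects = NULL,
                              long_covariates = numeric(), order = 15) {
  rule <- gl_rule(order)
  if (cp$alpha == 0) {
    # no biomarker dependence: H has the closed Weibull form
    if (any(t < 0)) stop("t must be >= 0")
    eta <- if (length(cp$zeta)) sum(cp$zeta * covariates) else 0
    return(cp$rate * exp(eta) * t^cp$shape)
  }
  vapply(t, function(tt) {
    if (tt < 0) stop("t must be >= 0")
    if (tt == 0) return(0)
    u <- tt * rule$x
    m_u <- if (cp$alpha != 0) {
      if (is.null(long_params)) stop("alpha != 0 requires trajectory inputs")
      trajectory_value(long_params, effects %||% list(b = c(0, 0)),
                       long_covariates, u)
    } else 0
    sum(tt * rule$w * weib_hazard(cp, u, covariates, m_u))
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Survival log-likelihood contribution of one subject
#'
#' A subject censored at T contributes -sum_k H_k(T); a subject with event
#' of cause k contributes log h_k(T) - sum_k H_k(T). In single-cause mode
#' (competing risks ignored) the competing event codes 2 and 3 contribute
#' the censoring term only.
#'
#' @param all_cause_params named list of [cause_params()]; names
#'   \code{death}, \code{hd}, \code{ktx} in competing-risks mode, a single
#'   element otherwise.
#' @param event_time,event_code the subject's follow-up time and cause code
#'   (0 censored, 1 death, 2 HD, 3 KTx).
#' @param covariates_by_cause named list of covariate vectors, one per
#'   cause (a single vector is recycled).
#' @param competing_risks logical; if \code{FALSE} only the first cause is
#'   modelled and codes 2/3 are censoring.
#' @inheritParams cumulative_hazard
#' @export
survival_loglik <- function(all_cause_params, event_time, event_code,
                            covariates_by_cause = list(numeric()),
                            long_params = NULL, effects = NULL,
                            long_covariates = numeric(),
                            competing_risks = FALSE, order = 15) {
  if (!event_code %in% 0:3) stop("unknown event code: ", event_code)
  causes <- if (competing_risks) seq_along(all_cause_params) else 1L
  if (!is.list(covariates_by_cause[[1]]) && !is.null(names(covariates_by_cause)) &&
      all(vapply(covariates_by_cause, is.numeric, TRUE))) {
    # already a list of numeric vectors
  }
  covs <- function(k) {
    if (length(covariates_by_cause) >= k) covariates_by_cause[[k]]
    else covariates_by_cause[[1]]
  }
  ll <- 0
  for (k in causes) {
    cp <- all_cause_params[[k]]
    ll <- ll - cumulative_hazard(cp, event_time, covs(k), long_params,
                                 effects, long_covariates, order)
  }
  cause_idx <- if (competing_risks) {
    if (event_code == 0) 0L else match(c("death", "hd", "ktx")[event_code],
                                       names(all_cause_params))
  } else {
    if (event_code == 1) 1L else 0L
  }
  if (!is.na(cause_idx) && cause_idx > 0L) {
    cp <- all_cause_params[[cause_idx]]
    m_T <- if (cp$alpha != 0)
      trajectory_value(long_params, effects %||% list(b = c(0, 0)),
                       long_covariates, event_time) else 0
    ll <- ll + log(weib_hazard(cp, event_time, covs(cause_idx), m_T))
  }
  ll
}

#' Cause-specific cumulative incidence functions
#'
#' CIF_k(t) = integral_0^t h_k(u) S(u) du with S the overall (all-cause)
#' survival; computed by nested Gauss-Legendre quadrature. The CIFs and
#' overall survival partition probability: sum_k CIF_k(t) + S(t) = 1.
#'
#' @inheritParams survival_loglik
#' @param t evaluation time(s) >= 0.
#' @param order_outer quadrature order for the outer integral.
#' @return data.frame with one row per t: \code{time}, \code{surv}, and one
#'   \code{cif_<cause>} column per cause.
#' @export
cause_specific_cif <- function(all_cause_params, t,
                               covariates_by_cause = list(numeric()),
                               long_params = NULL, effects = NULL,
                               long_covariates = numeric(),
                               order = 15, order_outer = 30) {
  K <- length(all_cause_params)
  covs <- function(k) {
    if (length(covariates_by_cause) >= k) covariates_by_cause[[k]]
    else covariates_by_cause[[1]]
  }
  H_tot <- function(u) {
    Reduce(`+`, lapply(seq_len(K), function(k)
      cumulative_hazard(all_cause_params[[k]], u, covs(k), long_params,
                        effects, long_covariates, order)))
  }
  rule <- gl_rule(order_outer)
  res <- t(vapply(t, function(tt) {
    if (tt < 0) stop("t must be >= 0")
    if (tt == 0) return(c(1, rep(0, K)))
    u <- tt * rule$x
    S_u <- exp(-H_tot(u))
    cifs <- vapply(seq_len(K), function(k) {
      cp <- all_cause_params[[k]]
      m_u <- if (cp$alpha != 0)
        trajectory_value(long_params, effects %||% list(b = c(0, 0)),
                         long_covariates, u) else 0
      sum(tt * rule$w * weib_hazard(cp, u, covs(k), m_u) * S_u)
    }, numeric(1))
    c(exp(-H_tot(tt)), cifs)
  }, numeric(K + 1)))
  out <- data.frame(time = t, surv = res[, 1])
  nm <- names(all_cause_params) %||% paste0("cause", seq_len(K))
  if (is.null(names(all_cause_params))) nm <- paste0("cause", seq_len(K))
  for (k in seq_len(K)) out[[paste0("cif_", nm[k])]] <- res[, k + 1]
  out
}
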