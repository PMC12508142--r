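split_rhat <- function(x_by_chain) {
  # x_by_chain: iterations x chains matrix
  n <- nrow(x_by_chain)
  half <- floor(n / 2)
  sub <- cbind(x_by_chain[seq_len(half), , drop = FALSE],
               x_by_chain[half + seq_len(half), , drop = FALSE])
  m <- ncol(sub)
  mns <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  B <- half * stats::var(mns)
  Wv <- mean(vars)
  if (Wv <= 0) return(1)
  sqrt(((half - 1) / half * Wv + B / half) / Wv)
}

ess_basic <- function(x_by_chain) {
  n <- nrow(x_by_chain); m <- ncol(x_by_chain)
  vars <- apply(x_by_chain, 2, stats::var)
  Wv <- mean(vars)
  if (Wv <= 0) return(n * m)
  lag_max <- min(n - 2, 200)
  rho_ch <- sapply(seq_len(m), function(j)
    stats::acf(x_by_chain[, j], lag.max = lag_max, plot = FALSE,
               demean = TRUE)$acf[-1])
  rho <- rowMeans(matrix(rho_ch, nrow = lag_max))
  # Geyer initial positive sequence on paired sums
  s <- 0
  for (t in seq(1, lag_max - 1, by = 2)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
  }
  max(m, min(n * m, n * m / (1 + 2 * s)))
}

#' Fit a joint model by blocked Metropolis-within-Gibbs sampling
#'
#' Estimates any of the twelve model variants. The Gamma scale-mixture
#' representation of the Student-t gives exact Gibbs updates for the mixing
#' weights, the random-effects covariance and the residual variance; fixed
#' and random effects are proposed from their longitudinal-conditional
#' Gaussians and accepted with the survival likelihood ratio; the Weibull,
#' association and degrees-of-freedom blocks use adaptive random-walk
#' Metropolis tuned during warmup. The biomarker is centred at the training
#' mean inside the hazard (stored as \code{m_ref}), a reparameterization
#' that leaves hazard ratios unchanged.
#'
#' @param spec a [jm_model_spec()].
#' @param data a \code{jm_data} training dataset.
#' @return A \code{jm_fit} object with elements \code{draws} (one list per
#'   chain), \code{diagnostics} (split R-hat and effective sample size per
#'   scalar parameter), \code{ll_points} (pointwise draw-by-subject
#'   log-likelihood, the WAIC input), \code{w_inflation} (posterior mean
#'   1/w outlier inflation factors), \code{m_ref}, and the model data.
#' @export
jm_fit <- function(spec, data) {
  stopifnot(inherits(spec, "jm_model_spec"), inherits(data, "jm_data"))
  ctrl <- spec$control
  if (ctrl$chains < 1) stop("need at least one chain")
  md <- make_model_data(spec, data)
  for (k in seq_len(md$K)) {
    if (!any(md$cause_of == k))
      stop("no subjects with events of cause '", spec$causes[k],
           "'; cannot estimate its hazard")
  }
  chains <- lapply(seq_len(ctrl$chains), function(ch) {
    run_jm_chain(md, spec,
                 chain_seed = (ctrl$seed * 7L + ch * 1013L) %% 2147483647L,
                 warmup = ctrl$warmup, iter = ctrl$iter)
  })

  # assemble scalar draws for diagnostics
  scalar_mats <- function(ch) {
    d <- ch$draws
    out <- cbind(d$beta, sigma = d$sigma, d$Sigma,
                 d$df[, colSums(!is.na(d$df)) > 0, drop = FALSE])
    for (k in seq_along(d$surv)) {
      m <- d$surv[[k]]
      colnames(m) <- paste0(spec$causes[k], ".", colnames(m))
      out <- cbind(out, m)
    }
    out
  }
  mats <- lapply(chains, scalar_mats)
  pn <- colnames(mats[[1]])
  diag_df <- data.frame(
    parameter = pn,
    rhat = vapply(seq_along(pn), function(j) {
      split_rhat(sapply(mats, function(m) m[, j]))
    }, numeric(1)),
    ess = vapply(seq_along(pn), function(j) {
      ess_basic(sapply(mats, function(m) m[, j]))
    }, numeric(1)))
  if (any(diag_df$rhat > 1.01, na.rm = TRUE))
    warning("some parameters have split R-hat > 1.01; ",
            "consider longer chains", call. = FALSE)

  S <- ctrl$iter
  fit <- structure(list(
    spec = spec, m_ref = md$m_ref,
    subject_ids = md$ids,
    model_data = md,
    chains = chains,
    scalars = do.call(rbind, mats),
    chain_id = rep(seq_len(ctrl$chains), each = S),
    ll_points = do.call(rbind, lapply(chains, function(ch) ch$draws$ll)),
    b_draws = do.call(abind1, lapply(chains, function(ch) ch$draws$b)),
    w_inflation = list(
      b = Reduce(`+`, lapply(chains, function(ch) ch$inv_wb)) / length(chains),
      e = Reduce(`+`, lapply(chains, function(ch) ch$inv_we)) / length(chains)),
    accept = rowMeans(sapply(chains, function(ch) ch$accept)),
    diagnostics = diag_df), class = "jm_fit")
  fit
}

abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1], 1L)),
                           d[2], d[3]))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' @export
print.jm_fit <- function(x, ...) {
  cat("Joint model fit: ", x$spec$variant,
      if (x$spec$competing_risks) "-cr" else "", "\n", sep = "")
  cat("  ", length(x$chains), " chain(s) x ", x$spec$control$iter,
      " retained iterations; ", length(x$subject_ids), " subjects\n", sep = "")
  cat("  max split R-hat: ", round(max(x$diagnostics$rhat), 3),
      "; min ESS: ", round(min(x$diagnostics$ess)), "\n", sep = "")
  invisible(x)
}

#' Posterior summary of a fitted joint model
#' @param object a \code{jm_fit}
#' @param probs interval probabilities
#' @param ... unused
#' @export
summary.jm_fit <- function(object, probs = c(0.025, 0.975), ...) {
  m <- object$scalars
  data.frame(parameter = colnames(m),
             mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             lo = apply(m, 2, stats::quantile, probs[1]),
             hi = apply(m, 2, stats::quantile, probs[2]),
             row.names = NULL)
}

# extract one parameter draw as lists usable by the prediction code
get_draw <- function(fit, j) {
  d1 <- fit$chains[[1]]$draws
  S <- nrow(d1$beta)
  ch <- (j - 1) %/% S + 1
  i <- (j - 1) %% S + 1
  d <- fit$chains[[ch]]$draws
  st <- variant_structure(fit$spec$variant)
  lp <- list(beta = d$beta[i, ],
             Sigma = matrix(c(d$Sigma[i, 1], d$Sigma[i, 3],
                              d$Sigma[i, 3], d$Sigma[i, 2]), 2, 2),
             sigma = d$sigma[i])
  if (st$shared) lp$gamma_df <- d$df[i, 3]
  if (st$b_t && !st$shared) lp$phi <- d$df[i, 1]
  if (st$e_t && !st$shared) lp$delta <- d$df[i, 2]
  sp <- lapply(seq_along(fit$spec$causes), function(k) {
    th <- d$surv[[k]][i, ]
    q <- length(th) - 3L
    list(logk = th[[1]], loglam = th[[2]],
         zeta = if (q) th[2 + seq_len(q)] else numeric(),
         alpha = th[[length(th)]])
  })
  names(sp) <- fit$spec$causes
  list(long = lp, surv = sp)
}

n_draws <- function(fit) nrow(fit$scalars)

#' Widely applicable information criterion
#'
#' WAIC = -2 (lppd - p_waic), with lppd the sum over subjects of the log of
#' the posterior-mean likelihood and p_waic the sum of pointwise posterior
#' variances of the log-likelihood. The pointwise unit is the subject: each
#' subject's longitudinal and survival contributions, conditional on that
#' subject's sampled random effects and mixing weights. Smaller is better;
#' differences of at least 5 points are conventionally considered
#' important.
#'
#' @param fit a \code{jm_fit} (or a draw-by-subject log-likelihood matrix).
#' @return list with \code{waic}, \code{lppd}, \code{p_waic}.
#' @export
waic <- function(fit) {
  ll <- if (inherits(fit, "jm_fit")) fit$ll_points else as.matrix(fit)
  if (nrow(ll) < 2) stop("need at least 2 posterior draws for WAIC")
  if (!all(is.finite(ll))) stop("non-finite pointwise log-likelihood")
  S <- nrow(ll)
  mx <- apply(ll, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(ll, 2, mx)))))
  p_waic <- sum(apply(ll, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

#' Hazard-ratio table from a fitted joint model
#'
#' Reports, per cause, the hazard ratio per 1 g/L \emph{decrease} of the
#' biomarker, exp(-alpha), and per-unit hazard ratios exp(zeta) for the
#' baseline covariates, with central 95\% credible intervals from the draw
#' quantiles.
#'
#' @param fit a \code{jm_fit}.
#' @return data.frame with columns cause, term, hr, lo95, hi95.
#' @export
hr_table <- function(fit) {
  stopifnot(inherits(fit, "jm_fit"))
  rows <- list()
  for (k in seq_along(fit$spec$causes)) {
    cz <- fit$spec$causes[k]
    m <- do.call(rbind, lapply(fit$chains, function(ch) ch$draws$surv[[k]]))
    alpha <- m[, ncol(m)]
    hr <- exp(-alpha)
    rows[[length(rows) + 1]] <- data.frame(
      cause = cz, term = "biomarker (per 1 g/L decrease)",
      hr = mean(hr), lo95 = stats::quantile(hr, 0.025),
      hi95 = stats::quantile(hr, 0.975))
    for (cn in fit$spec$survival_covariates[[cz]]) {
      zz <- exp(m[, paste0("zeta_", cn)])
      rows[[length(rows) + 1]] <- data.frame(
        cause = cz, term = cn, hr = mean(zz),
        lo95 = stats::quantile(zz, 0.025), hi95 = stats::quantile(zz, 0.975))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
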