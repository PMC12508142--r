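#' @keywords internal
JM_VARIANTS <- c("nor-nor", "t-t-mod1", "t-t-mod2", "nor-t-mod2",
                 "t-t-mod3", "nor-t-mod3")

variant_structure <- function(variant) {
  # b_t: random effects heavy-tailed; e_t: residuals heavy-tailed;
  # e_level: how residual mixing weights are shared within a subject
  switch(variant,
    "nor-nor"    = list(b_t = FALSE, e_t = FALSE, e_level = "none",    shared = FALSE),
    "t-t-mod1"   = list(b_t = TRUE,  e_t = TRUE,  e_level = "subject", shared = TRUE),
    "t-t-mod2"   = list(b_t = TRUE,  e_t = TRUE,  e_level = "subject", shared = FALSE),
    "nor-t-mod2" = list(b_t = FALSE, e_t = TRUE,  e_level = "subject", shared = FALSE),
    "t-t-mod3"   = list(b_t = TRUE,  e_t = TRUE,  e_level = "obs",     shared = FALSE),
    "nor-t-mod3" = list(b_t = FALSE, e_t = TRUE,  e_level = "obs",     shared = FALSE),
    stop("unknown variant '", variant, "'")
  )
}

#' Default priors for the joint model
#'
#' Weakly-informative defaults on the biomarker (g/L) and hazard scales.
#' Degrees-of-freedom parameters are supported on (2, 100]: below 2 the
#' t distribution has no variance, above 100 it is numerically normal.
#' The prior on df is a shifted Gamma: df = 2 + eta, eta ~ Gamma(shape,
#' rate), giving prior mass to the heavy-tailed region while allowing
#' near-normal fits.
#'
#' @param beta_sd prior SD of the fixed effects, Normal(0, beta_sd^2).
#' @param sigma_a,sigma_b inverse-Gamma prior on the residual variance.
#' @param Sigma_df,Sigma_scale inverse-Wishart prior on the 2x2
#'   random-effects covariance (degrees of freedom and scale matrix).
#' @param df_shape,df_rate shifted-Gamma prior on each degrees-of-freedom
#'   parameter.
#' @param logshape_sd,lograte_sd Normal prior SDs on the log Weibull shape
#'   and log rate.
#' @param zeta_sd,alpha_sd Normal prior SDs on baseline-covariate log-hazard
#'   coefficients and on the association coefficient (per g/L).
#' @return list of prior settings, to be passed to [jm_model_spec()].
#' @export
jm_priors <- function(beta_sd = 100, sigma_a = 0.01, sigma_b = 0.01,
                      Sigma_df = 4, Sigma_scale = diag(c(4, 0.25)),
                      df_shape = 2, df_rate = 0.2,
                      logshape_sd = 1, lograte_sd = 5,
                      zeta_sd = 2.5, alpha_sd = 1) {
  list(beta_sd = beta_sd, sigma_a = sigma_a, sigma_b = sigma_b,
       Sigma_df = Sigma_df, Sigma_scale = Sigma_scale,
       df_shape = df_shape, df_rate = df_rate,
       logshape_sd = logshape_sd, lograte_sd = lograte_sd,
       zeta_sd = zeta_sd, alpha_sd = alpha_sd)
}

#' MCMC control settings
#'
#' @param chains number of chains (>= 2 for split R-hat; a single chain is
#'   allowed but diagnostics then use within-chain halves only).
#' @param warmup,iter warmup (adaptation) and retained iterations per chain.
#' @param seed integer seed; mandatory, fits are deterministic given it.
#' @export
jm_control <- function(chains = 2L, warmup = 500L, iter = 500L, seed = 1L) {
  stopifnot(chains >= 1, warmup >= 50, iter >= 2)
  list(chains = as.integer(chains), warmup = as.integer(warmup),
       iter = as.integer(iter), seed = as.integer(seed))
}

#' Specify one of the twelve joint-model variants
#'
#' The six longitudinal outlier structures, each with or without
#' cause-specific competing-risks survival, enumerate the twelve model
#' variants. \code{"nor-nor"} is the standard joint model (normal random
#' effects and residuals); the t variants replace one or both by Student-t
#' scale mixtures. \code{mod1} ties random effects and residuals to a single
#' degrees-of-freedom parameter gamma; \code{mod2} uses separate phi
#' (subject level) and delta (a common residual weight per subject, making a
#' subject's residuals dependent); \code{mod3} gives every observation its
#' own residual weight.
#'
#' @param variant one of \code{"nor-nor"}, \code{"t-t-mod1"},
#'   \code{"t-t-mod2"}, \code{"nor-t-mod2"}, \code{"t-t-mod3"},
#'   \code{"nor-t-mod3"}.
#' @param competing_risks if \code{TRUE}, death, transfer-to-HD and
#'   transplantation each get their own Weibull cause-specific hazard;
#'   otherwise competing events are treated as censoring.
#' @param longitudinal_covariates names of baseline covariates entering the
#'   biomarker sub-model (besides intercept and time).
#' @param survival_covariates either a character vector (same covariates for
#'   every cause) or a named list with elements \code{death}, \code{hd},
#'   \code{ktx}.
#' @param priors see [jm_priors()].
#' @param control see [jm_control()].
#' @return object of class \code{jm_model_spec}.
#' @export
jm_model_spec <- function(variant = "nor-nor", competing_risks = FALSE,
                          longitudinal_covariates = character(),
                          survival_covariates = character(),
                          priors = jm_priors(), control = jm_control()) {
  variant <- match.arg(variant, JM_VARIANTS)
  causes <- if (competing_risks) c("death", "hd", "ktx") else "death"
  if (!is.list(survival_covariates))
    survival_covariates <- stats::setNames(
      rep(list(as.character(survival_covariates)), length(causes)), causes)
  if (!all(causes %in% names(survival_covariates)))
    stop("survival_covariates must name each cause: ",
         paste(causes, collapse = ", "))
  structure(list(variant = variant,
                 competing_risks = competing_risks,
                 causes = causes,
                 longitudinal_covariates = as.character(longitudinal_covariates),
                 survival_covariates = survival_covariates[causes],
                 link = "current value",
                 priors = priors, control = control),
            class = "jm_model_spec")
}

#' @export
print.jm_model_spec <- function(x, ...) {
  cat("Joint model spec: ", x$variant,
      if (x$competing_risks) "-cr" else "",
      " (link: ", x$link, ")\n", sep = "")
  invisible(x)
}
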