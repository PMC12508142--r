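baseline_biomarker <- function(data) {
  long <- data$longitudinal # sorted by subject, time
  first <- !duplicated(long$subject_id)
  stats::setNames(long$value[first], long$subject_id[first])
}

#' Fit a Cox proportional-hazards comparator
#'
#' The two benchmark models against which the joint model is compared:
#' \code{"baseline"} (Cox-1) uses each subject's first biomarker value as a
#' fixed covariate; \code{"timevarying"} (Cox-2) is the extended Cox model
#' in which the biomarker enters as a time-varying covariate via
#' last-value-carried-forward intervals between measurement times. Both
#' treat competing events as censoring, maximize the partial likelihood
#' with Breslow ties, and use the Breslow baseline hazard for absolute-risk
#' prediction. Fitting is delegated to [survival::coxph()].
#'
#' @param data a \code{jm_data}.
#' @param variant \code{"baseline"} or \code{"timevarying"}.
#' @param covariates baseline risk-factor columns of \code{data$survival}.
#' @param include_biomarker set \code{FALSE} for a covariate-free null
#'   model (its predictions reduce to the marginal Kaplan-Meier risk).
#' @return object of class \code{cox_fit}: the \code{coxph} model, the
#'   Breslow cumulative baseline hazard, and metadata.
#' @export
fit_cox <- function(data, variant = c("baseline", "timevarying"),
                    covariates = character(), include_biomarker = TRUE) {
  stopifnot(inherits(data, "jm_data"))
  variant <- match.arg(variant)
  sv <- data$survival
  if (!any(sv$event_code == 1)) stop("no deaths in dataset")
  terms <- c(if (include_biomarker) "biomarker", covariates)
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  if (variant == "baseline") {
    df <- sv
    df$biomarker <- unname(baseline_biomarker(data)[sv$subject_id])
    df$status <- as.numeric(sv$event_code == 1)
    fml <- stats::as.formula(paste("survival::Surv(event_time, status) ~", rhs))
  } else {
    long <- data$longitudinal
    rows <- lapply(seq_len(nrow(sv)), function(i) {
      id <- sv$subject_id[i]
      li <- long[long$subject_id == id, , drop = FALSE]
      tt <- li$time; vv <- li$value
      Tt <- sv$event_time[i]
      keep <- tt < Tt
      tt <- tt[keep]; vv <- vv[keep]
      if (!length(tt)) return(NULL)
      start <- tt
      stop_ <- c(tt[-1], Tt)
      data.frame(subject_id = id, tstart = start, tstop = stop_,
                 biomarker = vv,
                 status = c(rep(0, length(tt) - 1),
                            as.numeric(sv$event_code[i] == 1)),
                 sv[i, covariates, drop = FALSE], row.names = NULL)
    })
    df <- do.call(rbind, rows)
    fml <- stats::as.formula(paste("survival::Surv(tstart, tstop, status) ~",
                                   rhs))
  }
  model <- survival::coxph(fml, data = df, ties = "breslow")
  if (anyNA(stats::coef(model))) {
    bad <- names(which(is.na(stats::coef(model))))
    warning("constant or collinear covariate(s) ",
            paste(bad, collapse = ", "),
            ": coefficient set to 0 (flat partial likelihood)",
            call. = FALSE)
    model$coefficients[is.na(model$coefficients)] <- 0
  }
  bh <- survival::basehaz(model, centered = FALSE)
  structure(list(model = model, variant = variant,
                 covariate_names = covariates,
                 include_biomarker = include_biomarker,
                 bh = data.frame(time = bh$time, hazard = bh$hazard)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox comparator (", x$variant, " biomarker), Breslow ties\n", sep = "")
  print(stats::coef(x$model))
  invisible(x)
}

bh_eval <- function(bh, t) {
  vapply(t, function(tt) {
    idx <- which(bh$time <= tt)
    if (!length(idx)) 0 else bh$hazard[max(idx)]
  }, numeric(1))
}

#' Conditional death-risk prediction from a Cox comparator
#'
#' P(death in (s, s+u] | alive at s) = 1 - [S0(s+u)/S0(s)]^exp(lp), with
#' S0 the Breslow baseline survival. For the time-varying variant the last
#' biomarker value observed at or before s is carried forward and frozen
#' over the horizon - exactly the LVCF assumption that limits extended Cox
#' prediction.
#'
#' @param cox_fit a [fit_cox()] object.
#' @param newdata a \code{jm_data} with the subjects to predict.
#' @param ids subjects (default: all event-free at s).
#' @param s,u landmark and horizon(s), years.
#' @return data.frame: subject_id, s, u, p_death, model.
#' @export
cox_predict_death <- function(cox_fit, newdata, ids = NULL, s, u) {
  stopifnot(inherits(cox_fit, "cox_fit"), inherits(newdata, "jm_data"))
  sv <- newdata$survival
  if (is.null(ids)) ids <- sv$subject_id[sv$event_time > s]
  if (max(s + u) > max(cox_fit$bh$time))
    warning("prediction horizon beyond the fitted baseline-hazard support; ",
            "extrapolating a flat baseline", call. = FALSE)
  cf <- stats::coef(cox_fit$model)
  long <- newdata$longitudinal
  out <- list()
  for (id in ids) {
    row <- sv[sv$subject_id == id, , drop = FALSE]
    if (row$event_time <= s)
      stop("subject '", id, "' is not event-free at s = ", s)
    x <- numeric(0)
    if (cox_fit$include_biomarker) {
      li <- long[long$subject_id == id, , drop = FALSE]
      bm <- if (cox_fit$variant == "baseline") li$value[1] else {
        sel <- li$time <= s
        if (!any(sel)) stop("subject '", id,
                            "' has no measurement at or before s")
        li$value[max(which(sel))]
      }
      x <- c(biomarker = bm)
    }
    if (length(cox_fit$covariate_names))
      x <- c(x, stats::setNames(as.numeric(row[1, cox_fit$covariate_names]),
                                cox_fit$covariate_names))
    lp <- if (length(cf)) sum(cf * x[names(cf)]) else 0
    dH <- (bh_eval(cox_fit$bh, s + u) - bh_eval(cox_fit$bh, s)) * exp(lp)
    out[[length(out) + 1]] <- data.frame(
      subject_id = id, s = s, u = u, p_death = 1 - exp(-dH),
      model = paste0("cox-", if (cox_fit$variant == "baseline") "1" else "2"))
  }
  do.call(rbind, out)
}
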