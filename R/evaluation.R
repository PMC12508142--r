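# step-function evaluation of a Kaplan-Meier curve, right-continuous;
# left = TRUE gives the left limit G(t-)
km_eval <- function(times, surv, t, left = FALSE) {
  vapply(t, function(tt) {
    idx <- if (left) which(times < tt) else which(times <= tt)
    if (!length(idx)) 1 else surv[max(idx)]
  }, numeric(1))
}

censor_km <- function(event_time, is_censor) {
  sf <- survival::survfit(survival::Surv(event_time, is_censor) ~ 1)
  list(times = sf$time, surv = sf$surv)
}

prep_eval <- function(risk_scores, outcomes, s, u, competing) {
  stopifnot(length(risk_scores) == nrow(outcomes))
  if (!all(is.finite(risk_scores))) stop("risk scores must be finite")
  if (any(outcomes$event_time <= s))
    stop("all subjects must be event-free at the landmark s")
  code <- outcomes$event_code
  if (competing == "censor") code[code %in% c(2, 3)] <- 0
  Tt <- outcomes$event_time
  horizon <- s + u
  G <- censor_km(Tt, code == 0)
  cls <- ifelse(Tt > horizon, "control",
         ifelse(code == 1, "case",
         ifelse(code %in% c(2, 3), "competing", "censored")))
  w <- numeric(length(Tt))
  w[cls == "case"] <- 1 / pmax(km_eval(G$times, G$surv, Tt[cls == "case"],
                                       left = TRUE), 1e-10)
  w[cls == "control"] <- 1 / pmax(km_eval(G$times, G$surv, horizon), 1e-10)
  w[cls == "competing"] <- 1 / pmax(km_eval(G$times, G$surv,
                                            Tt[cls == "competing"],
                                            left = TRUE), 1e-10)
  list(cls = cls, w = w, p = risk_scores,
       counts = c(n_at_risk = length(Tt),
                  n_events = sum(cls == "case"),
                  n_competing = sum(cls == "competing"),
                  n_censored = sum(cls == "censored")))
}

metric_row <- function(name, value, s, u, counts) {
  data.frame(s = s, u = u, metric = name, value = value,
             n_at_risk = counts[["n_at_risk"]],
             n_events = counts[["n_events"]],
             n_competing = counts[["n_competing"]],
             n_censored = counts[["n_censored"]])
}

#' Time-dependent AUC with inverse-probability-of-censoring weighting
#'
#' Cumulative/dynamic discrimination at landmark s over horizon u: the
#' IPCW-weighted probability that a subject dying in (s, s+u] received a
#' higher risk score than a subject surviving past s+u (ties count 1/2).
#' Subjects censored inside the window contribute through the weights only;
#' in competing-risks mode subjects with a competing event in the window
#' are, by default, controls for death discrimination (the
#' cumulative-incidence definition of a case), or can be censored instead.
#'
#' @param risk_scores predicted death risks (any monotone score).
#' @param outcomes data.frame with \code{event_time}, \code{event_code}
#'   (0/1/2/3), one row per subject, aligned with \code{risk_scores}; all
#'   subjects must be event-free at s.
#' @param s,u landmark and horizon, years.
#' @param competing \code{"control"} (default) or \code{"censor"}.
#' @return one-row data.frame (metric = "AUC") with window counts; the
#'   value is \code{NA} (with a warning) when the window contains no event
#'   or no survivor.
#' @export
timedep_auc <- function(risk_scores, outcomes, s, u,
                        competing = c("control", "censor")) {
  competing <- match.arg(competing)
  pe <- prep_eval(risk_scores, outcomes, s, u, competing)
  is_case <- pe$cls == "case"
  is_ctrl <- pe$cls %in% c("control", if (competing == "control") "competing")
  if (!any(is_case) || !any(is_ctrl)) {
    warning("AUC undefined: window has no event or no survivor",
            call. = FALSE)
    return(metric_row("AUC", NA_real_, s, u, pe$counts))
  }
  pc <- pe$p[is_case]; wc <- pe$w[is_case]
  pn <- pe$p[is_ctrl]; wn <- pe$w[is_ctrl]
  conc <- outer(pc, pn, ">") + 0.5 * outer(pc, pn, "==")
  val <- sum(outer(wc, wn) * conc) / (sum(wc) * sum(wn))
  metric_row("AUC", val, s, u, pe$counts)
}

#' Brier score with inverse-probability-of-censoring weighting
#'
#' IPCW mean squared difference between the predicted death risk over
#' (s, s+u] and the observed death status at s+u, over the landmark risk
#' set. Without censoring this reduces to the plain mean squared error.
#'
#' @inheritParams timedep_auc
#' @return one-row data.frame (metric = "Brier") with window counts.
#' @export
brier_score <- function(risk_scores, outcomes, s, u,
                        competing = c("control", "censor")) {
  competing <- match.arg(competing)
  pe <- prep_eval(risk_scores, outcomes, s, u, competing)
  D <- as.numeric(pe$cls == "case")
  w <- pe$w
  if (competing == "censor") w[pe$cls == "competing"] <- 0
  w[pe$cls == "censored"] <- 0
  val <- sum(w * (D - pe$p)^2) / length(pe$p)
  metric_row("Brier", val, s, u, pe$counts)
}

#' Decile calibration against Kaplan-Meier
#'
#' Groups subjects by deciles of predicted risk and compares the mean
#' predicted death risk in each group with the observed risk
#' 1 - S_KM(s+u) from a within-group Kaplan-Meier estimate (competing
#' events censored, as in the usual calibration plot).
#'
#' @inheritParams timedep_auc
#' @param groups number of quantile groups (default 10).
#' @return data.frame with columns group, n, mean_predicted, observed.
#' @export
calibration_deciles <- function(risk_scores, outcomes, s, u, groups = 10) {
  stopifnot(length(risk_scores) == nrow(outcomes))
  if (any(outcomes$event_time <= s))
    stop("all subjects must be event-free at the landmark s")
  br <- unique(stats::quantile(risk_scores, seq(0, 1, length.out = groups + 1)))
  if (length(br) < groups + 1)
    warning("tied predicted risks: groups collapsed from ", groups, " to ",
            length(br) - 1, call. = FALSE)
  if (length(br) == 1) br <- c(br - 1e-12, br + 1e-12)
  g <- cut(risk_scores, br, include.lowest = TRUE, labels = FALSE)
  code <- outcomes$event_code
  status <- as.numeric(code == 1) # KM of death, competing censored
  out <- lapply(sort(unique(g)), function(gg) {
    sel <- g == gg
    sf <- survival::survfit(
      survival::Surv(outcomes$event_time[sel], status[sel]) ~ 1)
    obs <- 1 - km_eval(sf$time[sf$n.event > 0 | TRUE], sf$surv, s + u)
    data.frame(group = gg, n = sum(sel),
               mean_predicted = mean(risk_scores[sel]), observed = obs)
  })
  do.call(rbind, out)
}
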