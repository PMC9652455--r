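# Survival statistics used by both evaluation procedures. Kaplan-Meier,
# log-rank and the group hazard ratio delegate to the survival package;
# the cumulative/dynamic time-dependent ROC is computed in-package with
# Kaplan-Meier inverse-probability-of-censoring weights.

#' Kaplan-Meier product-limit estimate
#'
#' Standard tie convention: events precede censorings at identical times.
#' A dataset with no events returns an empty step list (survival is 1
#' everywhere).
#'
#' @param times follow-up times (months).
#' @param events event indicators (1 = event, 0 = censored).
#' @return object of class `km_curve`: list with `times` (distinct event
#'   times), `survival`, `at_risk`, `n_events`, and attribute
#'   `max_followup`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1,
            all(events %in% c(0, 1)))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- sf$n.event > 0
  structure(list(times = sf$time[keep],
                 survival = sf$surv[keep],
                 at_risk = sf$n.risk[keep],
                 n_events = sf$n.event[keep]),
            max_followup = max(times),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Value of the right-continuous step function at `t` (the last step at or
#' before `t`); 1 before the first event. Querying beyond the last
#' follow-up returns the last value with attribute `extrapolated = TRUE`.
#'
#' @param curve a [km_estimate()] result.
#' @param t non-negative time (months).
#' @return survival probability in `[0, 1]`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  idx <- findInterval(t, curve$times)
  val <- if (idx == 0L) 1 else curve$survival[idx]
  if (t > attr(curve, "max_followup")) attr(val, "extrapolated") <- TRUE
  val
}

#' Export per-group Kaplan-Meier curves as a table
#'
#' @param times,events follow-up data.
#' @param group_labels grouping vector.
#' @return data.frame with columns group, time, survival, at_risk, n_events.
#' @export
km_table <- function(times, events, group_labels) {
  do.call(rbind, lapply(sort(unique(as.character(group_labels))), function(g) {
    sel <- group_labels == g
    cv <- km_estimate(times[sel], events[sel])
    if (length(cv$times) == 0L) return(NULL)
    data.frame(group = g, time = cv$times, survival = cv$survival,
               at_risk = cv$at_risk, n_events = cv$n_events)
  }))
}

degenerate_groups <- function(times, events, group_labels) {
  tab <- table(factor(group_labels))
  if (length(tab) != 2L || any(tab == 0L)) return("single_group")
  if (sum(events) < 1) return("no_events")
  NULL
}

#' Two-group log-rank test statistic
#'
#' The standard observed-minus-expected chi-square statistic (1 d.f.) with
#' hypergeometric variance, summed over distinct event times.
#'
#' @param times,events follow-up data.
#' @param group_labels vector with exactly two non-empty groups.
#' @return object of class `logrank_result`: list with `statistic`,
#'   `observed_events`, `expected_events` (named per group).
#' @export
logrank_two_group <- function(times, events, group_labels) {
  reason <- degenerate_groups(times, events, group_labels)
  if (!is.null(reason)) {
    stop("log-rank undefined: ", reason, call. = FALSE)
  }
  g <- factor(group_labels)
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  structure(list(statistic = as.numeric(sd$chisq),
                 observed_events = stats::setNames(as.numeric(sd$obs), levels(g)),
                 expected_events = stats::setNames(as.numeric(sd$exp), levels(g))),
            class = "logrank_result")
}

#' Hazard ratio of the high- vs low-risk group
#'
#' `exp(coef)` from a univariate Cox proportional-hazards model on the
#' high-group indicator (low = reference), so HR > 1 means the high group
#' fares worse. With zero events in one group the partial likelihood is
#' monotone; the estimate is reported as `Inf` (no events in low) or `0`
#' (no events in high) with attribute `monotone = TRUE` instead of a
#' spuriously finite number.
#'
#' @param times,events follow-up data.
#' @param group_labels vector of `"high"` / `"low"` labels.
#' @return positive hazard ratio (possibly `0` or `Inf`, flagged).
#' @export
hazard_ratio_high_vs_low <- function(times, events, group_labels) {
  stopifnot(all(group_labels %in% c("high", "low")))
  if (!all(c("high", "low") %in% group_labels)) {
    stop("both risk groups must be non-empty", call. = FALSE)
  }
  ind <- as.numeric(group_labels == "high")
  ev_high <- sum(events[ind == 1])
  ev_low <- sum(events[ind == 0])
  if (ev_high == 0 || ev_low == 0) {
    hr <- if (ev_high == 0) 0 else Inf
    attr(hr, "monotone") <- TRUE
    return(hr)
  }
  # monotone-likelihood cases are caught above; remaining "coefficient may
  # be infinite" warnings on near-separated folds are expected and silenced
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(times, events) ~ ind, ties = "efron"))
  unname(exp(stats::coef(fit)))
}

# left limit G(t-) of a censoring survival curve
surv_left_limit <- function(fit_times, fit_surv, t) {
  idx <- findInterval(t - 1e-12, fit_times)
  ifelse(idx == 0L, 1, fit_surv[pmax(idx, 1L)])
}

#' Cumulative/dynamic time-dependent ROC for censored outcomes
#'
#' ROC of a risk score at horizon `t`: cases are subjects with an observed
#' event at or before `t`, controls are subjects still under observation
#' beyond `t`. Censoring is handled by inverse-probability-of-censoring
#' weighting with a Kaplan-Meier estimate of the censoring distribution
#' (cases weighted by `1/G(T-)`, controls by `1/G(t)`), which keeps
#' sensitivity and specificity monotone along the threshold sweep. AUC is
#' the trapezoid area under the resulting curve.
#'
#' @param scores numeric risk scores (higher = higher risk).
#' @param times,events follow-up data.
#' @param horizon_months evaluation horizon (default 60 = 5 years).
#' @return object of class `td_roc`: list with `horizon_months`,
#'   `thresholds`, `tpr`, `fpr`, `auc`, `n_cases`, `n_controls`.
#' @export
time_dependent_roc <- function(scores, times, events, horizon_months = 60) {
  stopifnot(length(scores) == length(times), length(times) == length(events))
  is_case <- events == 1 & times <= horizon_months
  is_control <- times > horizon_months
  if (sum(is_case) == 0L) stop("no cases by the horizon", call. = FALSE)
  if (sum(is_control) == 0L) stop("no controls beyond the horizon", call. = FALSE)

  cens_fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  w_case <- 1 / surv_left_limit(cens_fit$time, cens_fit$surv, times[is_case])
  g_horizon <- surv_left_limit(cens_fit$time, cens_fit$surv, horizon_months + 1e-9)
  w_control <- rep(1 / g_horizon, sum(is_control))
  if (any(!is.finite(w_case)) || any(!is.finite(w_control))) {
    stop("censoring weight degenerate at the horizon", call. = FALSE)
  }

  s_case <- scores[is_case]
  s_control <- scores[is_control]
  thresholds <- sort(unique(scores), decreasing = FALSE)
  tpr <- vapply(thresholds, function(c) sum(w_case[s_case > c]) / sum(w_case),
                numeric(1))
  fpr <- vapply(thresholds,
                function(c) sum(w_control[s_control > c]) / sum(w_control),
                numeric(1))
  # sweep from the most permissive classifier (everything positive) down
  tpr <- c(1, tpr); fpr <- c(1, fpr)
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(tpr)]) / 2)
  structure(list(horizon_months = horizon_months,
                 thresholds = c(-Inf, thresholds),
                 tpr = tpr, fpr = fpr, auc = auc,
                 n_cases = sum(is_case), n_controls = sum(is_control)),
            class = "td_roc")
}
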