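# Outcome analysis: median-threshold grouping, Kaplan-Meier with log-rank,
# univariate Cox (Efron ties), IPCW time-dependent ROC/AUC(t), and
# RECIST-style response-rate comparisons.

#' Median-threshold grouping
#'
#' High group = value strictly greater than the cohort median; ties at the
#' median fall in the low group.
#'
#' @param values numeric vector (length >= 2).
#' @return logical vector, TRUE = high group.
#' @export
median_groups <- function(values) {
  stopifnot(length(values) >= 2)
  if (length(unique(values)) < 2)
    stop("all values equal: median grouping would leave one group empty")
  values > stats::median(values)
}

#' Kaplan-Meier curves with log-rank test
#'
#' Product-limit estimator per group, per-group median survival (earliest
#' time with S(t) <= 0.5; `NA` when never reached), and the standard
#' log-rank chi-square test.
#'
#' @param time,event survival times (months) and event indicators (1 =
#'   death).
#' @param group logical or factor group per sample.
#' @param ties passed through for interface symmetry (KM is tie-free).
#' @return list with `curves` (data.frame: group, time, surv, n_risk,
#'   n_event), `median_survival` (named vector), `chisq`, `p_value`.
#' @export
km_logrank <- function(time, event, group, ties = NULL) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (sum(event) == 0) stop("log-rank test undefined: no events")
  group <- as.factor(group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata_names <- sub("^group=", "", names(fit$strata))
  grp <- rep(strata_names, fit$strata)
  curves <- data.frame(group = grp, time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       stringsAsFactors = FALSE)
  med <- vapply(strata_names, function(g) {
    cc <- curves[curves$group == g, ]
    i <- which(cc$surv <= 0.5)
    if (length(i)) cc$time[min(i)] else NA_real_
  }, numeric(1))
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(sd_fit$chisq, df = length(levels(group)) - 1,
                     lower.tail = FALSE)
  list(curves = curves, median_survival = med,
       chisq = unname(sd_fit$chisq), p_value = p)
}

#' Univariate Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling (Breslow via `ties`).
#' With `binary = TRUE` the covariate is first dichotomized at its median
#' ([median_groups()]), matching how biomarkers are compared across
#' cohorts; the continuous fit is available with `binary = FALSE`.
#'
#' @param time,event survival times and event indicators.
#' @param covariate numeric covariate (or logical, used as-is).
#' @param binary dichotomize at the median first (default TRUE).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level Wald confidence level.
#' @return list with `hr`, `ci` (length-2), `p_value`, `beta`, `se`,
#'   `n_events`.
#' @export
cox_univariate <- function(time, event, covariate, binary = TRUE,
                           ties = c("efron", "breslow"), conf_level = 0.95) {
  ties <- match.arg(ties)
  if (sum(event) == 0) stop("Cox fit undefined: no events")
  if (sum(event) < 10) warning("fewer than 10 events; estimates unstable")
  x <- if (is.logical(covariate)) covariate
       else if (binary) median_groups(covariate) else covariate
  fit <- survival::coxph(survival::Surv(time, event) ~ x, ties = ties)
  beta <- unname(stats::coef(fit))
  if (!is.finite(beta)) stop("Cox fit did not converge (non-finite coefficient)")
  se <- sqrt(unname(fit$var[1, 1]))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(hr = exp(beta), ci = exp(beta + c(-1, 1) * zq * se),
       p_value = 2 * stats::pnorm(-abs(beta / se)), beta = beta, se = se,
       n_events = sum(event))
}

#' Time-dependent AUC with inverse-probability-of-censoring weights
#'
#' Cumulative-case / dynamic-control AUC(t): at each grid time t, cases are
#' subjects with an observed event by t, controls those still at risk
#' beyond t; pairs are weighted by the inverse of the Kaplan-Meier estimate
#' of the censoring distribution (at the case's event time and at t,
#' respectively).  Ties in the marker count 1/2.  Without censoring this
#' reduces to the plain pairwise concordance of cases versus controls.
#'
#' @param time,event survival times and event indicators.
#' @param marker numeric marker (higher = higher risk).
#' @param time_grid evaluation times; times beyond the last observed time
#'   are dropped with a warning.
#' @return data.frame with `time`, `auc`, `n_cases`, `n_controls`.
#' @export
time_dependent_auc <- function(time, event, marker, time_grid) {
  stopifnot(length(time) == length(event), length(time) == length(marker))
  beyond <- time_grid > max(time)
  if (any(beyond)) {
    warning("dropping ", sum(beyond), " grid time(s) beyond follow-up")
    time_grid <- time_grid[!beyond]
  }
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  surv_c <- function(t) {
    # left-continuous KM of the censoring distribution, S_C(t-)
    vapply(t, function(tt) {
      i <- which(cens_fit$time < tt)
      if (!length(i)) 1 else cens_fit$surv[max(i)]
    }, numeric(1))
  }
  out <- lapply(time_grid, function(t0) {
    cases <- which(time <= t0 & event == 1)
    controls <- which(time > t0)
    if (!length(cases) || !length(controls))
      return(data.frame(time = t0, auc = NA_real_, n_cases = length(cases),
                        n_controls = length(controls)))
    w_case <- 1 / surv_c(time[cases])
    w_ctrl <- rep(1 / surv_c(t0 + 1e-12), length(controls))
    mi <- marker[cases]
    mj <- marker[controls]
    conc <- outer(mi, mj, function(a, b) (a > b) + 0.5 * (a == b))
    wmat <- outer(w_case, w_ctrl)
    data.frame(time = t0, auc = sum(conc * wmat) / sum(wmat),
               n_cases = length(cases), n_controls = length(controls))
  })
  do.call(rbind, out)
}

#' Responder and objective-responder rates with Fisher tests
#'
#' Responder = CR, PR, or SD lasting at least 6 months; objective responder
#' = CR or PR.  SD records without a duration are excluded from the
#' responder comparison with a warning.  Two-sided Fisher exact test per
#' definition.
#'
#' @param response character vector in CR/PR/SD/PD.
#' @param sd_duration SD duration in months (`NA` for non-SD rows).
#' @param groups logical vector (e.g. CPS-high).
#' @return list with `responder` and `objective` elements, each holding the
#'   2x2 `table` (group x responder), per-group `rates`, and `p_value`.
#' @export
response_rates <- function(response, sd_duration, groups) {
  stopifnot(length(response) == length(groups))
  response <- toupper(response)
  stopifnot(all(response %in% c("CR", "PR", "SD", "PD")))
  objective <- response %in% c("CR", "PR")
  resp <- objective | (response == "SD" & !is.na(sd_duration) & sd_duration >= 6)
  usable <- !(response == "SD" & is.na(sd_duration))
  if (any(!usable))
    warning(sum(!usable), " SD record(s) without duration excluded from ",
            "the responder comparison")
  one <- function(flag, keep) {
    tab <- table(group = factor(groups[keep], levels = c(FALSE, TRUE)),
                 responder = factor(flag[keep], levels = c(FALSE, TRUE)))
    rates <- tab[, "TRUE"] / rowSums(tab)
    list(table = tab, rates = stats::setNames(as.numeric(rates),
                                              c("low", "high")),
         p_value = stats::fisher.test(tab)$p.value)
  }
  list(responder = one(resp, usable),
       objective = one(objective, rep(TRUE, length(groups))))
}
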