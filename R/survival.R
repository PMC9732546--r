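# Time-to-progression endpoints: the event is the tumor reaching a fold of
# its baseline volume (RTV x 2 = doubling, RTV x 4 = quadrupling). The
# product-limit estimate and the Mantel-Cox log-rank test are computed with
# the survival package.

#' Time to an RTV-fold progression event
#'
#' The event time is the first measurement day on which the mouse's RTV
#' reaches `fold` (no interpolation between the weekly measurements). A
#' mouse that never crosses is censored at its last measurement day, which
#' for sacrificed mice is the sacrifice day.
#'
#' @param curve a [growth_curve()].
#' @param fold RTV multiple defining progression, typically 2 or 4.
#' @return one-row data.frame: `mouse_id`, `arm`, `fold`, `time_days`,
#'   `event` (1 = crossed, 0 = censored).
#' @export
event_time <- function(curve, fold) {
  stopifnot(inherits(curve, "growth_curve"), is.numeric(fold), fold > 1)
  ser <- rtv_series(curve)
  hit <- which(ser$rtv >= fold)
  if (length(hit) > 0L) {
    time <- ser$day[hit[1]]; event <- 1L
  } else {
    time <- ser$day[nrow(ser)]; event <- 0L
  }
  data.frame(mouse_id = curve$mouse_id, arm = curve$arm_label,
             fold = fold, time_days = time, event = event)
}

#' RTV-fold event table for a whole study
#'
#' @param study a [pdx_study()] (or a single [study_arm()]).
#' @param folds RTV multiples to evaluate (default `c(2, 4)`).
#' @return data.frame of [event_time()] rows for every mouse and fold.
#' @export
fold_event_table <- function(study, folds = c(2, 4)) {
  arms <- if (inherits(study, "study_arm")) list(study) else study$arms
  curves <- unlist(lapply(arms, `[[`, "curves"), recursive = FALSE)
  do.call(rbind, lapply(folds, function(f)
    do.call(rbind, lapply(curves, event_time, fold = f))))
}

#' Kaplan-Meier product-limit estimate
#'
#' Ties between events and censorings at the same time are resolved with
#' events first, the standard product-limit convention.
#'
#' @param time event/censoring times (days), positive.
#' @param event 1 (or TRUE) = event observed, 0 = censored.
#' @return object of class `km_curve`: data.frame with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (survival probability immediately after
#'   `time`); `S(0) = 1` implicitly.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) pdx_validation_error("no survival records supplied")
  if (length(event) != length(time))
    pdx_validation_error("time and event must have equal length")
  if (any(!is.finite(time) | time <= 0))
    pdx_validation_error("times must be positive")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability of a KM curve at a time point
#'
#' @param km a [km_estimate()] result.
#' @param t time (days).
#' @return `S(t)`, the estimated probability of remaining event-free
#'   through `t`.
#' @export
km_surv_at <- function(km, t) {
  s <- c(1, km$surv)
  brk <- c(-Inf, km$time)
  s[findInterval(t, brk)]
}

#' Mantel-Cox log-rank test for two groups
#'
#' Standard two-group log-rank statistic with the hypergeometric variance
#' and no continuity correction; one degree of freedom, two-sided p from
#' the chi-square distribution.
#'
#' @param time_a,event_a times and event indicators of group A.
#' @param time_b,event_b times and event indicators of group B.
#' @return list of class `pdx_test`: `statistic` (chi-square),
#'   `p_two_sided`, `method = "log-rank"`, `n_per_group`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L)
    pdx_validation_error("both groups must be non-empty")
  event_a <- as.integer(event_a); event_b <- as.integer(event_b)
  if (sum(event_a) + sum(event_b) == 0L) {
    warning("no events in either group; log-rank p set to 1")
    return(structure(list(statistic = 0, p_two_sided = 1, method = "log-rank",
                          n_per_group = c(length(time_a), length(time_b)),
                          test = "Log-rank (Mantel-Cox)"),
                     class = "pdx_test"))
  }
  d <- data.frame(time = c(time_a, time_b),
                  event = c(event_a, event_b),
                  group = rep(c("A", "B"), c(length(time_a), length(time_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d,
                           rho = 0)
  chisq <- unname(sd$chisq)
  structure(list(statistic = chisq,
                 p_two_sided = pchisq(chisq, df = 1, lower.tail = FALSE),
                 method = "log-rank",
                 n_per_group = c(length(time_a), length(time_b)),
                 test = "Log-rank (Mantel-Cox)"),
            class = "pdx_test")
}

#' Log-rank comparison of a treated arm against control on an RTV-fold event
#'
#' @param treated,control [study_arm()] objects.
#' @param fold RTV multiple (2 or 4).
#' @return as [logrank_test()].
#' @export
logrank_fold <- function(treated, control, fold) {
  ta <- fold_event_table(treated, folds = fold)
  tb <- fold_event_table(control, folds = fold)
  logrank_test(ta$time_days, ta$event, tb$time_days, tb$event)
}
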