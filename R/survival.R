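#' Kaplan-Meier product-limit estimator
#'
#' Nonparametric estimate of the survivor function under right censoring:
#' at each distinct event time \eqn{t_i} with \eqn{d_i} events among
#' \eqn{n_i} at risk, \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)}.
#' Ties between events and censorings at the same time are resolved
#' events-before-censorings (a record censored at \eqn{t_i} is still at risk
#' for events at \eqn{t_i}), the standard convention.
#'
#' @param time non-negative follow-up times.
#' @param event event indicators (1 = event observed, 0 = censored).
#' @return data.frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`; a leading row at time 0
#'   carries \eqn{S(0) = 1}.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop_input("need at least one record", "collmot_input_error")
  if (any(time < 0)) stop_input("negative survival times", "collmot_input_error")
  if (!all(event %in% c(0, 1))) stop_input("event must be 0/1", "collmot_input_error")
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- sort(unique(time))
  n <- length(time)
  n_risk <- n_event <- n_censor <- integer(length(ut))
  s <- numeric(length(ut))
  surv <- 1
  at_risk <- n
  for (i in seq_along(ut)) {
    here <- time == ut[i]
    d <- sum(event[here] == 1)
    c_ <- sum(event[here] == 0)
    n_risk[i] <- at_risk
    n_event[i] <- d
    n_censor[i] <- c_
    if (d > 0) surv <- surv * (1 - d / at_risk)
    s[i] <- surv
    at_risk <- at_risk - d - c_
  }
  rbind(
    data.frame(time = 0, n_risk = n, n_event = 0L, n_censor = 0L, survival = 1),
    data.frame(time = ut, n_risk = n_risk, n_event = n_event,
               n_censor = n_censor, survival = s)
  )
}

#' Two-group log-rank test
#'
#' The standard observed-minus-expected formulation: at each distinct event
#' time, the expected events in group 1 are \eqn{e_{1i} = d_i n_{1i}/n_i}
#' with hypergeometric variance
#' \eqn{v_i = d_i (n_{1i}/n_i)(1 - n_{1i}/n_i)(n_i - d_i)/(n_i - 1)}
#' (handling tied events; no continuity correction).  The statistic
#' \eqn{(O_1 - E_1)^2 / V} is referred to a chi-square with 1 degree of
#' freedom.
#'
#' @param time non-negative follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param group two-level group labels.
#' @return list with `statistic`, `df`, `p_value`, `observed` and `expected`
#'   (per group, in level order).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop_input("log-rank test requires exactly 2 non-empty groups", "collmot_input_error")
  }
  group <- droplevels(group)
  if (any(time < 0)) stop_input("negative survival times", "collmot_input_error")
  if (sum(event == 1) < 1) stop_input("need at least one event", "collmot_input_error")
  g1 <- group == levels(group)[1]
  event_times <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in event_times) {
    at <- time >= t
    n_i <- sum(at)
    n1_i <- sum(at & g1)
    d_i <- sum(time == t & event == 1)
    d1_i <- sum(time == t & event == 1 & g1)
    o1 <- o1 + d1_i
    e1 <- e1 + d_i * n1_i / n_i
    if (n_i > 1) {
      v <- v + d_i * (n1_i / n_i) * (1 - n1_i / n_i) * (n_i - d_i) / (n_i - 1)
    }
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  total_events <- sum(event == 1)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = c(o1, total_events - o1),
       expected = c(e1, total_events - e1))
}

#' Kaplan-Meier curves per group, as one tidy table
#'
#' @param time,event,group as in [logrank_test()].
#' @return data.frame of per-group [km_estimate()] tables with a `group`
#'   column.
#' @export
km_by_group <- function(time, event, group) {
  parts <- lapply(split(seq_along(time), group), function(idx) {
    km <- km_estimate(time[idx], event[idx])
    km$group <- group[idx[1]]
    km
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
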