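## Pre-fit admissibility checks and descriptive survival: Kaplan-Meier
## curves (via survival::survfit), the nonparametric cured-fraction
## estimate (KM terminal value), and the Maller-Zhou style sufficient
## follow-up statistic q_n.

#' Kaplan-Meier product-limit curve
#'
#' Wraps [survival::survfit()] to compute the product-limit estimator
#' \eqn{\hat S(t) = \prod_{t_j \le t} (1 - d_j / n_j)}. Ties are grouped;
#' censored observations tied with an event time remain at risk through that
#' event (the standard convention).
#'
#' @param records Survival records (see [validate_records()]).
#' @return An object of class `km_curve`: list with `times` (event times),
#'   `survival` (step values), `n_risk`, `n_event`, `plateau_start` (largest
#'   event time, 0 when there are no events) and `max_time` (largest
#'   observed time).
#' @examples
#' kaplan_meier(data.frame(time = 1:4, event = 1, age = 50))
#' @export
kaplan_meier <- function(records) {
  records <- validate_records(records)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  ev <- sf$n.event > 0
  structure(list(
    times = sf$time[ev],
    survival = sf$surv[ev],
    n_risk = sf$n.risk[ev],
    n_event = sf$n.event[ev],
    plateau_start = if (any(ev)) max(sf$time[ev]) else 0,
    max_time = max(records$time),
    n = nrow(records)
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event time(s), max follow-up %.3g\n",
              x$n, length(x$times), x$max_time))
  cat(sprintf("terminal survival %.4f; last event at %.3g\n",
              km_terminal(x), x$plateau_start))
  invisible(x)
}

#' Plot a Kaplan-Meier curve
#'
#' Step-function plot of the product-limit estimate.
#'
#' @param x A `km_curve` object.
#' @param add Add to an existing plot.
#' @param ... Further graphical parameters (e.g. `col`, `lty`).
#' @return Invisibly, `x`.
#' @export
plot.km_curve <- function(x, add = FALSE, ...) {
  tt <- c(0, x$times, x$max_time)
  ss <- c(1, x$survival, km_terminal(x))
  if (add) {
    graphics::lines(tt, ss, type = "s", ...)
  } else {
    graphics::plot(tt, ss, type = "s", ylim = c(0, 1),
                   xlab = "Time (years)", ylab = "Survival probability", ...)
  }
  invisible(x)
}

km_terminal <- function(curve) {
  if (length(curve$survival)) curve$survival[length(curve$survival)] else 1
}

#' Nonparametric cured-fraction estimate
#'
#' The Kaplan-Meier estimate evaluated at the largest observed time. Under
#' sufficient follow-up the KM plateau level is a consistent estimate of the
#' cured proportion.
#'
#' @param records Survival records.
#' @return A probability in \[0, 1\].
#' @export
cured_fraction_np <- function(records) {
  km_terminal(kaplan_meier(records))
}

#' Sufficient follow-up statistic
#'
#' With \eqn{t_{max}} the largest observed time and \eqn{t^*_{max}} the
#' largest uncensored time, counts the uncensored times in the interval
#' \eqn{(2 t^*_{max} - t_{max},\ t^*_{max}]} and reports the fraction
#' \eqn{q_n = N_n / n}. A clearly positive \eqn{q_n} indicates that events
#' were still accruing close to the end of observed event activity relative
#' to total follow-up, supporting the sufficient-follow-up assumption; the
#' statistic is 0 when there are no events or when the very last observation
#' is itself an event.
#'
#' @param records Survival records.
#' @param threshold Flag level: `sufficient` is `FALSE` when `q_n` falls
#'   below it (default 0.05). No formal p-value is computed.
#' @return A list with `q_n`, `N_n`, `interval` (the half-open window),
#'   `n`, and `sufficient`.
#' @export
sufficient_followup <- function(records, threshold = 0.05) {
  records <- validate_records(records)
  n <- nrow(records)
  ev_times <- records$time[records$event == 1]
  t_max <- max(records$time)
  if (!length(ev_times)) {
    return(list(q_n = 0, N_n = 0L, interval = c(NA_real_, NA_real_), n = n,
                sufficient = FALSE))
  }
  t_star <- max(ev_times)
  lo <- 2 * t_star - t_max
  N_n <- sum(ev_times > lo & ev_times <= t_star)
  if (t_star >= t_max) N_n <- 0L  # window (t_max, t_max] is empty
  q_n <- N_n / n
  list(q_n = q_n, N_n = as.integer(N_n), interval = c(lo, t_star), n = n,
       sufficient = q_n >= threshold)
}

#' Plateau summary of a Kaplan-Meier curve
#'
#' Length and level of the terminal flat stretch of the curve: the time from
#' the last observed event to the end of follow-up, and the survival value
#' there. A long plateau at a clearly positive level is the visual evidence
#' for a cured fraction.
#'
#' @param curve A `km_curve` object.
#' @return A list with `plateau_length` (years) and `plateau_level`
#'   (probability).
#' @export
plateau_summary <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  list(plateau_length = curve$max_time - curve$plateau_start,
       plateau_level = km_terminal(curve))
}

#' Kaplan-Meier curves on either side of a cut point
#'
#' Splits records at `age <= tau` / `age > tau` and computes an independent
#' Kaplan-Meier curve per group with the same tie conventions.
#'
#' @param records Survival records.
#' @param tau Cut point in the age covariate.
#' @return A list with components `left` and `right`, each a `km_curve`.
#' @export
km_by_cutpoint <- function(records, tau) {
  records <- validate_records(records)
  sel <- records$age <= tau
  if (!any(sel))
    stop("left group (age <= tau) is empty", call. = FALSE)
  if (all(sel))
    stop("right group (age > tau) is empty", call. = FALSE)
  list(left = kaplan_meier(records[sel, , drop = FALSE]),
       right = kaplan_meier(records[!sel, , drop = FALSE]))
}
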