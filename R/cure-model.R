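#' cpcure: change-point exponential mixture cure models
#'
#' Tools for locating a change point in a continuous covariate (typically age
#' at diagnosis) at which the cure fraction and exponential hazard of a
#' mixture cure model switch between two regimes, from right-censored
#' survival data.
#'
#' The population survival in each covariate segment is the two-component
#' mixture \eqn{S(t) = p + (1-p) e^{-\lambda t}}: a proportion \eqn{p} of
#' subjects is cured (immune to the event) and the remainder are susceptible
#' with exponential event times. The full model has five parameters: the
#' change point \eqn{\tau} and a \eqn{(p, \lambda)} pair on each side.
#'
#' @keywords internal
"_PACKAGE"

## ---- domain types -------------------------------------------------------

#' Per-segment mixture cure parameters
#'
#' A cure fraction and an exponential hazard for the susceptible
#' sub-population of one covariate segment.
#'
#' @param cure_p Cure fraction, a probability in \[0, 1\]: the proportion of
#'   subjects immune to the event.
#' @param hazard_lambda Exponential hazard (1/years) of event times among
#'   susceptible (non-cured) subjects; must be positive.
#' @return An object of class `segment_params`.
#' @examples
#' segment_params(0.65, 0.16)
#' @export
segment_params <- function(cure_p, hazard_lambda) {
  if (!is.numeric(cure_p) || length(cure_p) != 1L || is.na(cure_p) ||
      cure_p < 0 || cure_p > 1)
    stop("'cure_p' must be a single probability in [0, 1]", call. = FALSE)
  if (!is.numeric(hazard_lambda) || length(hazard_lambda) != 1L ||
      is.na(hazard_lambda) || hazard_lambda <= 0 || !is.finite(hazard_lambda))
    stop("'hazard_lambda' must be a single positive finite number",
         call. = FALSE)
  structure(list(cure_p = as.numeric(cure_p),
                 hazard_lambda = as.numeric(hazard_lambda)),
            class = "segment_params")
}

#' Full change-point cure model parameters
#'
#' The five-parameter model: a change point in the covariate plus one
#' [segment_params()] pair on each side. The left segment applies to
#' subjects with covariate value at or below `tau` (closed-left rule),
#' the right segment to values strictly above `tau`.
#'
#' @param tau Change point, in covariate units (years of age); finite.
#' @param left,right [segment_params()] for the `age <= tau` and
#'   `age > tau` segments respectively.
#' @return An object of class `cp_cure_params`.
#' @examples
#' cp_cure_params(50.46, segment_params(0.65, 0.16), segment_params(0.31, 0.13))
#' @export
cp_cure_params <- function(tau, left, right) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau))
    stop("'tau' must be a single finite number", call. = FALSE)
  if (!inherits(left, "segment_params") || !inherits(right, "segment_params"))
    stop("'left' and 'right' must be segment_params objects", call. = FALSE)
  structure(list(tau = as.numeric(tau), left = left, right = right),
            class = "cp_cure_params")
}

#' @export
print.segment_params <- function(x, ...) {
  cat(sprintf("Mixture cure segment: cure fraction p = %.4g, hazard = %.4g /yr\n",
              x$cure_p, x$hazard_lambda))
  invisible(x)
}

#' @export
print.cp_cure_params <- function(x, ...) {
  cat(sprintf("Change-point cure model (tau = %.4g)\n", x$tau))
  cat(sprintf("  age <= tau: p = %.4g, lambda = %.4g\n",
              x$left$cure_p, x$left$hazard_lambda))
  cat(sprintf("  age >  tau: p = %.4g, lambda = %.4g\n",
              x$right$cure_p, x$right$hazard_lambda))
  invisible(x)
}

## records are a plain data.frame(time, event, age); validated once at the
## boundary so the likelihood loops stay branch-free.

#' Validate right-censored survival records
#'
#' Checks a data frame of survival records: `time` non-negative follow-up in
#' years, `event` indicator (1 = event, 0 = right-censored), `age` finite
#' covariate value in years.
#'
#' @param records Data frame with numeric columns `time`, `event`, `age`.
#' @param allow_empty Accept a zero-row data frame (default `FALSE`).
#' @return The validated data frame, invisibly coerced to numeric columns.
#' @export
validate_records <- function(records, allow_empty = FALSE) {
  if (!is.data.frame(records))
    stop("records must be a data.frame", call. = FALSE)
  need <- c("time", "event", "age")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(records) == 0L) {
    if (allow_empty) return(records)
    stop("records must contain at least one row", call. = FALSE)
  }
  t <- as.numeric(records$time); d <- as.numeric(records$event)
  a <- as.numeric(records$age)
  if (anyNA(t) || any(t < 0))
    stop("all times must be non-negative and non-missing", call. = FALSE)
  if (anyNA(d) || !all(d %in% c(0, 1)))
    stop("event indicator must be 0 (censored) or 1 (event)", call. = FALSE)
  if (anyNA(a) || any(!is.finite(a)))
    stop("all ages must be finite and non-missing", call. = FALSE)
  records$time <- t; records$event <- d; records$age <- a
  records
}

## ---- model mathematics --------------------------------------------------

#' Population survival of the mixture cure model
#'
#' \eqn{S(t) = p + (1-p) e^{-\lambda t}}: everyone is alive at entry
#' (\eqn{S(0) = 1}) and the cured proportion survives indefinitely
#' (\eqn{S(\infty) = p}).
#'
#' @param t Non-negative time(s), years.
#' @param params A [segment_params()] object.
#' @return Survival probabilities in `[p, 1]`, same length as `t`.
#' @examples
#' population_survival(c(0, 5, 50), segment_params(0.31, 0.13))
#' @export
population_survival <- function(t, params) {
  stopifnot(inherits(params, "segment_params"))
  t <- as.numeric(t)
  if (anyNA(t) || any(t < 0))
    stop("'t' must be non-negative", call. = FALSE)
  params$cure_p + (1 - params$cure_p) * exp(-params$hazard_lambda * t)
}

#' Population (improper) event-time density
#'
#' \eqn{f(t) = (1-p)\,\lambda\, e^{-\lambda t}}, the negative derivative of
#' [population_survival()]. It is improper: it integrates to the susceptible
#' mass \eqn{1-p}, not to 1.
#'
#' @inheritParams population_survival
#' @return Non-negative densities, same length as `t`.
#' @export
population_density <- function(t, params) {
  stopifnot(inherits(params, "segment_params"))
  t <- as.numeric(t)
  if (anyNA(t) || any(t < 0))
    stop("'t' must be non-negative", call. = FALSE)
  (1 - params$cure_p) * params$hazard_lambda * exp(-params$hazard_lambda * t)
}

## per-record log-likelihood terms under one segment's parameters;
## delta = 1 -> log f(t), delta = 0 -> log S(t).  p = 1 with an event gives
## log(0) = -Inf by design (sentinel, not an error) so optimizers can retreat.
loglik_terms <- function(time, event, params) {
  p <- params$cure_p; lam <- params$hazard_lambda
  e <- exp(-lam * time)
  out <- numeric(length(time))
  ev <- event == 1
  out[ev] <- suppressWarnings(log1p(-p) + log(lam)) - lam * time[ev]
  out[!ev] <- log(p + (1 - p) * e[!ev])
  out
}

#' Censored-data log-likelihood of one segment
#'
#' Sum over records of \eqn{\delta_i \log f(t_i) + (1-\delta_i)\log S(t_i)}
#' under a single segment's mixture cure parameters. When `cure_p` is 1 and
#' any record is an event the value is `-Inf` (log of a zero density); this
#' is returned, not raised, so numerical optimizers can penalize it.
#'
#' @param records Survival records (see [validate_records()]).
#' @param params A [segment_params()] object.
#' @return A single numeric log-likelihood.
#' @export
segment_loglik <- function(records, params) {
  records <- validate_records(records)
  stopifnot(inherits(params, "segment_params"))
  sum(loglik_terms(records$time, records$event, params))
}

#' Two-segment change-point log-likelihood
#'
#' Partitions records at the change point (`age <= tau` vs `age > tau`) and
#' sums the two segment log-likelihoods. An empty segment contributes 0.
#'
#' @param records Survival records.
#' @param params A [cp_cure_params()] object.
#' @return A single numeric log-likelihood.
#' @export
change_point_loglik <- function(records, params) {
  records <- validate_records(records)
  stopifnot(inherits(params, "cp_cure_params"))
  left <- records$age <= params$tau
  ll <- 0
  if (any(left))
    ll <- ll + sum(loglik_terms(records$time[left], records$event[left],
                                params$left))
  if (any(!left))
    ll <- ll + sum(loglik_terms(records$time[!left], records$event[!left],
                                params$right))
  ll
}

#' Kernel-smoothed change-point log-likelihood
#'
#' Replaces the hard indicator `age <= tau` by the standard normal CDF weight
#' \eqn{w_i = \Phi((\tau - x_i)/h)} and returns
#' \eqn{\sum_i w_i \ell_i(\mathrm{left}) + (1-w_i)\ell_i(\mathrm{right})},
#' where \eqn{\ell_i} is record i's log-likelihood term under the given
#' segment parameters. As `bandwidth` shrinks to 0 this converges to
#' [change_point_loglik()] for every record with `age != tau`; a record at
#' exactly `tau` always gets weight 1/2.
#'
#' Smoothing makes the objective differentiable in `tau`, which is what
#' permits joint numerical maximization over all five parameters.
#'
#' @inheritParams change_point_loglik
#' @param bandwidth Positive kernel bandwidth `h`, in covariate units.
#' @return A single numeric log-likelihood.
#' @export
smoothed_loglik <- function(records, params, bandwidth) {
  records <- validate_records(records)
  stopifnot(inherits(params, "cp_cure_params"))
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
      is.na(bandwidth) || bandwidth <= 0)
    stop("'bandwidth' must be a single positive number", call. = FALSE)
  w <- stats::pnorm((params$tau - records$age) / bandwidth)
  ll_l <- loglik_terms(records$time, records$event, params$left)
  ll_r <- loglik_terms(records$time, records$event, params$right)
  ## 0 * -Inf would poison the sum; a zero weight means the term is absent
  s <- function(w, l) sum(ifelse(w == 0, 0, w * l))
  s(w, ll_l) + s(1 - w, ll_r)
}
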