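## Maximum-likelihood fitting: per-segment MLE on the transformed scale,
## profile search over the change point, optional smoothed joint refinement,
## and nonparametric bootstrap confidence intervals.

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

## negative segment log-likelihood in theta = (logit p, log lambda)
seg_negloglik <- function(theta, time, event) {
  p <- expit(theta[1L]); lam <- exp(theta[2L])
  -sum(loglik_terms(time, event, segment_params_unsafe(p, lam)))
}

## same objective with the event terms pre-aggregated: the event part is
## d*log((1-p)*lambda) - lambda*sum(t_events); only censored records need
## per-record work inside the optimizer loop.
seg_negloglik_fast <- function(theta, d, sum_tev, t_cens) {
  p <- expit(theta[1L]); lam <- exp(theta[2L])
  ll <- d * (log1p(-p) + theta[2L]) - lam * sum_tev
  if (length(t_cens))
    ll <- ll + sum(log(p + (1 - p) * exp(-lam * t_cens)))
  -ll
}

## Kaplan-Meier terminal value without the survfit machinery, for starting
## values inside profile scans; events precede tied censorings.
km_terminal_fast <- function(time, event) {
  o <- order(time, -event)
  d <- event[o]
  n <- length(d)
  at_risk <- n - seq_len(n) + 1
  prod(1 - d / at_risk)
}

## constructor without validation, for optimizer inner loops
segment_params_unsafe <- function(p, lam) {
  structure(list(cure_p = p, hazard_lambda = lam), class = "segment_params")
}

#' Maximum-likelihood fit of one segment's cure parameters
#'
#' Maximizes [segment_loglik()] over \eqn{(p, \lambda)} by derivative-free
#' local search (Nelder-Mead) on the transformed scale
#' \eqn{(\mathrm{logit}\,p, \log\lambda)}, from several starting points.
#' The data-driven start uses the Kaplan-Meier value at the largest observed
#' time for \eqn{p_0} and the reciprocal mean of uncensored times for
#' \eqn{\lambda_0}.
#'
#' @param records Survival records containing at least one event.
#' @param extra_starts Optional list of additional `c(p, lambda)` starting
#'   values (used internally to warm-start profile scans).
#' @param min_records Below this many records the fit is flagged as
#'   small-sample (default 10).
#' @param reltol Convergence tolerance on the objective (default `1e-8`).
#' @param data_starts Use the three default starting points in addition to
#'   `extra_starts` (internal; `FALSE` keeps only the data-driven start).
#' @return A list with elements `params` ([segment_params()]), `loglik`,
#'   `converged`, `small_sample`, and `theta` (the transformed optimum).
#' @export
fit_segment_mle <- function(records, extra_starts = NULL, min_records = 10L,
                            reltol = 1e-8, data_starts = TRUE) {
  records <- validate_records(records)
  time <- records$time; event <- records$event
  d <- sum(event)
  if (d == 0)
    stop("no events in segment: cure fraction is unidentifiable", call. = FALSE)

  p0 <- km_terminal_fast(time, event)
  p0 <- min(max(p0, 0.02), 0.98)
  tev <- time[event == 1]
  mt <- mean(tev)
  lam0 <- if (mt > 0) 1 / mt else 1
  starts <- c(list(c(p0, lam0)),
              if (data_starts) list(c(0.2, 2 * lam0),
                                    c(0.8, max(lam0 / 2, 1e-3))),
              extra_starts)

  t_cens <- time[event == 0]
  best <- NULL
  for (s in starts) {
    th0 <- c(logit(min(max(s[1L], 1e-4), 1 - 1e-4)), log(max(s[2L], 1e-8)))
    fit <- stats::optim(th0, seg_negloglik_fast, d = d, sum_tev = sum(tev),
                        t_cens = t_cens, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = 1000L))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  theta <- best$par
  list(params = segment_params(expit(theta[1L]), exp(theta[2L])),
       loglik = -best$value,
       converged = best$convergence == 0L,
       small_sample = nrow(records) < min_records,
       theta = theta)
}

## Wald 95% CI for (p, lambda) from the numerical observed information on the
## transformed scale, mapped back; NULL when the hessian is not usable.
segment_wald_ci <- function(records, theta) {
  h <- try(stats::optimHess(theta, seg_negloglik,
                            time = records$time, event = records$event),
           silent = TRUE)
  if (inherits(h, "try-error")) return(NULL)
  v <- try(solve(h), silent = TRUE)
  if (inherits(v, "try-error") || any(diag(v) <= 0)) return(NULL)
  se <- sqrt(diag(v)); z <- stats::qnorm(0.975)
  rbind(cure_p = expit(theta[1L] + c(-1, 1) * z * se[1L]),
        hazard_lambda = exp(theta[2L] + c(-1, 1) * z * se[2L]))
}

#' Profile maximum-likelihood estimation of the change-point cure model
#'
#' For each candidate change point (the unique observed covariate values
#' inside a quantile band, subject to a minimum number of events on each
#' side), the two segments `age <= tau` and `age > tau` are fitted
#' independently by [fit_segment_mle()]; the candidate with the largest
#' summed log-likelihood is the profile estimate. Optionally the solution is
#' refined by a joint five-parameter maximization of the kernel-smoothed
#' log-likelihood started from the profile optimum.
#'
#' @param records Survival records with at least two distinct ages.
#' @param q_bounds Quantile band of ages searched for candidates
#'   (default `c(0.10, 0.90)`).
#' @param min_events_side Minimum number of events each candidate must leave
#'   on both sides (default 5).
#' @param smooth If `TRUE`, refine the profile solution by maximizing
#'   [smoothed_loglik()] jointly over all five parameters.
#' @param bandwidth Kernel bandwidth for the smoothed refinement; default
#'   `sd(age) / sqrt(n)`.
#' @param min_records Small-sample flag threshold per segment, passed to
#'   [fit_segment_mle()].
#' @param reltol Optimizer tolerance.
#' @return An object of class `cpcure_fit`: a list with `params`
#'   ([cp_cure_params()] point estimates), `loglik` (hard change-point
#'   log-likelihood at the estimate), `profile` (data frame of candidate
#'   `tau` and profiled log-likelihood), `n_left`, `n_right`, `converged`,
#'   `wald` (secondary Wald intervals for the per-segment parameters),
#'   `smoothed` (refinement details or `NULL`), and `ci` (filled by
#'   [bootstrap_ci()], else `NULL`).
#' @examples
#' spec <- study_preset()
#' coh <- generate_cohort(spec, seed = 1)
#' fit <- estimate_change_point(coh)
#' fit$params$tau
#' @export
estimate_change_point <- function(records,
                                  q_bounds = c(0.10, 0.90),
                                  min_events_side = 5L,
                                  smooth = FALSE,
                                  bandwidth = NULL,
                                  min_records = 10L,
                                  reltol = 1e-8) {
  records <- validate_records(records)
  ages <- records$age
  if (length(unique(ages)) < 2L)
    stop("all ages identical: change point is undefined", call. = FALSE)

  qs <- stats::quantile(ages, q_bounds, names = FALSE, type = 7)
  cand <- sort(unique(ages))
  cand <- cand[cand >= qs[1L] & cand <= qs[2L]]
  cand <- cand[cand < max(ages)]  # right side must be non-empty
  if (length(cand)) {
    ev_left <- vapply(cand, function(tau) sum(records$event[ages <= tau]), 0)
    ev_right <- sum(records$event) - ev_left
    cand <- cand[ev_left >= min_events_side & ev_right >= min_events_side]
  }
  if (!length(cand))
    stop("insufficient events for change-point search: no admissible ",
         "candidate leaves ", min_events_side, " event(s) on both sides",
         call. = FALSE)

  ## scan: warm-started fits (previous candidate's optimum + data-driven
  ## start) keep the sweep cheap; the winning candidate is re-fitted below
  ## with the full multi-start set.
  prof <- numeric(length(cand))
  best <- NULL
  warm_l <- NULL; warm_r <- NULL
  for (i in seq_along(cand)) {
    tau <- cand[i]
    sel <- ages <= tau
    fl <- fit_segment_mle(records[sel, , drop = FALSE], extra_starts = warm_l,
                          min_records = min_records, reltol = reltol,
                          data_starts = FALSE)
    fr <- fit_segment_mle(records[!sel, , drop = FALSE], extra_starts = warm_r,
                          min_records = min_records, reltol = reltol,
                          data_starts = FALSE)
    warm_l <- list(c(fl$params$cure_p, fl$params$hazard_lambda))
    warm_r <- list(c(fr$params$cure_p, fr$params$hazard_lambda))
    prof[i] <- fl$loglik + fr$loglik
    if (is.null(best) || prof[i] > best$loglik)
      best <- list(tau = tau, i = i, left = fl, right = fr, loglik = prof[i])
  }

  ## full multi-start refit at the profile maximizer
  sel <- ages <= best$tau
  best$left <- fit_segment_mle(
    records[sel, , drop = FALSE],
    extra_starts = list(c(best$left$params$cure_p,
                          best$left$params$hazard_lambda)),
    min_records = min_records, reltol = reltol)
  best$right <- fit_segment_mle(
    records[!sel, , drop = FALSE],
    extra_starts = list(c(best$right$params$cure_p,
                          best$right$params$hazard_lambda)),
    min_records = min_records, reltol = reltol)
  best$loglik <- best$left$loglik + best$right$loglik
  prof[best$i] <- best$loglik

  params <- cp_cure_params(best$tau, best$left$params, best$right$params)
  smoothed <- NULL
  if (smooth) {
    h <- if (is.null(bandwidth)) stats::sd(ages) / sqrt(nrow(records))
         else bandwidth
    th0 <- c(params$tau, best$left$theta, best$right$theta)
    obj <- function(th) {
      pr <- cp_cure_params(th[1L],
                           segment_params_unsafe(expit(th[2L]), exp(th[3L])),
                           segment_params_unsafe(expit(th[4L]), exp(th[5L])))
      -smoothed_loglik(records, pr, h)
    }
    opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                        control = list(reltol = reltol, maxit = 2000L))
    params <- cp_cure_params(opt$par[1L],
                             segment_params(expit(opt$par[2L]), exp(opt$par[3L])),
                             segment_params(expit(opt$par[4L]), exp(opt$par[5L])))
    smoothed <- list(bandwidth = h, objective = -opt$value,
                     start_objective = -obj(th0),
                     converged = opt$convergence == 0L)
  }

  n_left <- sum(ages <= params$tau)
  structure(list(
    params = params,
    loglik = change_point_loglik(records, params),
    profile = data.frame(tau = cand, loglik = prof),
    n_left = n_left,
    n_right = nrow(records) - n_left,
    converged = best$left$converged && best$right$converged &&
      (is.null(smoothed) || smoothed$converged),
    small_sample = best$left$small_sample || best$right$small_sample,
    wald = list(left = segment_wald_ci(records[ages <= best$tau, , drop = FALSE],
                                       best$left$theta),
                right = segment_wald_ci(records[ages > best$tau, , drop = FALSE],
                                        best$right$theta)),
    smoothed = smoothed,
    ci = NULL
  ), class = "cpcure_fit")
}

#' @export
print.cpcure_fit <- function(x, ...) {
  cat("Change-point exponential mixture cure model fit\n")
  est <- fit_estimates(x)
  if (!is.null(x$ci)) {
    est$lower <- x$ci[rownames(x$ci), "lower"]
    est$upper <- x$ci[rownames(x$ci), "upper"]
  }
  print(est, digits = 4)
  cat(sprintf("log-likelihood: %.4f  (n_left = %d, n_right = %d)\n",
              x$loglik, x$n_left, x$n_right))
  if (!x$converged) cat("warning: optimizer did not report convergence\n")
  invisible(x)
}

## point estimates as a named data.frame in Table-layout order
fit_estimates <- function(fit) {
  p <- fit$params
  data.frame(
    parameter = c("tau", "cure_left", "hazard_left", "cure_right",
                  "hazard_right"),
    label = c("Change-point estimate",
              "Cure estimate, age <= tau", "Hazard estimate, age <= tau",
              "Cure estimate, age > tau", "Hazard estimate, age > tau"),
    estimate = c(p$tau, p$left$cure_p, p$left$hazard_lambda,
                 p$right$cure_p, p$right$hazard_lambda),
    stringsAsFactors = FALSE
  )
}

#' Nonparametric bootstrap confidence intervals for the fitted model
#'
#' Case resampling: records are resampled with replacement `B` times,
#' [estimate_change_point()] is rerun on each replicate, and percentile
#' 2.5%/97.5% intervals are formed per parameter. Replicates whose fit
#' fails (for example, too few events on one side after resampling) are
#' dropped and counted; more than 50% failures is an error.
#'
#' Percentile intervals from small `B` need not contain the original point
#' estimate; when one does not, the result carries a `flagged` attribute.
#'
#' @param records Survival records.
#' @param B Number of bootstrap replicates (default 500).
#' @param seed Integer seed controlling the resampling (default 20190920).
#' @param level Confidence level (default 0.95).
#' @param ... Further arguments passed to [estimate_change_point()].
#' @return A matrix with rows `tau`, `cure_left`, `hazard_left`,
#'   `cure_right`, `hazard_right` and columns `lower`, `upper`; attributes
#'   `n_failed` (dropped replicates) and `flagged` (intervals not containing
#'   the point estimate, if any).
#' @export
bootstrap_ci <- function(records, B = 500L, seed = 20190920L, level = 0.95,
                         ...) {
  records <- validate_records(records)
  if (B < 2L) stop("'B' must be at least 2", call. = FALSE)
  fit0 <- estimate_change_point(records, ...)
  est0 <- fit_estimates(fit0)

  set.seed(seed)
  n <- nrow(records)
  draws <- matrix(NA_real_, nrow = B, ncol = 5L)
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- try(estimate_change_point(records[idx, , drop = FALSE], ...),
              silent = TRUE)
    if (inherits(fb, "try-error")) { n_failed <- n_failed + 1L; next }
    draws[b, ] <- fit_estimates(fb)$estimate
  }
  if (n_failed > B / 2)
    stop("bootstrap unstable: ", n_failed, " of ", B,
         " replicates failed to fit", call. = FALSE)
  keep <- stats::complete.cases(draws)
  a <- (1 - level) / 2
  ci <- t(apply(draws[keep, , drop = FALSE], 2L, stats::quantile,
                probs = c(a, 1 - a), names = FALSE))
  dimnames(ci) <- list(est0$parameter, c("lower", "upper"))
  outside <- est0$estimate < ci[, "lower"] | est0$estimate > ci[, "upper"]
  attr(ci, "n_failed") <- n_failed
  attr(ci, "flagged") <- est0$parameter[outside]
  ci
}
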