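# Independent oracles: direct per-record evaluation of the model formulas
# and a hand-rolled product-limit estimator. These deliberately avoid the
# package's internal code paths.

oracle_mix_S <- function(t, p, lam) p + (1 - p) * exp(-lam * t)
oracle_mix_f <- function(t, p, lam) (1 - p) * lam * exp(-lam * t)

# per-record censored-data log-likelihood term
oracle_term <- function(t, d, p, lam) {
  if (d == 1) log(oracle_mix_f(t, p, lam)) else log(oracle_mix_S(t, p, lam))
}

oracle_seg_ll <- function(rec, p, lam) {
  sum(vapply(seq_len(nrow(rec)),
             function(i) oracle_term(rec$time[i], rec$event[i], p, lam), 0))
}

# unpartitioned loop selecting parameters per record
oracle_cp_ll <- function(rec, tau, pl, ll, pr, lr) {
  tot <- 0
  for (i in seq_len(nrow(rec))) {
    if (rec$age[i] <= tau) tot <- tot + oracle_term(rec$time[i], rec$event[i], pl, ll)
    else tot <- tot + oracle_term(rec$time[i], rec$event[i], pr, lr)
  }
  tot
}

oracle_smooth_ll <- function(rec, tau, pl, ll, pr, lr, h) {
  tot <- 0
  for (i in seq_len(nrow(rec))) {
    w <- pnorm((tau - rec$age[i]) / h)
    tot <- tot + w * oracle_term(rec$time[i], rec$event[i], pl, ll) +
      (1 - w) * oracle_term(rec$time[i], rec$event[i], pr, lr)
  }
  tot
}

# hand product-limit estimator; returns survival evaluated just after each
# distinct event time, plus the terminal value at the largest observed time
oracle_km <- function(time, event) {
  o <- order(time, -event)  # events before tied censorings
  time <- time[o]; event <- event[o]
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (j in seq_along(ut)) {
    nj <- sum(time >= ut[j])
    dj <- sum(time == ut[j] & event == 1)
    s <- s * (1 - dj / nj)
    surv[j] <- s
  }
  list(times = ut, survival = surv, terminal = s)
}

# per-segment MLE by coarse grid search followed by local refinement, used
# to cross-check the package optimizer via an independent route
oracle_seg_mle <- function(rec) {
  pg <- seq(0.02, 0.98, length.out = 25)
  lg <- exp(seq(log(0.005), log(5), length.out = 25))
  best <- c(NA, NA); bestll <- -Inf
  for (p in pg) for (lam in lg) {
    ll <- sum(ifelse(rec$event == 1,
                     log((1 - p) * lam) - lam * rec$time,
                     log(p + (1 - p) * exp(-lam * rec$time))))
    if (ll > bestll) { bestll <- ll; best <- c(p, lam) }
  }
  nll <- function(th) {
    p <- 1 / (1 + exp(-th[1])); lam <- exp(th[2])
    -sum(ifelse(rec$event == 1,
                log((1 - p) * lam) - lam * rec$time,
                log(p + (1 - p) * exp(-lam * rec$time))))
  }
  op <- optim(c(log(best[1] / (1 - best[1])), log(best[2])), nll,
              method = "Nelder-Mead",
              control = list(reltol = 1e-10, maxit = 2000))
  list(p = 1 / (1 + exp(-op$par[1])), lam = exp(op$par[2]),
       loglik = -op$value)
}

# exhaustive change-point scan over every unique age, mirroring the
# estimator's admissibility rule (right side non-empty, minimum events per
# side) but fitting each side by the independent grid-refined MLE
oracle_cp_scan <- function(rec, min_events = 1L) {
  cand <- sort(unique(rec$age))
  cand <- cand[cand < max(rec$age)]
  best <- NULL
  for (tau in cand) {
    sel <- rec$age <= tau
    if (sum(rec$event[sel]) < min_events ||
        sum(rec$event[!sel]) < min_events) next
    fl <- oracle_seg_mle(rec[sel, , drop = FALSE])
    fr <- oracle_seg_mle(rec[!sel, , drop = FALSE])
    ll <- fl$loglik + fr$loglik
    if (is.null(best) || ll > best$loglik)
      best <- list(tau = tau, loglik = ll)
  }
  best
}

# small simulated dataset with a genuine change-point cure structure
make_cp_data <- function(n, tau = 50, pl = 0.7, laml = 0.5, pr = 0.2,
                         lamr = 0.5, age_range = c(30, 70), cens_max = 15,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  age <- runif(n, age_range[1], age_range[2])
  p <- ifelse(age <= tau, pl, pr)
  lam <- ifelse(age <= tau, laml, lamr)
  cured <- runif(n) < p
  latent <- ifelse(cured, Inf, rexp(n) / lam)
  cens <- runif(n, 0, cens_max)
  data.frame(time = pmin(latent, cens),
             event = as.numeric(latent <= cens),
             age = age)
}
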