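# Shared simulation study: cohorts drawn from the study preset, fitted by
# the profile estimator. Computed once and reused by the recovery tests.

.study_cache <- new.env(parent = emptyenv())

study_fits <- function(n_rep = 200L) {
  key <- paste0("fits", n_rep)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  spec <- study_preset()
  res <- t(vapply(seq_len(n_rep), function(i) {
    fit <- estimate_change_point(generate_cohort(spec, seed = i))
    c(tau = fit$params$tau,
      cure_left = fit$params$left$cure_p,
      hazard_left = fit$params$left$hazard_lambda,
      cure_right = fit$params$right$cure_p,
      hazard_right = fit$params$right$hazard_lambda)
  }, numeric(5)))
  .study_cache[[key]] <- res
  res
}
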