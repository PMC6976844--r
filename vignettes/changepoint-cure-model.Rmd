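---
title: "Change-point mixture cure models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Change-point mixture cure models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpcure)
```

## The model

`cpcure` fits a mixture cure model whose parameters switch at an unknown
change point in a continuous covariate. Within one covariate segment the
population survival is

$$S(t) = p + (1 - p)\, e^{-\lambda t},$$

a mixture of a cured fraction $p$ (immune to the event, survival 1 forever)
and susceptibles with exponential event times at hazard $\lambda$ per year.
The improper density is $f(t) = (1-p)\lambda e^{-\lambda t}$, integrating to
the susceptible mass $1-p$. The full model attaches one $(p, \lambda)$ pair
to each side of a change point $\tau$ in the covariate $x$ (age at
diagnosis, years): subjects with $x \le \tau$ follow the left segment,
subjects with $x > \tau$ the right one.

For right-censored records $(t_i, \delta_i, x_i)$ the log-likelihood is the
usual censored-data sum $\sum_i \delta_i \log f(t_i) +
(1-\delta_i)\log S(t_i)$, with segment parameters selected per record by
the indicator $x_i \le \tau$. Because the indicator makes the likelihood a
step function of $\tau$, only the observed covariate values can change its
value, and the change point is estimated by a *profile* search: for each
candidate $\tau$ (the unique observed ages), the two segments are fitted
independently, and the candidate with the largest summed log-likelihood
wins.

### Tie rule

The left segment is *closed*: $x \le \tau$. Where a boundary subject falls
is genuinely ambiguous in this model class; we fix the closed-left
convention once, use it identically in the likelihood, the fitted group
labels ("age &le; &tau;" / "age &gt; &tau;") and the group-wise
Kaplan-Meier split, and document it rather than offering a switch.

### Smoothed likelihood

The hard indicator can be replaced by the standard normal CDF weight
$w_i = \Phi((\tau - x_i)/h)$, giving the differentiable objective
$\sum_i w_i \ell_i(\text{left}) + (1-w_i)\,\ell_i(\text{right})$. As
$h \to 0$ this converges to the hard likelihood at every $x_i \ne \tau$; a
record exactly at $\tau$ always receives weight $\tfrac12$. The default
bandwidth is $h = \mathrm{sd}(x)\, n^{-1/2}$, which shrinks with the sample
so the smoothed objective tracks the hard one ever more closely while
remaining smooth enough for joint optimization. `estimate_change_point()`
can use this surface to refine all five parameters jointly from the profile
solution (`smooth = TRUE`); the refinement is **off by default** because
the profile solution already attains the hard-likelihood maximum over the
candidate set, and keeping it as the reported estimate preserves the exact
identity between the reported log-likelihood and
`change_point_loglik()` at the reported parameters.

## Estimation choices

* **Scale.** Each segment is maximized over $(\operatorname{logit} p,
  \log\lambda)$, so the optimizer is unconstrained while $p \in [0,1]$ and
  $\lambda > 0$ hold by construction.
* **Optimizer.** Derivative-free Nelder-Mead with relative tolerance
  $10^{-8}$ on the objective, from three starting points: a data-driven one
  ($p_0$ = Kaplan-Meier value at the largest observed time, $\lambda_0$ =
  reciprocal mean uncensored time) plus two dispersed ones. During the
  profile sweep each candidate is warm-started from its neighbour's
  optimum (plus the data-driven start), and the winning candidate is
  re-fitted with the full multi-start set; the sweep and the final refit
  agree with an exhaustive brute-force scan in the test suite.
* **Candidate grid.** Unique observed ages within the 10%–90% age
  quantiles, each required to leave at least 5 events on both sides
  (defaults; both configurable). This prevents boundary candidates whose
  segment likelihood is degenerate — a segment without events cannot
  identify $p$ at all, which is also why `fit_segment_mle()` refuses
  all-censored input.
* **Degenerate values.** $p = 1$ with an observed event gives a $\log 0$
  term; the likelihood returns $-\infty$ rather than raising, so optimizers
  can penalize and retreat.
* **Confidence intervals.** Nonparametric case-resampling percentile
  bootstrap (default $B = 500$), rerunning the whole profile fit per
  replicate; the change-point likelihood is non-regular, so Wald theory is
  not trusted for $\tau$. Replicates that fail to fit are dropped and
  counted, and more than 50% failures aborts. Wald intervals from the
  numerical observed information are still reported for the per-segment
  $(p, \lambda)$ as a cheap secondary check. Percentile intervals at small
  $B$ need not contain the point estimate; such intervals are flagged, not
  "fixed".

## Diagnostics

Two assumptions should be checked before interpreting any cure-model fit:

1. **A cured fraction exists.** The Kaplan-Meier curve should end in a
   plateau at a positive level; `plateau_summary()` reports the length of
   the terminal event-free stretch and its level, and
   `cured_fraction_np()` (the KM value at the largest observed time) is the
   nonparametric cure-fraction estimate.
2. **Follow-up is long enough** for that plateau to mean cure rather than
   truncation. With $t_{\max}$ the largest observed time and $t^*_{\max}$
   the largest *uncensored* time, `sufficient_followup()` counts the
   uncensored times in $(2t^*_{\max} - t_{\max},\, t^*_{\max}]$ and reports
   $q_n = N_n / n$. If events were still accruing right up to the end of
   follow-up ($t^*_{\max} = t_{\max}$), $q_n = 0$ and the plateau is not
   trustworthy. No formal reference distribution is computed — the
   statistic is reported with a configurable flag threshold (default
   $q_n < 0.05$), which is all the downstream `run_fit()` pipeline needs to
   warn (or, with `--strict`, refuse to fit).

Kaplan-Meier estimation itself is delegated to `survival::survfit()` with
the standard convention that censorings tied with an event time remain at
risk through that event; the test suite cross-checks it against a
hand-rolled product-limit computation.

## The synthetic-cohort generator

The registry data motivating this model class is not publicly deposited, so
the package ships a generator whose **defaults are the study conditions**:
`study_preset()` returns 345 subjects, age truncated-normal with mean 56.51
and SD 11.52 years on [20, 90], change point 50.46 years, left segment
(cure 0.65, hazard 0.16/yr), right segment (cure 0.31, hazard 0.13/yr), and
a 25-year follow-up horizon. Choices the summaries do not pin down were
fixed once:

* **Age distribution.** A truncated normal matching the reported mean/SD;
  [20, 90] years is a plausible adult diagnosis range. Under these values
  about 70% of subjects fall above the change point, so the older group
  predominates, as expected for this disease.
* **Censoring.** Entry staggered uniformly over a fixed study window with a
  single closing date is equivalent to administrative censoring times
  $U(0, 25)$ years. Administrative censoring alone cannot reach the
  reported 73% censored fraction given these hazards (it floors near 57%),
  so an independent exponential dropout (loss to follow-up) is added and
  its rate **calibrated** by `calibrate_dropout_rate()`: bisection on the
  rate, each probe a 20,000-subject simulation under common random numbers
  (which makes the simulated censored fraction monotone in the rate),
  until the target is matched within ±0.01. For the preset this yields
  ≈ 0.109/yr.
* **Truth sidecar.** Each generated cohort carries its latent truth (cure
  status, latent event and censoring times, segment) as an attribute used
  only by tests — estimation never reads it.

What the generator does *not* emulate: covariates other than age (sex,
family history), measurement error in survival times, cohort-entry trends,
or any dependence between age and censoring. Passing recovery tests
therefore show that the estimator works *when the model is true under
realistic sample size and censoring*, not that the model fits any
particular registry.

## Validation design and problem sizes

The test suite works at three levels:

* **Analytic identities** — $S(0) = 1$, $\int f = 1 - p$ (adaptive
  quadrature, $10^{-6}$), the censored-exponential closed form at $p = 0$,
  smoothed → hard likelihood as $h \to 0$ — and frozen values computed by
  independent term-by-term evaluation.
* **Oracle equivalence** — the profile estimator must match an exhaustive
  scan over every unique age with an independent grid-refined per-segment
  MLE (20 datasets of n = 60), and the segment MLE must beat a 200×200
  $(p, \lambda)$ grid on an n = 2,000 cohort.
* **Monte-Carlo recovery** — 200 preset cohorts of n = 345: the medians of
  $(\hat\tau, \hat p_1, \hat\lambda_1, \hat p_2, \hat\lambda_2)$ must land
  within ±3 years, ±0.10, and ±0.05 of the generating values respectively,
  and 50 cohorts must reproduce the mean age within ±1.5 years and the
  censored fraction within ±5 points. These replicate counts keep the full
  suite around five minutes on one CPU while leaving the Monte-Carlo error
  of a median (≈ 0.25 years for $\hat\tau$) far below the tolerances; a
  reduced bootstrap-coverage smoke test (8 cohorts, $B = 25$) checks for
  gross interval miscalibration only.

## Known limitations

* One change point, one covariate; no covariate link on the cure fraction.
* Exponential susceptible survival only — with heavier-tailed true
  survival the hazard estimates absorb the misfit.
* Single-cohort intervals at n ≈ 345 with ~73% censoring are wide,
  especially for the left-segment parameters (only ~20 events); this is a
  property of the design, not the optimizer.
* $q_n$ is reported without a p-value; treat the flag as a screen, not a
  test.
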