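# cpcure

Change-point exponential mixture cure models for right-censored survival
data.

## The problem

In oncology, long-term follow-up of patients often shows a survival curve
that flattens out at a positive level: a fraction of patients is effectively
cured and will never experience the event (death from the disease or
recurrence). The mixture cure model describes this as a two-component
population,

    S(t) = p + (1 - p) * exp(-lambda * t),

where `p` is the cure fraction and the susceptible (non-cured) patients have
exponential event times with hazard `lambda` (per year). `S(0) = 1` and
`S(inf) = p`: the cured proportion is the plateau of the survival curve.

When prognosis shifts at some unknown value of a continuous covariate —
here, age at diagnosis — both `p` and `lambda` may switch between two
regimes at a change point `tau`. `cpcure` estimates all five parameters
`(tau, p1, lambda1, p2, lambda2)` from right-censored records
`(time, event, age)` by maximum likelihood. The censored-data likelihood
contribution of patient *i* is `f(t_i)^delta_i * S(t_i)^(1-delta_i)`, with
the parameters of the segment their age falls in (`age <= tau` is the
"left"/younger segment). The change point is found by a profile search over
the observed ages; an optional kernel-smoothed likelihood (normal CDF
weights replacing the hard age indicator) allows joint five-parameter
refinement. Confidence intervals come from a nonparametric case-resampling
bootstrap.

The package also provides the admissibility diagnostics that should precede
any cure-model fit — Kaplan-Meier plateau evidence of a cured fraction and
a sufficient-follow-up statistic `q_n` — and a calibrated synthetic-cohort
generator for simulation studies, since the motivating registry cohort
(n = 345 colorectal-cancer patients, ~73% censored, 25-year horizon) is not
publicly available.

## Worked example

```r
library(cpcure)

spec <- study_preset()        # calibrated study-like simulation conditions
print(spec)
#> Cohort spec: n = 345, age ~ TN(56.51, 11.52) on [20, 90]
#>   tau = 50.46; left (p = 0.65, lambda = 0.16); right (p = 0.31, lambda = 0.13)
#>   censoring: admin U(0, 25) + dropout rate 0.1094 /yr

cohort <- generate_cohort(spec, seed = 42)
mean(cohort$event == 0)       # 0.736 censored

kaplan_meier(cohort)
#> Kaplan-Meier curve: n = 345, 91 event time(s), max follow-up 20.9
#> terminal survival 0.4924; last event at 12.1

fit <- estimate_change_point(cohort)
fit$ci <- bootstrap_ci(cohort, B = 200, seed = 42)
print(fit)
#> Change-point exponential mixture cure model fit
#>      parameter                       label estimate     lower   upper
#> 1          tau       Change-point estimate  51.0218 4.497e+01 66.1075
#> 2    cure_left   Cure estimate, age <= tau   0.7979 4.029e-07  0.9107
#> 3  hazard_left Hazard estimate, age <= tau   0.2385 1.661e-02  0.9727
#> 4   cure_right    Cure estimate, age > tau   0.3195 4.125e-08  0.4425
#> 5 hazard_right  Hazard estimate, age > tau   0.1369 9.222e-02  0.2256
#> log-likelihood: -337.5353  (n_left = 110, n_right = 235)
```

The fitted change point (51.0 years) sits close to the generating value of
50.46; patients diagnosed at or below it have a much larger estimated cure
fraction (0.80) than older patients (0.32). The KM plateau at 0.49 from
year 12 onward is the nonparametric evidence of a cured fraction, and the
wide bootstrap intervals at n = 345 show how hard the cure/hazard split is
to pin down in a single cohort of this size — which is why the package's
validation works with medians over many replicate cohorts.

A command-line interface wrapping the same functions is installed at
`inst/cli/cpcure`:

```sh
Rscript inst/cli/cpcure simulate --out cohort.csv --seed 1
Rscript inst/cli/cpcure fit --in cohort.csv --out results --bootstrap 200
Rscript inst/cli/cpcure diagnose --in cohort.csv
```

`fit` writes a five-row parameter table (`results.txt`), the same numbers
machine-readably (`results.json`), and overall/by-group Kaplan-Meier plots.

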