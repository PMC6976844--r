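test_that("population survival has the mixture cure shape", {
  left <- segment_params(0.65, 0.16)
  right <- segment_params(0.31, 0.13)

  expect_identical(population_survival(0, left), 1)
  expect_equal(population_survival(1e6, right), 0.31)
  # pure exponential median when nobody is cured
  expect_equal(population_survival(log(2) / 0.4, segment_params(0, 0.4)), 0.5)

  t <- seq(0, 60, by = 0.25)
  s <- population_survival(t, left)
  expect_true(all(diff(s) <= 0))
  expect_true(all(s >= left$cure_p & s <= 1))

  expect_error(population_survival(-1, left), "non-negative")
  expect_error(segment_params(1.2, 1), "probability")
  expect_error(segment_params(0.5, 0), "positive")
})

test_that("population density matches -dS/dt and integrates to 1 - p", {
  expect_equal(population_density(3, segment_params(1, 0.7)), 0)
  expect_equal(population_density(0, segment_params(0, 2)), 2)

  for (par in list(c(0.5, 1), c(0.65, 0.16), c(0, 2.5), c(0.9, 0.05))) {
    sp <- segment_params(par[1], par[2])
    mass <- integrate(population_density, 0, Inf, params = sp,
                      rel.tol = 1e-10)$value
    expect_equal(mass, 1 - par[1], tolerance = 1e-6)
    # numerical derivative of S
    eps <- 1e-6
    expect_equal(-(population_survival(2 + eps, sp) -
                     population_survival(2 - eps, sp)) / (2 * eps),
                 population_density(2, sp), tolerance = 1e-5)
  }
})

test_that("segment log-likelihood matches worked and oracle values", {
  # censored record: S(1) = 0.5 + 0.5 exp(-log 2) = 0.75
  r1 <- data.frame(time = 1, event = 0, age = 40)
  expect_equal(segment_loglik(r1, segment_params(0.5, log(2))), log(0.75))

  # event at the origin: f(0) = (1-p) * lambda
  r2 <- data.frame(time = 0, event = 1, age = 40)
  expect_equal(segment_loglik(r2, segment_params(0.5, 1)), log(0.5))

  # frozen three-record value from independent term-by-term evaluation
  r3 <- data.frame(time = c(2, 1, 3), event = c(1, 0, 0), age = 40)
  expect_equal(segment_loglik(r3, segment_params(0.3, 0.4)),
               -3.00704547918263, tolerance = 1e-12)
  expect_equal(segment_loglik(r3, segment_params(0.3, 0.4)),
               oracle_seg_ll(r3, 0.3, 0.4))
})

test_that("p = 0 reduces to the censored-exponential closed form", {
  set.seed(11)
  rec <- data.frame(time = rexp(40, 0.3), event = rbinom(40, 1, 0.5),
                    age = 50)
  for (lam in c(0.1, 0.5, 2)) {
    d <- sum(rec$event)
    expect_equal(segment_loglik(rec, segment_params(0, lam)),
                 d * log(lam) - lam * sum(rec$time))
  }
})

test_that("a saturated cure fraction with events yields -Inf, not an error", {
  rec <- data.frame(time = c(1, 2), event = c(1, 0), age = 50)
  expect_identical(segment_loglik(rec, segment_params(1, 0.5)), -Inf)
  # with only censored records p = 1 is fine: everyone survives
  cen <- data.frame(time = c(1, 2), event = c(0, 0), age = 50)
  expect_identical(segment_loglik(cen, segment_params(1, 0.5)), 0)
})

straddle <- data.frame(time = c(2, 10, 5, 20), event = c(1, 0, 1, 0),
                       age = c(45, 50, 55, 62))
tab1 <- cp_cure_params(50, segment_params(0.65, 0.16),
                       segment_params(0.31, 0.13))

test_that("change-point log-likelihood partitions at tau (closed left)", {
  # all records left of tau: reduces to the left segment alone
  rec <- data.frame(time = c(1, 4, 2), event = c(1, 0, 1), age = c(30, 40, 50))
  expect_equal(change_point_loglik(rec, tab1),
               segment_loglik(rec, tab1$left))

  # the record at age exactly 50 belongs to the left segment
  expect_equal(change_point_loglik(straddle, tab1),
               -7.60945911863525, tolerance = 1e-12)
  expect_equal(change_point_loglik(straddle, tab1),
               oracle_cp_ll(straddle, 50, 0.65, 0.16, 0.31, 0.13))

  # additivity over the induced partition
  sel <- straddle$age <= tab1$tau
  expect_equal(change_point_loglik(straddle, tab1),
               segment_loglik(straddle[sel, ], tab1$left) +
                 segment_loglik(straddle[!sel, ], tab1$right))
})

test_that("change-point log-likelihood is invariant to record order", {
  set.seed(21)
  rec <- make_cp_data(50)
  base <- change_point_loglik(rec, tab1)
  for (i in 1:5) {
    perm <- rec[sample.int(nrow(rec)), ]
    expect_equal(change_point_loglik(perm, tab1), base)
  }
})

test_that("smoothed log-likelihood interpolates and converges to the hard one", {
  # a record exactly at tau gets kernel weight 1/2
  at_tau <- data.frame(time = 3, event = 1, age = 50)
  expect_equal(smoothed_loglik(at_tau, tab1, bandwidth = 2),
               0.5 * segment_loglik(at_tau, tab1$left) +
                 0.5 * segment_loglik(at_tau, tab1$right))

  # frozen value from independent weighted summation (h = 1)
  expect_equal(smoothed_loglik(straddle, tab1, bandwidth = 1),
               -7.79419833533296, tolerance = 1e-12)
  expect_equal(smoothed_loglik(straddle, tab1, bandwidth = 1),
               oracle_smooth_ll(straddle, 50, 0.65, 0.16, 0.31, 0.13, 1))

  # monotone approach to the hard likelihood as the bandwidth shrinks,
  # on data with every age at least one unit away from tau
  off <- straddle[straddle$age != 50, ]
  hard <- change_point_loglik(off, tab1)
  gaps <- vapply(c(1, 0.1, 1e-4),
                 function(h) abs(smoothed_loglik(off, tab1, h) - hard), 0)
  expect_true(all(diff(gaps) <= 0))
  expect_lt(abs(smoothed_loglik(off, tab1, 1e-8) - hard), 1e-6)

  expect_error(smoothed_loglik(straddle, tab1, 0), "positive")
  expect_error(smoothed_loglik(straddle, tab1, -1), "positive")
})

test_that("record validation enforces the domain invariants", {
  expect_error(validate_records(data.frame(time = -1, event = 0, age = 50)),
               "non-negative")
  expect_error(validate_records(data.frame(time = 1, event = 2, age = 50)),
               "0.*1")
  expect_error(validate_records(data.frame(time = 1, event = 1, age = Inf)),
               "finite")
  expect_error(validate_records(data.frame(time = 1, event = 1)), "age")
  expect_error(validate_records(data.frame(time = numeric(0),
                                           event = numeric(0),
                                           age = numeric(0))),
               "at least one")
})
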