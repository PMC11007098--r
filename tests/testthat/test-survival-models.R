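# Candidate parametric families: closed forms, medians, per-cycle
# probabilities and nesting relations of the generalized gamma.

example_models <- list(
  exponential = parametric_survival("exponential", rate = 0.05),
  weibull     = parametric_survival("weibull", shape = 1.4, scale = 80),
  gamma       = parametric_survival("gamma", shape = 2, rate = 0.03),
  gengamma    = parametric_survival("gengamma", mu = 2.88767, sigma = 1.45261, Q = -1.30760),
  lognormal   = parametric_survival("lognormal", meanlog = 4.83614, sdlog = 1.01581),
  loglogistic = parametric_survival("loglogistic", shape = 1.63351, scale = 112.73457),
  gompertz    = parametric_survival("gompertz", shape = 0.02, rate = 0.01)
)

test_that("S(0) = 1 and survival is non-increasing within [0, 1] for every family", {
  grid <- seq(0, 600, length.out = 1000)
  for (m in example_models) {
    s <- survival_at(m, grid)
    expect_equal(s[1], 1, info = m$family)
    expect_true(all(s >= 0 & s <= 1), info = m$family)
    expect_true(all(diff(s) <= 1e-12), info = m$family)
  }
})

test_that("medians match closed forms and the quantile route", {
  expect_equal(median_survival(example_models$loglogistic), 112.73457)
  expect_equal(median_survival(example_models$lognormal), exp(4.83614))
  expect_equal(median_survival(example_models$exponential), log(2) / 0.05)
  # bisection oracle for the generalized gamma
  gg <- example_models$gengamma
  oracle <- uniroot(function(t) survival_at(gg, t) - 0.5, c(1e-6, 1000),
                    tol = 1e-10)$root
  expect_equal(median_survival(gg), oracle, tolerance = 1e-8)
  # every family: S(median) = 0.5
  for (m in example_models) {
    expect_equal(survival_at(m, median_survival(m)), 0.5,
                 tolerance = 1e-8, info = m$family)
  }
})

test_that("generalized gamma recovers its log-normal and Weibull special cases", {
  t <- c(12, 60, 120)
  gg0 <- parametric_survival("gengamma", mu = 4.83614, sigma = 1.01581, Q = 1e-8)
  expect_equal(survival_at(gg0, t),
               survival_at(example_models$lognormal, t), tolerance = 1e-5)
  wb <- example_models$weibull
  gg1 <- parametric_survival("gengamma", mu = log(80), sigma = 1 / 1.4, Q = 1)
  expect_lt(max(abs(survival_at(gg1, seq(0.5, 400, by = 0.5)) -
                    survival_at(wb, seq(0.5, 400, by = 0.5)))), 1e-8)
})

test_that("per-cycle event probabilities are conditional survival ratios", {
  delta <- 21 / 30.4375
  ll <- example_models$loglogistic
  # direct recomputation from two survival evaluations
  k <- 10
  expect_equal(interval_event_prob(ll, k, delta),
               1 - survival_at(ll, k * delta) / survival_at(ll, (k - 1) * delta),
               tolerance = 1e-12)
  # first cycle: 1 - S(delta)
  expect_equal(interval_event_prob(ll, 1, delta), 1 - survival_at(ll, delta))
  # memorylessness of the exponential
  ex <- example_models$exponential
  probs <- vapply(1:50, interval_event_prob, numeric(1),
                  model = ex, cycle_length = delta)
  expect_equal(probs, rep(1 - exp(-0.05 * delta), 50), tolerance = 1e-12)
})

test_that("chained per-cycle probabilities telescope to the survival curve", {
  delta <- 21 / 30.4375
  for (m in example_models) {
    q <- vapply(1:100, interval_event_prob, numeric(1),
                model = m, cycle_length = delta)
    expect_equal(prod(1 - q), survival_at(m, 100 * delta),
                 tolerance = 1e-10, info = m$family)
  }
})

test_that("invalid inputs are rejected", {
  expect_error(parametric_survival("loglogistic", shape = -1, scale = 10), "positive")
  expect_error(parametric_survival("lognormal", meanlog = 1), "requires parameter")
  expect_error(parametric_survival("cureplineal"), "arg")
  expect_error(survival_at(example_models$weibull, -1), "non-negative")
  expect_error(interval_event_prob(example_models$weibull, 0, 0.7), ">= 1")
  # survival numerically exhausted -> dedicated condition class
  steep <- parametric_survival("exponential", rate = 1e5)
  expect_error(interval_event_prob(steep, 2, 10), class = "exhausted_survival")
})

test_that("the base-case registry instantiates all four fitted curves", {
  curves <- base_case_survival(default_parameters())
  expect_named(curves, c("dfs_active", "dfs_control", "os_active", "os_control"))
  expect_equal(curves$dfs_active$family, "loglogistic")
  expect_equal(curves$os_control$family, "lognormal")
  expect_equal(median_survival(curves$dfs_active), 112.73457)
  # fitted OS curves imply 5-year survival near the trial's reported rates
  expect_equal(survival_at(curves$os_active, 60), 0.88, tolerance = 0.01)
  expect_equal(survival_at(curves$os_control, 60), 0.78, tolerance = 0.02)
})
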