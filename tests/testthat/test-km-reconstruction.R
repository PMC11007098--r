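# Pseudo-IPD reconstruction from digitized curves and the product-limit
# estimator used to verify it.

test_that("product-limit estimate matches hand calculations", {
  # 3 events, no censoring: steps 2/3, 1/3, 0
  km <- km_estimator(pseudo_ipd(1:3, c(1, 1, 1)))
  expect_equal(km$points$survival, c(1, 2/3, 1/3, 0))
  # all censored: flat at 1
  km_flat <- km_estimator(pseudo_ipd(1:4, rep(0, 4)))
  expect_equal(km_flat$points$survival, 1)
  # mixed: S(3) = (4/5)(2/3), S(5) = 0
  km_mix <- km_estimator(hand_ipd())
  expect_equal(curve_survival(km_mix, 3), (4/5) * (2/3))
  expect_equal(curve_survival(km_mix, 5), 0)
  # at-risk counts count subjects with time >= t
  expect_equal(km_mix$risk_table$n_risk, c(5, 1))
})

test_that("no-censoring curves reconstruct exactly", {
  curve <- digitized_curve(
    points = data.frame(time = c(0, 5, 8), survival = c(1, 0.9, 0.8)),
    risk_table = data.frame(time = c(0, 10), n_risk = c(10, 8)))
  ipd <- reconstruct_ipd(curve)
  expect_equal(nrow(ipd), 10)
  expect_equal(sum(ipd$event), 2)
  expect_equal(ipd$time[ipd$event == 1], c(5, 8))
  # the 8 survivors are administratively censored at the window end
  expect_equal(ipd$time[ipd$event == 0], rep(10, 8))
  km <- km_estimator(ipd)
  expect_equal(curve_survival(km, c(5, 8)), c(0.9, 0.8))
})

test_that("a flat curve yields zero events, all censored at window end", {
  curve <- digitized_curve(
    points = data.frame(time = 0, survival = 1),
    risk_table = data.frame(time = c(0, 12), n_risk = c(10, 10)))
  ipd <- reconstruct_ipd(curve)
  expect_equal(nrow(ipd), 10)
  expect_equal(sum(ipd$event), 0)
  expect_true(all(abs(ipd$time - 12) < 1e-6))
})

test_that("reconstruction round-trips a censored synthetic curve", {
  model <- parametric_survival("loglogistic", shape = 1.6, scale = 110)
  ipd0 <- simulate_ipd(trial_sim_spec(model, n = 250, accrual_months = 24,
                                      followup_months = 96, seed = 42))
  risk_times <- seq(0, 108, by = 12)
  curve <- digitize(ipd0, risk_times)
  ipd1 <- reconstruct_ipd(curve)

  # record count equals the initial at-risk count
  expect_equal(nrow(ipd1), curve$risk_table$n_risk[1])
  # KM of the reconstruction matches the digitized curve at every step point
  km1 <- km_estimator(ipd1, risk_times)
  dev <- abs(curve_survival(km1, curve$points$time) - curve$points$survival)
  expect_lt(max(dev), 1 / min(curve$risk_table$n_risk))
  # and the generating survival function to digitization accuracy
  tt <- seq(6, 96, by = 6)
  expect_lt(max(abs(curve_survival(km1, tt) - curve_survival(digitize(ipd0), tt))), 0.02)
  # at-risk counts at the table times match exactly
  expect_equal(vapply(risk_times, function(t) sum(ipd1$time >= t), numeric(1)),
               curve$risk_table$n_risk)
})

test_that("inconsistent digitized inputs are rejected with the offending location", {
  expect_error(digitized_curve(
    points = data.frame(time = c(0, 3, 6), survival = c(1, 0.7, 0.8)),
    risk_table = data.frame(time = c(0, 10), n_risk = c(10, 5))),
    "rises")
  expect_error(digitized_curve(
    points = data.frame(time = 0, survival = 1),
    risk_table = data.frame(time = c(0, 10), n_risk = c(10, 12))),
    "non-increasing")
  expect_error(digitized_curve(
    points = data.frame(time = 0, survival = 1),
    risk_table = data.frame(time = 0, n_risk = 10)),
    "at least 2 rows")
  # more survivors claimed at the next risk time than the curve allows
  steep <- digitized_curve(
    points = data.frame(time = c(0, 5), survival = c(1, 0.2)),
    risk_table = data.frame(time = c(0, 10), n_risk = c(10, 9)))
  expect_error(reconstruct_ipd(steep), "interval")
  expect_error(pseudo_ipd(c(0, 1), c(1, 1)), "positive")
})

test_that("curves and pseudo-IPD round-trip through CSV", {
  tmp <- withr::local_tempdir()
  curve <- km_estimator(hand_ipd(), risk_times = c(0, 2, 4))
  write_digitized_curve(curve, file.path(tmp, "pts.csv"), file.path(tmp, "risk.csv"))
  curve2 <- read_digitized_curve(file.path(tmp, "pts.csv"), file.path(tmp, "risk.csv"))
  expect_equal(curve2$points, curve$points)
  expect_equal(curve2$risk_table, curve$risk_table)
  write_ipd(hand_ipd(), file.path(tmp, "ipd.csv"))
  expect_equal(as.data.frame(read_ipd(file.path(tmp, "ipd.csv"))),
               as.data.frame(hand_ipd()))
})
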