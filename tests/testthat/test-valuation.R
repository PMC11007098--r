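# Cost and QALY accrual over a trace, and incremental summaries.

spec <- model_spec()
lt <- default_life_table()
traces <- build_traces(default_parameters(), spec, lt)

test_that("zero unit costs zero the cost stream but not the QALYs", {
  p0 <- zero_cost_params()
  for (arm in c("active", "control")) {
    res <- accrue_arm(traces[[arm]], spec, p0, arm = arm)
    expect_equal(res$total_cost, 0)
    expect_gt(res$total_qalys, 0)
    base <- accrue_arm(traces[[arm]], spec, default_parameters(), arm = arm)
    expect_equal(res$total_qalys, base$total_qalys)
  }
})

test_that("unit utilities without discounting recover undiscounted life-years", {
  spec0 <- model_spec(annual_discount_rate = 0)
  tr <- build_traces(default_parameters(), spec0, lt)$control
  p <- zero_cost_params()
  p$utilities$dfs <- 1; p$utilities$recurrence <- 1
  res <- accrue_arm(tr, spec0, p, arm = "control")
  n <- spec0$n_cycles
  ly <- sum((tr$dfs + tr$recurrence)[1:n] + (tr$dfs + tr$recurrence)[2:(n + 1)]) / 2 *
    spec0$cycle_length_years
  expect_equal(res$total_qalys, ly)
})

test_that("one cycle of active-arm therapy costs 21 days of drug", {
  # a cohort that stays disease-free through a single undiscounted cycle
  spec1 <- model_spec(n_cycles = 1, annual_discount_rate = 0)
  flat <- parametric_survival("exponential", rate = 1e-12)
  tr <- run_cohort(spec1, flat, flat, null_life_table())
  p <- default_parameters()
  p$costs[setdiff(names(p$costs), "osimertinib_80mg_day")] <-
    lapply(setdiff(names(p$costs), "osimertinib_80mg_day"), function(x) 0)
  sched <- monitoring_schedule(spec1, first_cycles = 1L, q24_through = 1L,
                               annual_interval = 1L)
  res <- accrue_arm(tr, spec1, p, sched, arm = "active")
  expect_equal(res$total_cost, 21 * 566.64, tolerance = 1e-6)
  # the control arm accrues no drug cost
  expect_equal(accrue_arm(tr, spec1, p, sched, arm = "control")$total_cost, 0)
})

test_that("the treatment cap stops drug accrual after 52 cycles", {
  expect_equal(spec$treatment_cap_cycles, 52L)
  p <- default_parameters()
  res <- accrue_arm(traces$active, spec, p, arm = "active")
  # doubling the horizon-wide price only scales the capped drug component
  p2 <- set_parameter(p, "cost_osimertinib", 2 * 566.64)
  res2 <- accrue_arm(traces$active, spec, p2, arm = "active")
  expect_equal(res2$total_cost - res$total_cost, res$components[["drug"]])
})

test_that("raising any unit cost never lowers either arm's total", {
  p <- default_parameters()
  base <- vapply(c("active", "control"), function(a)
    accrue_arm(traces[[a]], spec, p, arm = a)$total_cost, numeric(1))
  for (nm in grep("^cost_", parameter_table(p)$parameter, value = TRUE)) {
    p_up <- set_parameter(p, nm, get_parameter(p, nm) * 1.5)
    up <- vapply(c("active", "control"), function(a)
      accrue_arm(traces[[a]], spec, p_up, arm = a)$total_cost, numeric(1))
    expect_true(all(up >= base - 1e-9), info = nm)
  }
})

test_that("discounting monotonicity holds in both directions", {
  rates <- c(0, 0.03, 0.05)
  out <- lapply(rates, function(r) {
    s <- model_spec(annual_discount_rate = r)
    tr <- build_traces(default_parameters(), s, lt)
    lapply(c("active", "control"), function(a)
      accrue_arm(tr[[a]], s, default_parameters(), arm = a))
  })
  for (i in 1:2) {
    costs <- vapply(out, function(x) x[[i]]$total_cost, numeric(1))
    qalys <- vapply(out, function(x) x[[i]]$total_qalys, numeric(1))
    expect_true(all(diff(costs) < 0))
    expect_true(all(diff(qalys) < 0))
  }
})

test_that("totals equal their stream sums and components", {
  res <- accrue_arm(traces$active, spec, default_parameters(), arm = "active")
  expect_equal(res$total_cost, sum(res$cycles$cost))
  expect_equal(res$total_qalys, sum(res$cycles$qalys))
  expect_equal(res$total_cost, sum(res$components))
  expect_true(all(res$cycles$cost >= 0) && all(res$cycles$qalys >= 0))
})

test_that("incremental summaries divide and classify correctly", {
  mk <- function(cost, q) structure(list(total_cost = cost, total_qalys = q),
                                    class = "arm_result")
  # division of the published rounded deltas
  inc <- compute_icer(mk(620436, 8.05), mk(127726, 6.46))
  expect_equal(inc$icer, 492710 / 1.59)
  expect_equal(inc$icer * inc$delta_qalys, inc$delta_cost, tolerance = 1e-9)
  expect_equal(inc$classification, "ratio")
  expect_equal(compute_icer(mk(100, 1), mk(100, 1))$classification, "equivalent")
  expect_equal(compute_icer(mk(200, 1), mk(100, 2))$classification, "dominated")
  expect_equal(compute_icer(mk(50, 2), mk(100, 1))$classification, "dominant")
})

test_that("a schedule beyond the horizon is rejected", {
  bad <- structure(list(dfs_assessment_cycles = 300L, imaging_interval = 2L),
                   class = "monitoring_schedule")
  expect_error(accrue_arm(traces$active, spec, schedule = bad, arm = "active"),
               "beyond the model horizon")
})

test_that("monitoring assessments follow the week-12/24, 24-weekly, then annual calendar", {
  sched <- monitoring_schedule(spec)
  expect_equal(sched$dfs_assessment_cycles[1:4], c(4L, 8L, 16L, 24L))
  expect_true(all(diff(sched$dfs_assessment_cycles[2:10]) == 8))
  late <- sched$dfs_assessment_cycles[sched$dfs_assessment_cycles > 87]
  expect_true(all(diff(late) == 17))
  expect_lte(max(sched$dfs_assessment_cycles), spec$n_cycles)
})
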