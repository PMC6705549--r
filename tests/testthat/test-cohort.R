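test_that("discount factors follow (1+r)^-t", {
  expect_identical(discount_factor(0.05, 0), 1)
  expect_identical(discount_factor(0, 17), 1)
  expect_equal(discount_factor(0.05, 10), 0.6139132535, tolerance = 1e-9)
  expect_equal(discount_factor(0.05, 0:2), c(1, 1 / 1.05, 1 / 1.05^2))
})

test_that("one propagation step reproduces a hand matrix-vector product", {
  p <- sus_edentulism_problem()
  tr <- run_trace(p$strategies$CTP, p$settings, "A")
  # full cohort in A at cycle 0, then one step of the (renormalized) A-row
  expect_identical(unname(tr["0", ]), c(1e6, 0, 0, 0))
  expect_equal(unname(tr["1", ]),
               c(0.1697, 0.5121, 0.3106, 0.0075) / 0.9999 * 1e6,
               tolerance = 1e-9)
  tr2 <- run_trace(p$strategies$ISTP, p$settings, "A")
  expect_equal(unname(tr2["1", "D"]), 7500, tolerance = 1e-9)
})

test_that("an identity transition matrix is a fixed point of the trace", {
  p <- frozen_problem()
  tr <- run_trace(p$strategies$a, p$settings, "L")
  expect_true(all(tr[, "L"] == 1e6) && all(tr[, "D"] == 0))
})

test_that("unvalidated matrices are refused by the trace", {
  p <- frozen_problem()
  s <- p$strategies$a
  s$transition[1L, ] <- c(0.7, 0.2) # sums to 0.9
  expect_error(run_trace(s, p$settings, "L"), "not validated")
})

test_that("cohort mass is conserved and death occupancy is monotone", {
  for (seed in 1:20) {
    p <- random_problem(sample(2:6, 1L), seed = seed)
    tr <- run_trace(p$strategies[[1L]], p$settings, p$initial_state)
    expect_lt(max(abs(rowSums(tr) - p$settings$cohort_size)) /
                p$settings$cohort_size, 1e-9)
    expect_true(all(tr >= -1e-9))
    expect_true(all(diff(tr[, "death"]) >= -1e-9))
  }
})

test_that("with death as the only exit, mortality follows 1-(1-p)^t", {
  p_death <- 0.0075
  prob <- chain_problem(p = p_death, horizon = 30L)
  tr <- run_trace(prob$strategies$a, prob$settings, "L")
  t <- 0:30
  expect_equal(unname(tr[, "D"]) / 1e6, 1 - (1 - p_death)^t, tolerance = 1e-12)
})

test_that("undiscounted utility in a frozen cohort is horizon times base QAPY", {
  p <- frozen_problem(horizon = 20L, rate = 0, base_qapy = 0.94)
  mult <- c(L = 1, D = 0)
  tr <- run_trace(p$strategies$a, p$settings, "L")
  for (cv in list(cycle_conventions("end"), cycle_conventions("start"),
                  cycle_conventions(half_cycle_correction = TRUE))) {
    expect_equal(as.numeric(accrue_effects(tr, p$strategies$a, p$settings,
                                           mult, cv)), 20 * 0.94)
  }
})

test_that("a cohort sent straight to death accrues no utility", {
  states <- list(health_state("L"), health_state("D", absorbing = TRUE))
  m <- matrix(c(0, 1, 0, 1), 2L, byrow = TRUE)
  strat <- strategy_model("a", m, cost_schedule(0), 1)
  prob <- decision_problem(states, list(strat, strategy_model("b", m, cost_schedule(0), 1)),
                           econ_settings(horizon = 20L), initial_state = "L")
  out <- run_strategy(prob, "a", cycle_conventions("end"))
  expect_identical(out$total_effect_pp, 0)
})

test_that("an immortal cohort pays the initial cost plus three replacements", {
  p <- frozen_problem(horizon = 20L, rate = 0, initial_cost = 196.83)
  for (payers in c("alive", "prosthesis", "cohort")) {
    out <- run_strategy(p, "a", cycle_conventions(replacement_payers = payers))
    expect_equal(out$total_cost_pp, 196.83 * 4) # t = 0, 5, 10, 15
  }
  zero <- frozen_problem(initial_cost = 0)
  expect_identical(run_strategy(zero, "a")$total_cost_pp, 0)
})

test_that("discounting can only shrink totals", {
  for (seed in c(3, 11, 25)) {
    p0 <- random_problem(4L, seed = seed)
    rates <- c(0, 0.03, 0.08, 0.15)
    runs <- lapply(rates, function(r) run_strategy(with_rates(p0, r),
                                                   names(p0$strategies)[1L]))
    costs <- vapply(runs, `[[`, numeric(1L), "total_cost_pp")
    effects <- vapply(runs, `[[`, numeric(1L), "total_effect_pp")
    expect_true(all(diff(costs) <= 1e-9))
    expect_true(all(diff(effects) <= 1e-9))
  }
  # zero rate reproduces plain sums exactly
  p <- frozen_problem(horizon = 7L, rate = 0, base_qapy = 0.5, initial_cost = 10)
  out <- run_strategy(p, "a", cycle_conventions(replacement_payers = "alive"))
  expect_identical(out$total_effect_pp, 7 * 0.5)
  expect_identical(out$total_cost_pp, 10 * 2) # replacement at t = 5 only
})

test_that("bundled-scenario totals sit in the expected range", {
  p <- sus_edentulism_problem()
  ctp <- run_strategy(p, "CTP")
  istp <- run_strategy(p, "ISTP")
  expect_gt(ctp$total_cost_pp, 540); expect_lt(ctp$total_cost_pp, 580)
  expect_equal(istp$total_effect_pp, 10.3, tolerance = 0.03)
  expect_true(istp$total_cost_pp > ctp$total_cost_pp)
  expect_true(istp$total_effect_pp > ctp$total_effect_pp)
})

test_that("trace exports to tidy long format", {
  p <- frozen_problem(horizon = 3L)
  tr <- run_trace(p$strategies$a, p$settings, "L")
  df <- as.data.frame(tr)
  expect_identical(names(df), c("cycle", "state", "occupancy"))
  expect_identical(nrow(df), 8L)
  expect_identical(sum(df$occupancy), 4 * 1e6)
})
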