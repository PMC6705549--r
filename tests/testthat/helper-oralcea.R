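# Small constructors reused across the test files.

# Two-state live/dead chain with per-cycle death probability p.
chain_problem <- function(p = 0.1, horizon = 20L, rate = 0,
                          initial_cost = 100, base_qapy = 1) {
  states <- list(health_state("L", utility_multiplier = 1),
                 health_state("D", absorbing = TRUE))
  m <- matrix(c(1 - p, p, 0, 1), 2L, byrow = TRUE)
  strat <- function(nm) {
    strategy_model(nm, m, cost_schedule(initial_cost), base_qapy)
  }
  decision_problem(states, list(strat("a"), strat("b")),
                   econ_settings(discount_rate_costs = rate,
                                 discount_rate_effects = rate,
                                 horizon = horizon, cohort_size = 1e6),
                   initial_state = "L")
}

# Everyone stays put forever (identity transitions, one nominal death state).
frozen_problem <- function(horizon = 20L, rate = 0, base_qapy = 0.94,
                           initial_cost = 196.83) {
  chain_problem(p = 0, horizon = horizon, rate = rate,
                base_qapy = base_qapy, initial_cost = initial_cost)
}

# Minimal strategy_outcome stand-in for testing the econ layer in isolation.
fake_outcome <- function(name, cost, effect) {
  structure(list(strategy = name, total_cost_pp = cost,
                 total_effect_pp = effect,
                 conventions = cycle_conventions()),
            class = "strategy_outcome")
}

# psa_result stand-in holding a given (delta_cost, delta_effect) cloud.
fake_psa <- function(delta_cost, delta_effect) {
  structure(list(samples = data.frame(iteration = seq_along(delta_cost),
                                      delta_cost = delta_cost,
                                      delta_effect = delta_effect),
                 reference = "a", comparator = "b", seed = 0L,
                 spec = NULL, conventions = cycle_conventions(),
                 failures = 0L),
            class = "psa_result")
}

# Rebuild a problem with different discount rates (shared by several tests).
with_rates <- function(problem, rate) {
  s <- problem$settings
  decision_problem(problem$states, problem$strategies,
                   econ_settings(rate, rate, s$horizon, s$cycle_length,
                                 s$cohort_size, s$wtp_thresholds),
                   initial_state = problem$initial_state)
}
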