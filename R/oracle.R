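#' Individual-level microsimulation of one strategy arm
#'
#' Stochastic counterpart of the cohort engine, used as a brute-force
#' validation oracle: each of `n` patients starts in the initial state and
#' moves each cycle according to the current state's transition row. Costs
#' and QAPY are accrued deterministically from the visited states under the
#' identical timing conventions as [accrue_costs()] / [accrue_effects()],
#' so the microsimulation mean estimates exactly what the cohort engine
#' computes and only the state paths are random.
#'
#' @param problem A validated [decision_problem()].
#' @param strategy_name Arm to simulate.
#' @param n Number of simulated patients (>= 1).
#' @param seed Integer seed (own RNG stream; caller's state restored).
#' @param conventions A [cycle_conventions()].
#' @return Object of class `microsim_result`: list with `trajectories`
#'   (`n x (horizon+1)` matrix of state ids), per-patient `cost` and
#'   `effect` vectors, and `summary` (means with standard errors).
#' @export
simulate_patients <- function(problem, strategy_name, n = 50000L, seed = 1L,
                              conventions = cycle_conventions()) {
  stopifnot(inherits(problem, "decision_problem"), n >= 1)
  s <- problem$strategies[[strategy_name]]
  if (is.null(s)) stop(sprintf("no strategy named '%s'", strategy_name), call. = FALSE)
  settings <- problem$settings
  h <- settings$horizon
  ids <- state_ids(problem)
  k <- length(ids)
  m <- s$transition

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  # state paths as integer indices; one vectorized draw per (cycle, state)
  path <- matrix(0L, nrow = n, ncol = h + 1L)
  path[, 1L] <- match(problem$initial_state, ids)
  for (t in seq_len(h)) {
    cur <- path[, t]
    nxt <- integer(n)
    for (j in seq_len(k)) {
      idx <- which(cur == j)
      if (length(idx)) {
        nxt[idx] <- sample.int(k, length(idx), replace = TRUE, prob = m[j, ])
      }
    }
    path[, t + 1L] <- nxt
  }

  mult <- utility_multipliers(problem)
  u <- s$base_qapy * mult
  re <- settings$discount_rate_effects
  if (conventions$half_cycle_correction) {
    effect <- rowSums(
      (matrix(u[path[, 1:h]], n) + matrix(u[path[, 2:(h + 1L)]], n)) / 2 *
        rep(discount_factor(re, 0:(h - 1L)), each = n))
  } else if (conventions$effect_timing == "start") {
    effect <- rowSums(matrix(u[path[, 1:h]], n) *
                        rep(discount_factor(re, 0:(h - 1L)), each = n))
  } else {
    effect <- rowSums(matrix(u[path[, 2:(h + 1L)]], n) *
                        rep(discount_factor(re, 1:h), each = n))
  }

  rc <- settings$discount_rate_costs
  cs <- s$costs
  cost <- rep(cs$initial_cost, n)
  reps <- if (cs$replacement_interval <= h - 1L) {
    seq(cs$replacement_interval, h - 1L, by = cs$replacement_interval)
  } else integer(0)
  if (length(reps) && cs$replacement_cost > 0) {
    payers <- match(payer_states(problem, conventions), ids)
    for (t in reps) {
      pays <- if (identical(conventions$replacement_payers, "cohort")) {
        rep(TRUE, n)
      } else path[, t + 1L] %in% payers
      cost <- cost + pays * discount_factor(rc, t) * cs$replacement_cost
    }
  }
  pc <- cs$per_state_cycle_cost
  if (any(pc > 0)) {
    if (conventions$half_cycle_correction) {
      cost <- cost + rowSums(
        (matrix(pc[path[, 1:h]], n) + matrix(pc[path[, 2:(h + 1L)]], n)) / 2 *
          rep(discount_factor(rc, 0:(h - 1L)), each = n))
    } else if (conventions$effect_timing == "start") {
      cost <- cost + rowSums(matrix(pc[path[, 1:h]], n) *
                               rep(discount_factor(rc, 0:(h - 1L)), each = n))
    } else {
      cost <- cost + rowSums(matrix(pc[path[, 2:(h + 1L)]], n) *
                               rep(discount_factor(rc, 1:h), each = n))
    }
  }

  traj <- matrix(ids[path], nrow = n, dimnames = list(NULL, 0:h))
  structure(
    list(trajectories = traj,
         cost = cost, effect = effect,
         summary = data.frame(
           quantity = c("cost_pp", "effect_pp"),
           mean = c(mean(cost), mean(effect)),
           se = c(stats::sd(cost), stats::sd(effect)) / sqrt(n)
         ),
         strategy = strategy_name, n = n, seed = seed,
         conventions = conventions),
    class = "microsim_result"
  )
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("<microsim_result> %s: %d patients (seed %d)\n",
              x$strategy, x$n, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Empirical state occupancy of a microsimulation
#'
#' @param sim A [simulate_patients()] result.
#' @param problem The decision problem it was simulated from.
#' @return `(horizon+1) x K` matrix of patient counts per state and cycle.
#' @export
microsim_occupancy <- function(sim, problem) {
  ids <- state_ids(problem)
  t(apply(sim$trajectories, 2L, function(col) {
    tabulate(match(col, ids), nbins = length(ids))
  }))
}

#' Long-format export of simulated trajectories
#'
#' @param sim A [simulate_patients()] result.
#' @return Data frame with columns `patient`, `cycle`, `state`.
#' @export
trajectories_long <- function(sim) {
  traj <- sim$trajectories
  data.frame(
    patient = rep(seq_len(nrow(traj)), times = ncol(traj)),
    cycle = rep(as.integer(colnames(traj)), each = nrow(traj)),
    state = as.vector(traj),
    stringsAsFactors = FALSE
  )
}

#' Generate a random, valid decision problem
#'
#' Draws a well-formed two-strategy decision problem for property testing:
#' `k_states` states of which the last is absorbing (death), transition
#' rows uniform on the simplex over all destinations, initial costs uniform
#' on [50, 2000] BRL, replacement interval in 2..8 years, base QAPY and
#' live-state multipliers uniform on (0, 1] with the initial state at
#' multiplier 1, horizon uniform in 5..40 years. Always passes
#' [decision_problem()] validation.
#'
#' @param k_states Number of states (>= 2).
#' @param seed Integer seed (own RNG stream; caller's state restored).
#' @return A validated [decision_problem()].
#' @export
random_problem <- function(k_states = 4L, seed = 1L) {
  stopifnot(k_states >= 2L)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  k <- as.integer(k_states)
  ids <- c(LETTERS[seq_len(k - 1L)], "death")
  states <- c(
    lapply(seq_len(k - 1L), function(i) {
      health_state(ids[i], utility_multiplier = if (i == 1L) 1 else stats::runif(1L))
    }),
    list(health_state("death", absorbing = TRUE))
  )
  rand_matrix <- function() {
    m <- matrix(0, k, k)
    for (i in seq_len(k - 1L)) m[i, ] <- rdirichlet1(rep(1, k))
    m[k, k] <- 1
    m
  }
  horizon <- sample(5:40, 1L)
  strategies <- lapply(c("arm1", "arm2"), function(nm) {
    strategy_model(
      nm, rand_matrix(),
      cost_schedule(initial_cost = stats::runif(1L, 50, 2000),
                    replacement_interval = sample(2:8, 1L)),
      base_qapy = stats::runif(1L, 0.2, 1)
    )
  })
  decision_problem(states, strategies,
                   econ_settings(discount_rate_costs = stats::runif(1L, 0, 0.1),
                                 discount_rate_effects = stats::runif(1L, 0, 0.1),
                                 horizon = horizon,
                                 cohort_size = 1e6),
                   initial_state = ids[1L], tol = 1e-9)
}
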