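#' Discount factor for an annual cycle
#'
#' @param rate Annual discount rate as a fraction (>= 0).
#' @param t Cycle index (integer >= 0); may be a vector.
#' @return `(1 + rate)^(-t)`.
#' @export
discount_factor <- function(rate, t) {
  stopifnot(rate >= 0, all(t >= 0))
  (1 + rate)^(-t)
}

#' Cycle accounting conventions
#'
#' An annual-cycle spreadsheet Markov model leaves several timing choices
#' open; published totals can only be reproduced under the conventions the
#' original model used, so all of them are explicit toggles here.
#'
#' \describe{
#'   \item{effect_timing}{`"end"` accrues cycle-`t` utility on the state
#'     occupied at the end of the cycle, discounted by `(1+r)^(-t)` for
#'     `t = 1..horizon`; `"start"` uses the cycle-start occupancy discounted
#'     by `(1+r)^(-t)`, `t = 0..horizon-1`. Default `"end"`: a
#'     prosthesis-year is evaluated once it has been lived.}
#'   \item{half_cycle_correction}{If `TRUE`, utilities (and per-cycle state
#'     costs) accrue on the average of cycle-start and cycle-end occupancy —
#'     the standard half-cycle correction; overrides `effect_timing`.}
#'   \item{replacement_payers}{Which states pay the scheduled replacement
#'     cost at cycles `t = interval, 2*interval, ...` (`t < horizon`):
#'     `"alive"` (default) — every living patient stays on the public
#'     provision schedule; `"prosthesis"` — only states still bearing a
#'     functional prosthesis (non-absorbing states with utility multiplier
#'     > 0.5, i.e. A and B in the bundled scenario); `"cohort"` — the whole
#'     initial cohort regardless of state, the bluntest spreadsheet
#'     convention.}
#' }
#'
#' @param effect_timing `"end"` or `"start"`.
#' @param half_cycle_correction Logical.
#' @param replacement_payers `"alive"`, `"prosthesis"` or `"cohort"`.
#' @return An object of class `cycle_conventions`.
#' @export
cycle_conventions <- function(effect_timing = c("end", "start"),
                              half_cycle_correction = FALSE,
                              replacement_payers = c("alive", "prosthesis", "cohort")) {
  structure(
    list(effect_timing = match.arg(effect_timing),
         half_cycle_correction = isTRUE(half_cycle_correction),
         replacement_payers = match.arg(replacement_payers)),
    class = "cycle_conventions"
  )
}

#' All combinations of the cycle conventions
#'
#' Convenience grid for sensitivity checks of the accounting conventions.
#'
#' @return Data frame with one row per convention combination and a
#'   list-column `conventions` of [cycle_conventions()] objects.
#' @export
conventions_grid <- function() {
  g <- expand.grid(effect_timing = c("end", "start"),
                   half_cycle_correction = c(FALSE, TRUE),
                   replacement_payers = c("alive", "prosthesis", "cohort"),
                   stringsAsFactors = FALSE)
  # with half-cycle correction on, effect_timing is moot; drop duplicates
  g <- g[!(g$half_cycle_correction & g$effect_timing == "start"), ]
  rownames(g) <- NULL
  g$conventions <- lapply(seq_len(nrow(g)), function(i) {
    cycle_conventions(g$effect_timing[i], g$half_cycle_correction[i],
                      g$replacement_payers[i])
  })
  g
}

payer_states <- function(problem, conventions) {
  ids <- state_ids(problem)
  abs_ <- absorbing_flags(problem)
  mult <- utility_multipliers(problem)
  switch(conventions$replacement_payers,
         alive = ids[!abs_],
         prosthesis = ids[!abs_ & mult > 0.5],
         cohort = ids)
}

#' Propagate a cohort through a strategy's transition matrix
#'
#' Expected-value cohort propagation: the full cohort starts in
#' `initial_state` at cycle 0 and `occupancy[t+1, ] = occupancy[t, ] %*% M`
#' for each annual cycle.
#'
#' @param strategy A [strategy_model()] with a validated (row-stochastic)
#'   transition matrix — pass strategies out of a [decision_problem()].
#' @param settings An [econ_settings()].
#' @param initial_state State id holding the cohort at cycle 0.
#' @return Object of class `cohort_trace`: a `(horizon+1) x K` occupancy
#'   matrix (rows named by cycle `0..horizon`, columns by state id).
#' @export
run_trace <- function(strategy, settings, initial_state) {
  m <- strategy$transition
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-9) || any(m < 0)) {
    stop("transition matrix is not validated; run the strategy through decision_problem() or validate_matrix()",
         call. = FALSE)
  }
  ids <- colnames(m)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(m)))
  h <- settings$horizon
  occ <- matrix(0, nrow = h + 1L, ncol = ncol(m),
                dimnames = list(0:h, ids))
  occ[1L, initial_state] <- settings$cohort_size
  for (t in seq_len(h)) occ[t + 1L, ] <- occ[t, , drop = FALSE] %*% m
  structure(occ, class = c("cohort_trace", "matrix"))
}

#' Discounted QAPY accrued per patient
#'
#' Sums utility over the horizon under the timing convention: each cycle a
#' patient contributes `base_qapy * multiplier(state)`, discounted at the
#' effects rate.
#'
#' @param trace A [run_trace()] result for the same strategy/settings.
#' @param strategy,settings As in [run_trace()].
#' @param multipliers Named numeric vector of state utility multipliers.
#' @param conventions A [cycle_conventions()].
#' @return Per-patient discounted QAPY, with attribute `cycle_effects`
#'   (discounted cohort QAPY per cycle).
#' @export
accrue_effects <- function(trace, strategy, settings, multipliers,
                           conventions = cycle_conventions()) {
  h <- settings$horizon
  if (nrow(trace) != h + 1L) stop("trace/settings horizon mismatch", call. = FALSE)
  u <- strategy$base_qapy * multipliers[colnames(trace)]
  r <- settings$discount_rate_effects
  if (conventions$half_cycle_correction) {
    occ <- (trace[1:h, , drop = FALSE] + trace[2:(h + 1L), , drop = FALSE]) / 2
    w <- discount_factor(r, 0:(h - 1L))
  } else if (conventions$effect_timing == "start") {
    occ <- trace[1:h, , drop = FALSE]
    w <- discount_factor(r, 0:(h - 1L))
  } else {
    occ <- trace[2:(h + 1L), , drop = FALSE]
    w <- discount_factor(r, 1:h)
  }
  per_cycle <- as.numeric(occ %*% u) * w
  total <- sum(per_cycle) / settings$cohort_size
  structure(total, cycle_effects = per_cycle)
}

#' Discounted cost accrued per patient
#'
#' Initial procedure cost at cycle 0 (undiscounted) for the whole cohort;
#' replacement cost at every cycle that is a positive multiple of the
#' replacement interval (strictly before the horizon), paid by the occupancy
#' of the payer states at that cycle; optional per-state per-cycle costs
#' under the same occupancy convention as effects.
#'
#' @inheritParams accrue_effects
#' @param problem The enclosing [decision_problem()] (for state roles).
#' @return Per-patient discounted cost in BRL, with attribute `cycle_costs`.
#' @export
accrue_costs <- function(trace, strategy, settings, problem,
                         conventions = cycle_conventions()) {
  h <- settings$horizon
  if (nrow(trace) != h + 1L) stop("trace/settings horizon mismatch", call. = FALSE)
  r <- settings$discount_rate_costs
  n <- settings$cohort_size
  cs <- strategy$costs
  cycle_costs <- numeric(h + 1L)
  cycle_costs[1L] <- cs$initial_cost * n

  reps <- if (cs$replacement_interval <= h - 1L) {
    seq(cs$replacement_interval, h - 1L, by = cs$replacement_interval)
  } else integer(0)
  if (length(reps) && cs$replacement_cost > 0) {
    payers <- payer_states(problem, conventions)
    for (t in reps) {
      paying <- if (identical(conventions$replacement_payers, "cohort")) n
                else sum(trace[t + 1L, payers])
      cycle_costs[t + 1L] <- cycle_costs[t + 1L] +
        discount_factor(r, t) * paying * cs$replacement_cost
    }
  }

  pc <- cs$per_state_cycle_cost
  if (any(pc > 0)) {
    pc <- pc[colnames(trace)]
    if (conventions$half_cycle_correction) {
      occ <- (trace[1:h, , drop = FALSE] + trace[2:(h + 1L), , drop = FALSE]) / 2
      tt <- 0:(h - 1L)
    } else if (conventions$effect_timing == "start") {
      occ <- trace[1:h, , drop = FALSE]
      tt <- 0:(h - 1L)
    } else {
      occ <- trace[2:(h + 1L), , drop = FALSE]
      tt <- 1:h
    }
    cycle_costs[tt + 1L] <- cycle_costs[tt + 1L] +
      as.numeric(occ %*% pc) * discount_factor(r, tt)
  }

  structure(sum(cycle_costs) / n, cycle_costs = cycle_costs)
}

#' Run one strategy arm: trace plus discounted totals
#'
#' @param problem A [decision_problem()].
#' @param strategy_name Name of the arm to run.
#' @param conventions A [cycle_conventions()].
#' @return Object of class `strategy_outcome` with `total_cost_pp`,
#'   `total_effect_pp` (discounted, per patient) and the `cohort_trace`.
#' @export
run_strategy <- function(problem, strategy_name,
                         conventions = cycle_conventions()) {
  stopifnot(inherits(problem, "decision_problem"))
  s <- problem$strategies[[strategy_name]]
  if (is.null(s)) stop(sprintf("no strategy named '%s'", strategy_name), call. = FALSE)
  tr <- run_trace(s, problem$settings, problem$initial_state)
  eff <- accrue_effects(tr, s, problem$settings, utility_multipliers(problem),
                        conventions)
  cost <- accrue_costs(tr, s, problem$settings, problem, conventions)
  structure(
    list(strategy = strategy_name,
         total_cost_pp = as.numeric(cost),
         total_effect_pp = as.numeric(eff),
         cycle_costs = attr(cost, "cycle_costs"),
         cycle_effects = attr(eff, "cycle_effects"),
         trace = tr,
         conventions = conventions),
    class = "strategy_outcome"
  )
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome> %s: cost %.2f BRL pp, effect %.4f QAPY pp (discounted)\n",
              x$strategy, x$total_cost_pp, x$total_effect_pp))
  invisible(x)
}

#' Long-format export of a cohort trace
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return Data frame with columns `cycle`, `state`, `occupancy`.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  m <- unclass(x)
  data.frame(
    cycle = rep(as.integer(rownames(m)), times = ncol(m)),
    state = rep(colnames(m), each = nrow(m)),
    occupancy = as.vector(m),
    stringsAsFactors = FALSE
  )
}
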