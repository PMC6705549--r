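#' Define a health state
#'
#' A health state of the annual-cycle Markov model. States are mutually
#' exclusive; exactly one state of a decision problem may be absorbing
#' (death). The utility multiplier scales the strategy's base QAPY while a
#' patient occupies the state (e.g. 0.75 encodes a 25% utility decrement for
#' a damaged-but-repairable prosthesis).
#'
#' @param id Short unique token, e.g. `"A"`.
#' @param label Human-readable description.
#' @param absorbing Logical; once entered, never left. The absorbing death
#'   state carries utility multiplier 0.
#' @param utility_multiplier Fraction in `[0, 1]` applied to the strategy's
#'   base QAPY per cycle spent in the state.
#' @return An object of class `health_state`.
#' @export
health_state <- function(id, label = id, absorbing = FALSE,
                         utility_multiplier = if (absorbing) 0 else 1) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(utility_multiplier) || length(utility_multiplier) != 1L ||
      is.na(utility_multiplier) ||
      utility_multiplier < 0 || utility_multiplier > 1) {
    stop("`utility_multiplier` must be a single number in [0, 1]", call. = FALSE)
  }
  if (absorbing && utility_multiplier != 0) {
    stop("an absorbing death state must have utility_multiplier 0", call. = FALSE)
  }
  structure(
    list(id = id, label = label, absorbing = isTRUE(absorbing),
         utility_multiplier = as.numeric(utility_multiplier)),
    class = "health_state"
  )
}

#' Validate and normalize a transition matrix
#'
#' Checks a square matrix of per-cycle transition probabilities (rows =
#' origin state, columns = destination) and rescales each row proportionally
#' so it sums to exactly 1. Published tables often print probabilities to
#' four decimals so rows can sum to e.g. 0.9999; proportional rescaling
#' preserves the printed ratios. Rows of absorbing states must already be
#' identity rows and are left untouched.
#'
#' @param m Square numeric matrix with finite, non-negative entries.
#' @param tol Maximum tolerated deviation of a row sum from 1 before
#'   normalization (default 0.005, generous for 4-decimal rounding).
#' @param absorbing Optional logical vector flagging absorbing rows.
#' @return The matrix with every row summing to 1 (within 1e-12).
#' @export
validate_matrix <- function(m, tol = 0.005, absorbing = NULL) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("transition matrix must be square", call. = FALSE)
  }
  if (any(!is.finite(m))) stop("transition matrix entries must be finite", call. = FALSE)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative transition probability at row %d, column %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  if (any(m > 1)) stop("transition probabilities must not exceed 1", call. = FALSE)
  if (is.null(absorbing)) absorbing <- rep(FALSE, nrow(m))
  rs <- rowSums(m)
  off <- abs(rs - 1)
  if (any(off > tol)) {
    i <- which.max(off)
    lab <- if (!is.null(rownames(m))) rownames(m)[i] else as.character(i)
    stop(sprintf("row '%s' sums to %.6f, outside tolerance %g of 1",
                 lab, rs[i], tol), call. = FALSE)
  }
  for (i in seq_len(nrow(m))) {
    if (absorbing[i]) {
      ident <- as.numeric(seq_len(ncol(m)) == i)
      if (any(abs(m[i, ] - ident) > tol)) {
        stop(sprintf("absorbing state row %d is not an identity row", i),
             call. = FALSE)
      }
      m[i, ] <- ident
    } else {
      m[i, ] <- m[i, ] / rs[i]
    }
  }
  m
}

#' Cost schedule of a rehabilitation strategy
#'
#' Costs in BRL. The initial procedure cost is incurred for the whole cohort
#' at treatment start (cycle 0). A replacement cost is paid every
#' `replacement_interval` cycles thereafter by the states selected through
#' the cycle conventions (see [cycle_conventions()]); by default it equals
#' the full initial procedure cost. `per_state_cycle_cost` allows recurring
#' per-cycle state costs (zero in the bundled scenario: the SIGTAP table
#' prints no repair tariffs).
#'
#' @param initial_cost Non-negative BRL amount at treatment start.
#' @param replacement_cost Non-negative BRL amount per replacement event;
#'   defaults to `initial_cost`.
#' @param replacement_interval Whole number of cycles (years) between
#'   replacements; `>= 1`.
#' @param per_state_cycle_cost Named numeric vector of per-cycle costs by
#'   state id, or a single 0.
#' @return An object of class `cost_schedule`.
#' @export
cost_schedule <- function(initial_cost, replacement_cost = initial_cost,
                          replacement_interval = 5L,
                          per_state_cycle_cost = 0) {
  if (initial_cost < 0 || replacement_cost < 0 || any(per_state_cycle_cost < 0)) {
    stop("costs must be non-negative", call. = FALSE)
  }
  if (replacement_interval < 1 || replacement_interval != round(replacement_interval)) {
    stop("`replacement_interval` must be a whole number of cycles >= 1", call. = FALSE)
  }
  structure(
    list(initial_cost = as.numeric(initial_cost),
         replacement_cost = as.numeric(replacement_cost),
         replacement_interval = as.integer(replacement_interval),
         per_state_cycle_cost = per_state_cycle_cost),
    class = "cost_schedule"
  )
}

#' One strategy arm of a decision problem
#'
#' @param name Unique strategy token, e.g. `"CTP"`.
#' @param transition Square transition matrix (rows = origin), validated and
#'   normalized against the shared state list when the problem is assembled.
#' @param costs A [cost_schedule()].
#' @param base_qapy Base quality-adjusted prosthesis year of a cycle spent in
#'   the reference (complication-free) state, in `[0, 1]`.
#' @return An object of class `strategy_model`.
#' @export
strategy_model <- function(name, transition, costs, base_qapy) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!inherits(costs, "cost_schedule")) stop("`costs` must be a cost_schedule", call. = FALSE)
  if (!is.numeric(base_qapy) || length(base_qapy) != 1L ||
      base_qapy < 0 || base_qapy > 1) {
    stop("`base_qapy` must be a single number in [0, 1]", call. = FALSE)
  }
  structure(
    list(name = name, transition = transition, costs = costs,
         base_qapy = as.numeric(base_qapy)),
    class = "strategy_model"
  )
}

#' Economic settings shared by all strategies
#'
#' @param discount_rate_costs,discount_rate_effects Annual discount rates as
#'   fractions (default 0.05 each).
#' @param horizon Number of annual cycles (default 20).
#' @param cycle_length Cycle length in years; fixed at 1.
#' @param cohort_size Number of patients propagated (default 1e6).
#' @param wtp_thresholds Willingness-to-pay thresholds in BRL per QAPY.
#' @return An object of class `econ_settings`.
#' @export
econ_settings <- function(discount_rate_costs = 0.05,
                          discount_rate_effects = 0.05,
                          horizon = 20L, cycle_length = 1,
                          cohort_size = 1e6,
                          wtp_thresholds = c(250, 450, 750, 3050)) {
  if (discount_rate_costs < 0 || discount_rate_effects < 0) {
    stop("discount rates must be >= 0", call. = FALSE)
  }
  if (horizon < 1 || horizon != round(horizon)) stop("`horizon` must be an integer >= 1", call. = FALSE)
  if (cycle_length != 1) stop("only annual cycles (cycle_length = 1) are supported", call. = FALSE)
  if (cohort_size < 1) stop("`cohort_size` must be >= 1", call. = FALSE)
  structure(
    list(discount_rate_costs = discount_rate_costs,
         discount_rate_effects = discount_rate_effects,
         horizon = as.integer(horizon), cycle_length = 1,
         cohort_size = cohort_size,
         wtp_thresholds = as.numeric(wtp_thresholds)),
    class = "econ_settings"
  )
}

#' Assemble and validate a decision problem
#'
#' Binds a shared ordered state list, two or more strategy arms and the
#' economic settings into a validated decision problem. All transition
#' matrices are checked against the state list and row-normalized.
#'
#' @param states List of [health_state()] objects (order fixes matrix rows).
#' @param strategies List of [strategy_model()] objects (>= 2).
#' @param settings An [econ_settings()].
#' @param initial_state Id of the state holding the whole cohort at cycle 0;
#'   must exist and be non-absorbing.
#' @param tol Row-sum tolerance passed to [validate_matrix()].
#' @return An object of class `decision_problem`.
#' @export
decision_problem <- function(states, strategies, settings,
                             initial_state = states[[1L]]$id, tol = 0.005) {
  stopifnot(is.list(states), length(states) >= 2L,
            is.list(strategies), length(strategies) >= 2L,
            inherits(settings, "econ_settings"))
  ids <- vapply(states, function(s) s$id, character(1L))
  if (anyDuplicated(ids)) stop("state ids must be unique", call. = FALSE)
  snames <- vapply(strategies, function(s) s$name, character(1L))
  if (anyDuplicated(snames)) stop("strategy names must be unique", call. = FALSE)
  absorbing <- vapply(states, function(s) s$absorbing, logical(1L))
  if (!initial_state %in% ids) stop("`initial_state` must be one of the state ids", call. = FALSE)
  if (absorbing[match(initial_state, ids)]) {
    stop("`initial_state` must not be absorbing", call. = FALSE)
  }
  k <- length(ids)
  strategies <- lapply(strategies, function(s) {
    m <- as.matrix(s$transition)
    if (nrow(m) != k || ncol(m) != k) {
      stop(sprintf("strategy '%s': transition matrix is %dx%d, expected %dx%d",
                   s$name, nrow(m), ncol(m), k, k), call. = FALSE)
    }
    dimnames(m) <- list(ids, ids)
    s$transition <- validate_matrix(m, tol = tol, absorbing = absorbing)
    pc <- s$costs$per_state_cycle_cost
    if (length(pc) == 1L && is.null(names(pc))) {
      pc <- stats::setNames(rep(as.numeric(pc), k), ids)
    } else {
      full <- stats::setNames(numeric(k), ids)
      full[names(pc)] <- pc
      pc <- full
    }
    s$costs$per_state_cycle_cost <- pc
    s
  })
  names(strategies) <- snames
  names(states) <- ids
  structure(
    list(states = states, strategies = strategies, settings = settings,
         initial_state = initial_state),
    class = "decision_problem"
  )
}

#' @export
print.decision_problem <- function(x, ...) {
  ids <- names(x$states)
  cat("<decision_problem>\n")
  cat("  states:    ", paste(ids, collapse = ", "),
      sprintf(" (absorbing: %s)\n",
              paste(ids[vapply(x$states, `[[`, logical(1L), "absorbing")],
                    collapse = ", ")))
  cat("  strategies:", paste(names(x$strategies), collapse = ", "), "\n")
  cat(sprintf("  horizon %d years, discount %.1f%% costs / %.1f%% effects, cohort %s\n",
              x$settings$horizon, 100 * x$settings$discount_rate_costs,
              100 * x$settings$discount_rate_effects,
              format(x$settings$cohort_size, big.mark = ",")))
  invisible(x)
}

# --- helpers shared by the accessors ---------------------------------------

state_ids <- function(problem) names(problem$states)

utility_multipliers <- function(problem) {
  vapply(problem$states, function(s) s$utility_multiplier, numeric(1L))
}

absorbing_flags <- function(problem) {
  vapply(problem$states, function(s) s$absorbing, logical(1L))
}

#' Sum a table of procedure tariffs
#'
#' Computes the total cost of an intervention from its per-procedure tariff
#' rows (unit value times quantity), as costed from a reference price table
#' such as SIGTAP. The total is rounded to centavos.
#'
#' @param rows Data frame with numeric columns `unit_value` (BRL) and
#'   `quantity`, one row per procedure.
#' @return Total cost in BRL, rounded to 2 decimals.
#' @export
sum_procedure_costs <- function(rows) {
  if (is.null(rows) || nrow(as.data.frame(rows)) == 0L) return(0)
  rows <- as.data.frame(rows)
  stopifnot(all(c("unit_value", "quantity") %in% names(rows)))
  if (any(rows$unit_value < 0)) stop("negative unit value", call. = FALSE)
  if (any(rows$quantity < 0)) stop("negative quantity", call. = FALSE)
  round(sum(rows$unit_value * rows$quantity), 2)
}
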