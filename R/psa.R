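#' Specification of parameter uncertainty for the PSA
#'
#' Standard second-order uncertainty choices for probabilistic sensitivity
#' analysis of a cohort model: transition rows on the probability simplex
#' via Dirichlet, non-negative costs via Gamma, utilities on `[0, 1]` via
#' Beta, all parameterized by their deterministic point estimate.
#'
#' \itemize{
#'   \item Transition rows: Dirichlet with concentration
#'     `transition_ess * point_estimates` over the live destinations; the
#'     probability of moving to an absorbing (death) state is held fixed at
#'     its point estimate when `fix_death = TRUE` (background mortality is
#'     not a treatment parameter), and the live sub-row is rescaled to the
#'     remaining mass.
#'   \item Costs: Gamma with mean at the point estimate and coefficient of
#'     variation `cost_cv`; zero-valued tariffs stay fixed at 0. A
#'     replacement cost equal to the initial cost is treated as the same
#'     parameter (one draw).
#'   \item Base QAPY and state utility multipliers: Beta matched to mean and
#'     `utility_cv` (variance clipped below the Beta-feasible maximum);
#'     multipliers of exactly 0 or 1 are degenerate and stay fixed. State
#'     multipliers are shared between arms, so one draw per iteration.
#' }
#'
#' @param iterations Number of Monte-Carlo iterations (>= 1).
#' @param seed Integer seed for the PSA's own RNG stream.
#' @param transition_ess Dirichlet effective sample size (may be `Inf` for
#'   a degenerate, fixed-transitions analysis).
#' @param cost_cv,utility_cv Coefficients of variation (0 disables sampling).
#' @param fix_death Hold transitions into absorbing states fixed.
#' @return Object of class `psa_spec`.
#' @export
psa_spec <- function(iterations = 10000L, seed = 42L,
                     transition_ess = 100, cost_cv = 0.20,
                     utility_cv = 0.10, fix_death = TRUE) {
  if (iterations < 1 || iterations != round(iterations)) {
    stop("`iterations` must be a whole number >= 1", call. = FALSE)
  }
  if (transition_ess <= 0) stop("`transition_ess` must be positive", call. = FALSE)
  if (cost_cv < 0 || utility_cv < 0) stop("coefficients of variation must be >= 0", call. = FALSE)
  structure(
    list(iterations = as.integer(iterations), seed = as.integer(seed),
         transition_ess = transition_ess, cost_cv = cost_cv,
         utility_cv = utility_cv, fix_death = isTRUE(fix_death)),
    class = "psa_spec"
  )
}

# Dirichlet draw via normalized Gamma variates; alpha entries of 0 give
# exact zeros, so structurally impossible transitions stay impossible.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s == 0) {
    out <- numeric(length(alpha))
    out[which.max(alpha)] <- 1
    return(out)
  }
  g / s
}

rgamma_mcv <- function(mean, cv) {
  if (mean == 0 || cv == 0) return(mean)
  shape <- 1 / cv^2
  stats::rgamma(1L, shape = shape, rate = shape / mean)
}

rbeta_mcv <- function(mean, cv) {
  if (mean <= 0 || mean >= 1 || cv == 0) return(mean)
  v <- (cv * mean)^2
  vmax <- mean * (1 - mean)
  if (v >= vmax) v <- 0.99 * vmax
  k <- vmax / v - 1
  stats::rbeta(1L, mean * k, (1 - mean) * k)
}

sample_transition_row <- function(row, absorbing, ess, fix_death) {
  if (!is.finite(ess)) return(row)
  if (fix_death) {
    p_abs <- sum(row[absorbing])
    live <- row[!absorbing]
    if (sum(live) <= 0) return(row)
    drawn <- rdirichlet1(ess * live / sum(live)) * (1 - p_abs)
    row[!absorbing] <- drawn
  } else {
    row <- rdirichlet1(ess * row)
  }
  row
}

#' Draw one parameter set from the uncertainty specification
#'
#' Replaces every uncertain parameter of `problem` by one random draw under
#' `spec`, using the current RNG state. Draw order is deterministic: shared
#' state multipliers first (in state order), then per strategy in listed
#' order its transition rows (origin order), costs, and base QAPY. Fixed
#' parameters (absorbing rows, death transitions, zero tariffs, degenerate
#' multipliers) are returned untouched.
#'
#' @param problem A validated [decision_problem()].
#' @param spec A [psa_spec()].
#' @return A new validated `decision_problem` with sampled parameters.
#' @export
sample_problem <- function(problem, spec) {
  stopifnot(inherits(problem, "decision_problem"), inherits(spec, "psa_spec"))
  abs_ <- absorbing_flags(problem)
  states <- lapply(problem$states, function(s) {
    s$utility_multiplier <- rbeta_mcv(s$utility_multiplier, spec$utility_cv)
    s
  })
  strategies <- lapply(problem$strategies, function(s) {
    m <- s$transition
    for (i in which(!abs_)) {
      m[i, ] <- sample_transition_row(m[i, ], abs_, spec$transition_ess,
                                      spec$fix_death)
    }
    s$transition <- m
    cs <- s$costs
    tied <- isTRUE(all.equal(cs$replacement_cost, cs$initial_cost))
    cs$initial_cost <- rgamma_mcv(cs$initial_cost, spec$cost_cv)
    cs$replacement_cost <- if (tied) cs$initial_cost
                           else rgamma_mcv(cs$replacement_cost, spec$cost_cv)
    cs$per_state_cycle_cost <- vapply(cs$per_state_cycle_cost, rgamma_mcv,
                                      numeric(1L), cv = spec$cost_cv)
    s$costs <- cs
    s$base_qapy <- rbeta_mcv(s$base_qapy, spec$utility_cv)
    s
  })
  decision_problem(states, strategies, problem$settings,
                   initial_state = problem$initial_state, tol = 1e-6)
}

#' Probabilistic sensitivity analysis by Monte-Carlo propagation
#'
#' For each iteration, draws one parameter set via [sample_problem()]
#' (parameters shared between arms — the state utility multipliers — are
#' drawn once), runs both cohort traces, and records the incremental cost
#' and effect of the last strategy versus the first. The run has its own
#' RNG stream seeded from `spec$seed`, so results are reproducible
#' bit-for-bit; the caller's RNG state is left untouched.
#'
#' @param problem A two-strategy [decision_problem()].
#' @param spec A [psa_spec()].
#' @param conventions A [cycle_conventions()].
#' @return Object of class `psa_result`: list with `samples` (data frame
#'   `iteration`, `delta_cost`, `delta_effect`), `seed`, `spec`,
#'   `failures` (count of iterations whose sampled problem failed
#'   validation; their rows carry `NA`).
#' @export
run_psa <- function(problem, spec = psa_spec(),
                    conventions = cycle_conventions()) {
  stopifnot(inherits(problem, "decision_problem"))
  nm <- names(problem$strategies)
  if (length(nm) < 2L) stop("PSA needs at least two strategies", call. = FALSE)
  ref <- nm[1L]; comp <- nm[length(nm)]

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  n <- spec$iterations
  dc <- numeric(n); de <- numeric(n); failures <- 0L
  for (i in seq_len(n)) {
    res <- tryCatch({
      p <- sample_problem(problem, spec)
      a <- run_strategy(p, ref, conventions)
      b <- run_strategy(p, comp, conventions)
      c(b$total_cost_pp - a$total_cost_pp,
        b$total_effect_pp - a$total_effect_pp)
    }, error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
      dc[i] <- NA_real_; de[i] <- NA_real_
    } else {
      dc[i] <- res[1L]; de[i] <- res[2L]
    }
  }
  structure(
    list(samples = data.frame(iteration = seq_len(n), delta_cost = dc,
                              delta_effect = de),
         reference = ref, comparator = comp,
         seed = spec$seed, spec = spec, conventions = conventions,
         failures = failures),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %s vs %s: %d iterations (seed %d, %d failures)\n",
              x$comparator, x$reference, nrow(x$samples), x$seed, x$failures))
  cat(sprintf("  mean incremental cost   %10.2f BRL\n",
              mean(x$samples$delta_cost, na.rm = TRUE)))
  cat(sprintf("  mean incremental effect %10.4f QAPY\n",
              mean(x$samples$delta_effect, na.rm = TRUE)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA iterations in
#' which the comparator has strictly positive incremental net monetary
#' benefit, `lambda * delta_effect - delta_cost > 0`.
#'
#' @param result A [run_psa()] result.
#' @param lambda_grid Non-empty numeric vector of thresholds (BRL/QAPY).
#' @return Data frame with columns `lambda` and `probability`.
#' @export
ceac <- function(result, lambda_grid) {
  stopifnot(inherits(result, "psa_result"))
  if (length(lambda_grid) == 0L) stop("`lambda_grid` must be non-empty", call. = FALSE)
  s <- result$samples[stats::complete.cases(result$samples), ]
  if (nrow(s) == 0L) stop("no complete PSA samples", call. = FALSE)
  prob <- vapply(lambda_grid, function(l) {
    mean(l * s$delta_effect - s$delta_cost > 0)
  }, numeric(1L))
  data.frame(lambda = as.numeric(lambda_grid), probability = prob)
}

#' Cost-effectiveness plane summary
#'
#' Quadrant proportions of the (incremental effect, incremental cost) cloud
#' (NE: more effective & more costly; SE: more effective & cheaper; NW:
#' less effective & more costly; SW: less effective & cheaper; boundary
#' points count toward the N/E sides) plus means and central 95% intervals.
#'
#' @param result A [run_psa()] result.
#' @return List with `quadrants` (named proportions summing to 1),
#'   `mean_delta_cost`, `mean_delta_effect`, `ci_delta_cost`,
#'   `ci_delta_effect` (2.5% and 97.5% quantiles).
#' @export
ce_plane_summary <- function(result) {
  stopifnot(inherits(result, "psa_result"))
  s <- result$samples[stats::complete.cases(result$samples), ]
  east <- s$delta_effect >= 0
  north <- s$delta_cost >= 0
  quad <- c(NE = mean(east & north), SE = mean(east & !north),
            NW = mean(!east & north), SW = mean(!east & !north))
  list(
    quadrants = quad,
    mean_delta_cost = mean(s$delta_cost),
    mean_delta_effect = mean(s$delta_effect),
    ci_delta_cost = stats::quantile(s$delta_cost, c(0.025, 0.975), names = FALSE),
    ci_delta_effect = stats::quantile(s$delta_effect, c(0.025, 0.975), names = FALSE)
  )
}
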