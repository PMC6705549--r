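#' Serialize a decision problem to a plain list
#'
#' Produces the list representation written by [write_problem()] and read
#' back by [read_problem()]; round-trips losslessly for any valid problem.
#'
#' @param problem A validated [decision_problem()].
#' @return A nested list with keys `states`, `strategies`, `settings`,
#'   `initial_state`.
#' @export
problem_to_list <- function(problem) {
  stopifnot(inherits(problem, "decision_problem"))
  list(
    states = lapply(unname(problem$states), function(s) {
      list(id = s$id, label = s$label, absorbing = s$absorbing,
           utility_multiplier = s$utility_multiplier)
    }),
    strategies = lapply(unname(problem$strategies), function(s) {
      list(
        name = s$name,
        transition = apply(s$transition, 1L, as.list, simplify = FALSE),
        costs = list(
          initial_cost = s$costs$initial_cost,
          replacement_cost = s$costs$replacement_cost,
          replacement_interval = s$costs$replacement_interval,
          per_state_cycle_cost = as.list(s$costs$per_state_cycle_cost)
        ),
        base_qapy = s$base_qapy
      )
    }),
    settings = list(
      discount_rate_costs = problem$settings$discount_rate_costs,
      discount_rate_effects = problem$settings$discount_rate_effects,
      horizon = problem$settings$horizon,
      cycle_length = problem$settings$cycle_length,
      cohort_size = problem$settings$cohort_size,
      wtp_thresholds = problem$settings$wtp_thresholds
    ),
    initial_state = problem$initial_state
  )
}

problem_from_list <- function(doc, tol = 0.005) {
  need <- c("states", "strategies", "settings", "initial_state")
  miss <- setdiff(need, names(doc))
  if (length(miss)) {
    stop(sprintf("scenario document is missing key(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  states <- lapply(doc$states, function(s) {
    if (is.null(s$id)) stop("states[]: missing `id`", call. = FALSE)
    health_state(id = s$id,
                 label = if (is.null(s$label)) s$id else s$label,
                 absorbing = isTRUE(s$absorbing),
                 utility_multiplier =
                   if (is.null(s$utility_multiplier)) {
                     if (isTRUE(s$absorbing)) 0 else 1
                   } else s$utility_multiplier)
  })
  k <- length(states)
  strategies <- lapply(doc$strategies, function(s) {
    if (is.null(s$name)) stop("strategies[]: missing `name`", call. = FALSE)
    m <- do.call(rbind, lapply(s$transition, function(r) as.numeric(unlist(r))))
    if (is.null(m) || nrow(m) != k || ncol(m) != k) {
      stop(sprintf("strategies[%s].transition: expected a %dx%d nested list",
                   s$name, k, k), call. = FALSE)
    }
    cs <- s$costs
    if (is.null(cs$initial_cost)) {
      stop(sprintf("strategies[%s].costs: missing `initial_cost`", s$name),
           call. = FALSE)
    }
    pc <- cs$per_state_cycle_cost
    pc <- if (is.null(pc)) 0 else unlist(pc)
    costs <- cost_schedule(
      initial_cost = cs$initial_cost,
      replacement_cost = if (is.null(cs$replacement_cost)) cs$initial_cost
                         else cs$replacement_cost,
      replacement_interval = if (is.null(cs$replacement_interval)) 5L
                             else cs$replacement_interval,
      per_state_cycle_cost = pc
    )
    if (is.null(s$base_qapy)) {
      stop(sprintf("strategies[%s]: missing `base_qapy`", s$name), call. = FALSE)
    }
    strategy_model(s$name, m, costs, s$base_qapy)
  })
  st <- doc$settings
  settings <- econ_settings(
    discount_rate_costs = if (is.null(st$discount_rate_costs)) 0.05 else st$discount_rate_costs,
    discount_rate_effects = if (is.null(st$discount_rate_effects)) 0.05 else st$discount_rate_effects,
    horizon = if (is.null(st$horizon)) 20L else st$horizon,
    cycle_length = if (is.null(st$cycle_length)) 1 else st$cycle_length,
    cohort_size = if (is.null(st$cohort_size)) 1e6 else st$cohort_size,
    wtp_thresholds = if (is.null(st$wtp_thresholds)) c(250, 450, 750, 3050)
                     else unlist(st$wtp_thresholds)
  )
  decision_problem(states, strategies, settings,
                   initial_state = doc$initial_state, tol = tol)
}

#' Read a decision problem from a YAML or JSON scenario file
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario document.
#' @param tol Row-sum tolerance for transition matrices.
#' @return A validated [decision_problem()].
#' @export
read_problem <- function(path, tol = 0.005) {
  if (!file.exists(path)) stop(sprintf("scenario file not found: %s", path), call. = FALSE)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  problem_from_list(doc, tol = tol)
}

#' Write a decision problem to a YAML or JSON scenario file
#'
#' @param problem A validated [decision_problem()].
#' @param path Output path; format chosen by extension (`.json` or YAML).
#' @return `path`, invisibly.
#' @export
write_problem <- function(problem, path) {
  doc <- problem_to_list(problem)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(doc, path, precision = 15L)
  }
  invisible(path)
}
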