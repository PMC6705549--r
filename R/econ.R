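#' Cost-effectiveness ratio
#'
#' @param cost_pp Discounted cost per patient (BRL).
#' @param effect_pp Discounted effectiveness per patient (QAPY); must be > 0.
#' @return `cost_pp / effect_pp` in BRL per QAPY.
#' @export
cer <- function(cost_pp, effect_pp) {
  if (any(effect_pp <= 0)) stop("effectiveness must be positive for a CER", call. = FALSE)
  cost_pp / effect_pp
}

#' Net monetary benefit
#'
#' @param cost_pp,effect_pp Discounted per-patient cost (BRL) and effect (QAPY).
#' @param lambda Willingness-to-pay threshold in BRL per QAPY (>= 0).
#' @return `lambda * effect_pp - cost_pp` in BRL.
#' @export
nmb <- function(cost_pp, effect_pp, lambda) {
  stopifnot(all(lambda >= 0))
  lambda * effect_pp - cost_pp
}

#' Incremental cost-effectiveness of one strategy over another
#'
#' Computes incremental cost and effectiveness of the comparator arm `b`
#' over the reference arm `a`, the ICER where defined, a dominance verdict,
#' and cost-effectiveness at each willingness-to-pay threshold. Ratios are
#' taken on unrounded per-patient totals; round only for presentation.
#' When one arm is both cheaper and more effective the ICER is reported for
#' completeness but dominance is the decision quantity. Ties
#' (`icer == lambda`) count as cost-effective.
#'
#' @param a Reference [run_strategy()] outcome (e.g. standard of care).
#' @param b Comparator outcome under identical settings and conventions.
#' @param wtp Numeric vector of thresholds (BRL/QAPY); defaults to the
#'   bundled grid 250/450/750/3050.
#' @return Object of class `icer_result` with fields `reference`,
#'   `comparator`, `delta_cost`, `delta_effect`, `icer` (`NA` when
#'   `delta_effect == 0`), `dominance` (one of `"comparator_dominates"`,
#'   `"reference_dominates"`, `"trade_off"`) and `cost_effective_at`, a
#'   named logical vector over `wtp`.
#' @export
icer <- function(a, b, wtp = c(250, 450, 750, 3050)) {
  stopifnot(inherits(a, "strategy_outcome"), inherits(b, "strategy_outcome"))
  if (!identical(a$conventions, b$conventions)) {
    stop("outcomes were computed under different cycle conventions", call. = FALSE)
  }
  dc <- b$total_cost_pp - a$total_cost_pp
  de <- b$total_effect_pp - a$total_effect_pp
  ratio <- if (de != 0) dc / de else NA_real_
  dominance <- if (dc <= 0 && de >= 0 && (dc < 0 || de > 0)) {
    "comparator_dominates"
  } else if (dc >= 0 && de <= 0 && (dc > 0 || de < 0)) {
    "reference_dominates"
  } else {
    "trade_off"
  }
  ce <- vapply(wtp, function(l) {
    if (dominance == "comparator_dominates") TRUE
    else if (dominance == "reference_dominates") FALSE
    else de > 0 && ratio <= l
  }, logical(1L))
  names(ce) <- format(wtp, trim = TRUE, scientific = FALSE)
  structure(
    list(reference = a$strategy, comparator = b$strategy,
         delta_cost = dc, delta_effect = de, icer = ratio,
         dominance = dominance, cost_effective_at = ce),
    class = "icer_result"
  )
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("<icer_result> %s vs %s\n", x$comparator, x$reference))
  cat(sprintf("  incremental cost   %10.2f BRL\n", x$delta_cost))
  cat(sprintf("  incremental effect %10.4f QAPY\n", x$delta_effect))
  if (x$dominance == "trade_off") {
    cat(sprintf("  ICER               %10.2f BRL/QAPY\n", x$icer))
  } else {
    cat(sprintf("  dominance: %s\n", x$dominance))
  }
  ce <- x$cost_effective_at
  cat("  cost-effective at lambda:",
      paste(sprintf("%s=%s", names(ce), ifelse(ce, "yes", "no")), collapse = ", "),
      "\n")
  invisible(x)
}

#' Deterministic cost-effectiveness analysis of a decision problem
#'
#' Runs every strategy arm through the cohort engine and assembles the
#' standard deterministic results table — per-patient discounted cost and
#' effectiveness, incremental quantities versus the first (reference)
#' strategy, CER and ICER — plus the pairwise [icer()] result of the final
#' arm against the reference.
#'
#' @param problem A [decision_problem()]; the first strategy is the
#'   reference (least costly standard of care by convention).
#' @param conventions A [cycle_conventions()].
#' @return Object of class `deterministic_result`: list with `table` (data
#'   frame, one row per strategy), `icer` (an `icer_result`), and
#'   `outcomes` (list of `strategy_outcome`).
#' @export
run_deterministic <- function(problem, conventions = cycle_conventions()) {
  stopifnot(inherits(problem, "decision_problem"))
  nm <- names(problem$strategies)
  outcomes <- lapply(nm, run_strategy, problem = problem,
                     conventions = conventions)
  names(outcomes) <- nm
  ref <- outcomes[[1L]]
  tab <- do.call(rbind, lapply(outcomes, function(o) {
    data.frame(
      strategy = o$strategy,
      cost = o$total_cost_pp,
      incremental_cost = o$total_cost_pp - ref$total_cost_pp,
      effect = o$total_effect_pp,
      incremental_effect = o$total_effect_pp - ref$total_effect_pp,
      cer = cer(o$total_cost_pp, o$total_effect_pp),
      stringsAsFactors = FALSE
    )
  }))
  tab$icer <- NA_real_
  for (i in seq_along(outcomes)[-1L]) {
    tab$icer[i] <- icer(ref, outcomes[[i]],
                        wtp = problem$settings$wtp_thresholds)$icer
  }
  rownames(tab) <- NULL
  structure(
    list(table = tab,
         icer = icer(ref, outcomes[[length(outcomes)]],
                     wtp = problem$settings$wtp_thresholds),
         outcomes = outcomes,
         conventions = conventions),
    class = "deterministic_result"
  )
}

#' @export
print.deterministic_result <- function(x, ...) {
  cat("<deterministic_result>\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1L))
  tab[num] <- lapply(tab[num], round, digits = 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Deterministic results under every cycle-convention combination
#'
#' Sensitivity of the deterministic totals and ICER to the accounting
#' conventions of [cycle_conventions()].
#'
#' @param problem A two-or-more-strategy [decision_problem()].
#' @return Data frame: one row per convention combination with the
#'   per-strategy costs/effects (columns `cost_<name>`, `effect_<name>`),
#'   `delta_cost`, `delta_effect` and `icer` of the last arm versus the
#'   first.
#' @export
run_conventions_grid <- function(problem) {
  g <- conventions_grid()
  rows <- lapply(g$conventions, function(cv) {
    det <- run_deterministic(problem, cv)
    tab <- det$table
    out <- data.frame(effect_timing = cv$effect_timing,
                      half_cycle_correction = cv$half_cycle_correction,
                      replacement_payers = cv$replacement_payers,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(tab))) {
      out[[paste0("cost_", tab$strategy[i])]] <- tab$cost[i]
      out[[paste0("effect_", tab$strategy[i])]] <- tab$effect[i]
    }
    out$delta_cost <- det$icer$delta_cost
    out$delta_effect <- det$icer$delta_effect
    out$icer <- det$icer$icer
    out
  })
  do.call(rbind, rows)
}
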