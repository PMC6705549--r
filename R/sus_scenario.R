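#' SIGTAP tariff rows for the bundled SUS scenario
#'
#' Per-procedure 2018 SIGTAP tariffs (BRL) making up the initial procedure
#' cost of each arm of the bundled mandibular-edentulism scenario:
#' conventional complete denture (CTP) and two-implant overdenture (ISTP).
#' Consultations priced at BRL 0 reflect unpaid primary-care visits in the
#' federal tariff table.
#'
#' @param strategy `"CTP"` or `"ISTP"`.
#' @return Data frame with columns `procedure`, `unit_value`, `quantity`.
#' @seealso [sum_procedure_costs()], [sus_edentulism_problem()]
#' @export
sus_tariff_rows <- function(strategy = c("CTP", "ISTP")) {
  strategy <- match.arg(strategy)
  if (strategy == "CTP") {
    data.frame(
      procedure = c("panoramic radiograph",
                    "primary-care consultation (non-physician)",
                    "specialized-care consultation (non-physician)",
                    "occlusal adjustment",
                    "complete mandibular prosthesis"),
      unit_value = c(9.03, 0, 6.30, 0, 150.00),
      quantity = c(1, 1, 6, 1, 1)
    )
  } else {
    data.frame(
      procedure = c("computed tomography of face/sinuses/TMJ",
                    "primary-care consultation (non-physician)",
                    "specialized-care consultation (non-physician)",
                    "osseointegrated dental implant",
                    "dental prosthesis on implant",
                    "occlusal adjustment"),
      unit_value = c(173.50, 0, 6.30, 260.10, 300.00, 0),
      quantity = c(1, 1, 9, 2, 1, 1)
    )
  }
}

#' Bundled scenario: mandibular overdenture vs conventional denture in SUS
#'
#' Builds the fully parameterized reference decision problem comparing
#' rehabilitation of mandibular edentulism by conventional complete denture
#' (CTP) against a two-implant-supported overdenture (ISTP), from the
#' perspective of the Brazilian Unified Health System.
#'
#' Four shared health states: A = rehabilitated without complications
#' (utility multiplier 1), B = rehabilitated with repairable damage (0.75,
#' i.e. a 25% QAPY decrement), C = treatment failure (0.50), and D =
#' non-treatment-related death (absorbing, 0). Annual transition
#' probabilities are strategy-specific with a flat background mortality of
#' 0.0075 from every living state. Initial procedure costs are the SIGTAP
#' tariff totals (BRL 196.83 for CTP, BRL 1,050.40 for ISTP), with full-cost
#' prosthesis replacement every 5 years. Base QAPY is 0.79 (CTP) and 0.94
#' (ISTP). Settings: 5% annual discounting of costs and effects, 20-year
#' horizon, cohort of 1,000,000 patients aged 55, willingness-to-pay grid
#' 250 / 450 / 750 / 3,050 BRL per QAPY.
#'
#' Two printed rows (CTP A-row, ISTP B-row) sum to 0.9999 at four decimals
#' and are proportionally renormalized by the validator.
#'
#' @return A validated [decision_problem()].
#' @export
sus_edentulism_problem <- function() {
  states <- list(
    health_state("A", "rehabilitated without complications",
                 utility_multiplier = 1.00),
    health_state("B", "rehabilitated with repairable damage",
                 utility_multiplier = 0.75),
    health_state("C", "treatment failure",
                 utility_multiplier = 0.50),
    health_state("D", "non-treatment-related death", absorbing = TRUE)
  )
  ctp_m <- matrix(c(
    0.1697, 0.5121, 0.3106, 0.0075,
    0.5403, 0.2231, 0.2291, 0.0075,
    0.0000, 0.0000, 0.9925, 0.0075,
    0.0000, 0.0000, 0.0000, 1.0000
  ), nrow = 4L, byrow = TRUE)
  istp_m <- matrix(c(
    0.9154, 0.0768, 0.0003, 0.0075,
    0.6519, 0.2909, 0.0496, 0.0075,
    0.0000, 0.0000, 0.9925, 0.0075,
    0.0000, 0.0000, 0.0000, 1.0000
  ), nrow = 4L, byrow = TRUE)
  strategies <- list(
    strategy_model(
      "CTP", ctp_m,
      cost_schedule(initial_cost = sum_procedure_costs(sus_tariff_rows("CTP")),
                    replacement_interval = 5L),
      base_qapy = 0.79
    ),
    strategy_model(
      "ISTP", istp_m,
      cost_schedule(initial_cost = sum_procedure_costs(sus_tariff_rows("ISTP")),
                    replacement_interval = 5L),
      base_qapy = 0.94
    )
  )
  decision_problem(states, strategies, econ_settings(), initial_state = "A")
}
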