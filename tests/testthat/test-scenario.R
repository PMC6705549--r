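test_that("transition rows are proportionally renormalized to sum exactly 1", {
  row <- c(0.1697, 0.5121, 0.3106, 0.0075) # printed sum 0.9999
  m <- rbind(row, c(0.5403, 0.2231, 0.2291, 0.0075),
             c(0, 0, 0.9925, 0.0075), c(0, 0, 0, 1))
  out <- validate_matrix(m, absorbing = c(FALSE, FALSE, FALSE, TRUE))
  expect_true(all(abs(rowSums(out) - 1) < 1e-12))
  expect_equal(out[1L, ], row / 0.9999, tolerance = 1e-12, ignore_attr = TRUE)
  # rows already summing to 1 are unchanged
  expect_identical(out[2L, ], m[2L, ])
  # absorbing identity row untouched
  expect_identical(out[4L, ], c(0, 0, 0, 1))
})

test_that("matrix validation rejects malformed inputs", {
  bad_sum <- rbind(c(0.5, 0.3, 0, 0), c(0, 0.5, 0.5, 0),
                   c(0, 0, 1, 0), c(0, 0, 0, 1))
  expect_error(validate_matrix(bad_sum), "sums to 0.8")
  neg <- rbind(c(1.2, -0.2), c(0, 1))
  expect_error(validate_matrix(neg), "negative")
  expect_error(validate_matrix(matrix(1, 2, 3)), "square")
  not_ident <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  expect_error(validate_matrix(not_ident, absorbing = c(FALSE, TRUE)),
               "identity")
})

test_that("procedure tariff rows sum to the SIGTAP intervention totals", {
  expect_identical(sum_procedure_costs(sus_tariff_rows("CTP")), 196.83)
  expect_identical(sum_procedure_costs(sus_tariff_rows("ISTP")), 1050.40)
  expect_identical(sum_procedure_costs(data.frame(unit_value = numeric(),
                                                  quantity = numeric())), 0)
  # order invariance and linearity in quantities
  rows <- sus_tariff_rows("ISTP")
  expect_identical(sum_procedure_costs(rows[sample(nrow(rows)), ]),
                   sum_procedure_costs(rows))
  doubled <- transform(rows, quantity = 2 * quantity)
  expect_equal(sum_procedure_costs(doubled), 2 * sum_procedure_costs(rows))
  expect_error(sum_procedure_costs(data.frame(unit_value = -1, quantity = 1)),
               "negative")
})

test_that("the bundled SUS scenario is assembled as documented", {
  p <- sus_edentulism_problem()
  expect_length(p$states, 4L)
  expect_length(p$strategies, 2L)
  expect_identical(p$settings$horizon, 20L)
  expect_identical(p$settings$discount_rate_costs, 0.05)
  expect_identical(p$settings$cohort_size, 1e6)
  expect_identical(p$initial_state, "A")
  expect_identical(p$strategies$CTP$costs$initial_cost, 196.83)
  expect_identical(p$strategies$ISTP$costs$initial_cost, 1050.40)
  expect_identical(p$strategies$ISTP$transition["A", "A"], 0.9154)
  expect_identical(p$strategies$CTP$base_qapy, 0.79)
  expect_identical(p$strategies$ISTP$base_qapy, 0.94)
  mult <- vapply(p$states, function(s) s$utility_multiplier, numeric(1L))
  expect_identical(unname(mult), c(1, 0.75, 0.5, 0))
  # flat background mortality in every live-state row (to printed precision)
  for (s in p$strategies) {
    expect_equal(unname(s$transition[1:3, "D"]), rep(0.0075, 3L),
                 tolerance = 1e-3)
  }
  expect_true(all(abs(rowSums(p$strategies$CTP$transition) - 1) < 1e-12))
})

test_that("decision problems round-trip through YAML and JSON", {
  for (seed in c(2, 7)) {
    p <- random_problem(4L, seed = seed)
    for (ext in c("yaml", "json")) {
      f <- tempfile(fileext = paste0(".", ext))
      write_problem(p, f)
      q <- read_problem(f)
      expect_equal(problem_to_list(q), problem_to_list(p), tolerance = 1e-9)
      # serialize(load(doc)) is a fixed point
      f2 <- tempfile(fileext = paste0(".", ext))
      write_problem(q, f2)
      expect_equal(problem_to_list(read_problem(f2)), problem_to_list(q),
                   tolerance = 1e-12)
      unlink(c(f, f2))
    }
  }
})

test_that("the bundled scenario file loads to the in-code builder's problem", {
  f <- system.file("extdata", "sus_edentulism.yaml", package = "oralcea")
  expect_true(nzchar(f))
  q <- read_problem(f)
  expect_equal(problem_to_list(q), problem_to_list(sus_edentulism_problem()),
               tolerance = 1e-12)
})

test_that("scenario documents with structural faults are rejected by path", {
  p <- sus_edentulism_problem()
  doc <- problem_to_list(p)
  doc$strategies[[1L]]$transition[[1L]] <- list(0.5, 0.2, 0.05, 0.05) # sums 0.8
  f <- tempfile(fileext = ".yaml"); yaml::write_yaml(doc, f)
  expect_error(read_problem(f), "sums to 0.8")
  doc2 <- problem_to_list(p); doc2$strategies[[2L]]$base_qapy <- NULL
  f2 <- tempfile(fileext = ".yaml"); yaml::write_yaml(doc2, f2)
  expect_error(read_problem(f2), "base_qapy")
  doc3 <- problem_to_list(p); doc3$states <- NULL
  f3 <- tempfile(fileext = ".yaml"); yaml::write_yaml(doc3, f3)
  expect_error(read_problem(f3), "states")
  expect_error(read_problem(tempfile()), "not found")
  unlink(c(f, f2, f3))
})

test_that("problem invariants are enforced at assembly", {
  p <- sus_edentulism_problem()
  dup <- p$states; dup[[2L]] <- dup[[1L]]
  expect_error(decision_problem(dup, p$strategies, p$settings, "A"), "unique")
  expect_error(decision_problem(p$states, p$strategies, p$settings, "D"),
               "absorbing")
  expect_error(decision_problem(p$states, p$strategies, p$settings, "Z"),
               "state ids")
  expect_error(health_state("D", absorbing = TRUE, utility_multiplier = 0.5),
               "multiplier 0")
  expect_error(cost_schedule(-1), "non-negative")
  expect_error(cost_schedule(10, replacement_interval = 0), ">= 1")
  expect_error(econ_settings(horizon = 0), "horizon")
})
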