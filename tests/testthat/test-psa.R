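test_that("a zero-variance uncertainty spec collapses to the deterministic run", {
  p <- sus_edentulism_problem()
  det <- run_deterministic(p)
  r <- run_psa(p, psa_spec(iterations = 5L, seed = 1L, transition_ess = Inf,
                           cost_cv = 0, utility_cv = 0))
  expect_identical(r$failures, 0L)
  expect_true(all(abs(r$samples$delta_cost - det$icer$delta_cost) < 1e-9))
  expect_true(all(abs(r$samples$delta_effect - det$icer$delta_effect) < 1e-9))
})

test_that("the PSA is reproducible bit-for-bit from its seed", {
  p <- sus_edentulism_problem()
  r1 <- run_psa(p, psa_spec(iterations = 40L, seed = 99L))
  r2 <- run_psa(p, psa_spec(iterations = 40L, seed = 99L))
  expect_identical(r1$samples, r2$samples)
  r3 <- run_psa(p, psa_spec(iterations = 40L, seed = 100L))
  expect_false(identical(r1$samples, r3$samples))
})

test_that("sampled problems stay on their domains", {
  p <- sus_edentulism_problem()
  set.seed(5)
  for (i in 1:50) {
    q <- sample_problem(p, psa_spec())
    for (s in q$strategies) {
      expect_true(all(s$transition >= 0 & s$transition <= 1))
      expect_true(all(abs(rowSums(s$transition) - 1) < 1e-9))
      # death transitions held fixed at the point estimate
      expect_equal(unname(s$transition[1:3, "D"]),
                   unname(p$strategies[[s$name]]$transition[1:3, "D"]))
      expect_gte(s$costs$initial_cost, 0)
      expect_true(s$base_qapy >= 0 && s$base_qapy <= 1)
    }
    mult <- vapply(q$states, function(s) s$utility_multiplier, numeric(1L))
    expect_true(all(mult >= 0 & mult <= 1))
    # degenerate multipliers (0 and 1) are fixed
    expect_identical(unname(mult[c("A", "D")]), c(1, 0))
  }
})

test_that("Dirichlet row means converge to the point estimates", {
  p <- sus_edentulism_problem()
  row <- p$strategies$CTP$transition["A", ]
  abs_ <- c(FALSE, FALSE, FALSE, TRUE)
  n <- 10000L
  set.seed(17)
  draws <- t(replicate(n, sample_transition_row(row, abs_, ess = 100,
                                                fix_death = TRUE)))
  se <- apply(draws, 2L, stats::sd) / sqrt(n)
  live <- !abs_
  expect_true(all(abs(colMeans(draws)[live] - row[live]) < 3 * se[live] + 1e-12))
  expect_true(all(draws[, "D"] == row[["D"]]))
  # concentration limit: huge ess pins the draws to the point estimate
  tight <- t(replicate(200, sample_transition_row(row, abs_, ess = 1e8,
                                                  fix_death = TRUE)))
  expect_lt(max(abs(sweep(tight, 2L, row))), 1e-3)
})

test_that("PSA sample means are consistent with the deterministic increments", {
  p <- sus_edentulism_problem()
  det <- run_deterministic(p)
  r <- run_psa(p, psa_spec(iterations = 2000L, seed = 8L))
  s <- r$samples
  se_e <- stats::sd(s$delta_effect) / sqrt(nrow(s))
  expect_lt(abs(mean(s$delta_effect) - det$icer$delta_effect), 3 * se_e)
  se_c <- stats::sd(s$delta_cost) / sqrt(nrow(s))
  expect_lt(abs(mean(s$delta_cost) - det$icer$delta_cost), 3 * se_c)
})

test_that("the CEAC matches its brute-force definition and limits", {
  dc <- c(-5, 3, 10, -2, 8, 0.5)
  de <- c(1, -0.5, 2, 0.2, -1, 0.1)
  r <- fake_psa(dc, de)
  grid <- c(0, 1, 5, 1e9)
  curve <- ceac(r, grid)
  brute <- vapply(grid, function(l) mean(l * de - dc > 0), numeric(1L))
  expect_identical(curve$probability, brute)
  expect_identical(curve$probability[1L], mean(dc < 0))
  expect_identical(curve$probability[length(grid)], mean(de > 0))
  expect_error(ceac(r, numeric()), "non-empty")
})

test_that("the CEAC is non-decreasing in lambda when every draw gains effect", {
  p <- sus_edentulism_problem()
  r <- run_psa(p, psa_spec(iterations = 300L, seed = 4L))
  s <- r$samples[r$samples$delta_effect > 0, ]
  rr <- fake_psa(s$delta_cost, s$delta_effect)
  curve <- ceac(rr, seq(0, 5000, by = 100))
  expect_true(all(diff(curve$probability) >= 0))
})

test_that("CE-plane quadrants partition the cloud", {
  r <- fake_psa(c(5, 5, -5, -5), c(1, -1, 1, -1))
  q <- ce_plane_summary(r)$quadrants
  expect_identical(unname(q), rep(0.25, 4L))
  expect_identical(sum(q), 1)
  set.seed(12)
  sym <- fake_psa(stats::rnorm(4000), stats::rnorm(4000))
  qs <- ce_plane_summary(sym)$quadrants
  expect_identical(sum(qs), 1)
  expect_true(all(abs(qs - 0.25) < 3 * sqrt(0.25 * 0.75 / 4000)))
  ne <- fake_psa(abs(stats::rnorm(50)) + 1, abs(stats::rnorm(50)) + 1)
  expect_identical(unname(ce_plane_summary(ne)$quadrants["NE"]), 1)
})

test_that("bundled-scenario PSA lives in the northeast quadrant", {
  p <- sus_edentulism_problem()
  r <- run_psa(p, psa_spec(iterations = 500L, seed = 23L))
  sm <- ce_plane_summary(r)
  expect_gt(sm$quadrants[["NE"]], 0.95)
  expect_gt(sm$mean_delta_cost, 0)
  expect_gt(sm$mean_delta_effect, 0)
  expect_true(sm$ci_delta_cost[1L] < sm$mean_delta_cost &&
                sm$mean_delta_cost < sm$ci_delta_cost[2L])
})

test_that("invalid uncertainty specs are rejected", {
  expect_error(psa_spec(iterations = 0), "iterations")
  expect_error(psa_spec(transition_ess = -1), "positive")
  expect_error(psa_spec(cost_cv = -0.1), "variation")
})
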