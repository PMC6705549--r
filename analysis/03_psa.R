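#!/usr/bin/env Rscript
# Probabilistic sensitivity analysis of the reference scenario: Monte-Carlo
# propagation of Dirichlet (transitions), Gamma (costs) and Beta (utilities)
# parameter uncertainty through both cohort arms, cost-effectiveness plane
# summary and acceptability curve. Writes results/psa_samples.csv,
# results/ceac.csv, results/ce_plane.json and (if ggplot2 is available)
# the corresponding figures.
#
# Desk-scale default: 10,000 iterations (override with --iterations N).

suppressMessages(library(oralcea))
dir.create("results", showWarnings = FALSE)

args <- commandArgs(trailingOnly = TRUE)
iter_arg <- which(args == "--iterations")
iterations <- if (length(iter_arg) == 1L) as.integer(args[iter_arg + 1L]) else 10000L
seed_arg <- which(args == "--seed")
seed <- if (length(seed_arg) == 1L) as.integer(args[seed_arg + 1L]) else 42L

problem <- sus_edentulism_problem()
spec <- psa_spec(iterations = iterations, seed = seed)
cat(sprintf("running PSA: %d iterations, seed %d ...\n", iterations, seed))
psa <- run_psa(problem, spec)
print(psa)
utils::write.csv(psa$samples, "results/psa_samples.csv", row.names = FALSE)

sm <- ce_plane_summary(psa)
cat(sprintf("CE plane: NE %.1f%%, SE %.1f%%, NW %.1f%%, SW %.1f%%\n",
            100 * sm$quadrants[["NE"]], 100 * sm$quadrants[["SE"]],
            100 * sm$quadrants[["NW"]], 100 * sm$quadrants[["SW"]]))
cat(sprintf("mean incremental cost %.2f BRL (95%% CI %.2f-%.2f)\n",
            sm$mean_delta_cost, sm$ci_delta_cost[1L], sm$ci_delta_cost[2L]))
cat(sprintf("mean incremental effect %.3f QAPY (95%% CI %.3f-%.3f)\n",
            sm$mean_delta_effect, sm$ci_delta_effect[1L], sm$ci_delta_effect[2L]))
jsonlite::write_json(sm, "results/ce_plane.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)

lambda_grid <- sort(unique(c(seq(0, 6000, by = 50),
                             problem$settings$wtp_thresholds)))
curve <- ceac(psa, lambda_grid)
utils::write.csv(curve, "results/ceac.csv", row.names = FALSE)
cat("acceptability at the reference thresholds:\n")
for (l in problem$settings$wtp_thresholds) {
  cat(sprintf("  lambda %5.0f BRL/QAPY: %.2f%%\n", l,
              100 * curve$probability[curve$lambda == l]))
}

manifest <- list(scenario = "bundled:sus_edentulism", command = "03_psa.R",
                 seed = seed, iterations = iterations,
                 conventions = unclass(cycle_conventions()),
                 package_version = as.character(utils::packageVersion("oralcea")))
jsonlite::write_json(manifest, "results/psa_manifest.json", auto_unbox = TRUE,
                     pretty = TRUE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  g1 <- ggplot(psa$samples, aes(delta_effect, delta_cost)) +
    geom_point(alpha = 0.15, size = 0.4, colour = "steelblue") +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    geom_vline(xintercept = 0, linewidth = 0.3) +
    geom_abline(slope = 3050, intercept = 0, linetype = "dashed") +
    labs(x = "incremental effect (QAPY per patient)",
         y = "incremental cost (BRL per patient)",
         title = "Cost-effectiveness plane, ISTP vs CTP",
         subtitle = "dashed line: willingness-to-pay 3,050 BRL/QAPY") +
    theme_minimal()
  ggsave("results/ce_plane.png", g1, width = 6, height = 5, dpi = 150)
  g2 <- ggplot(curve, aes(lambda, probability)) +
    geom_line(colour = "steelblue") +
    geom_vline(xintercept = 3050, linetype = "dashed") +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "willingness to pay (BRL per QAPY)",
         y = "probability ISTP is cost-effective",
         title = "Cost-effectiveness acceptability curve") +
    theme_minimal()
  ggsave("results/ceac.png", g2, width = 6, height = 4, dpi = 150)
  cat("figures written to results/ce_plane.png and results/ceac.png\n")
}
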