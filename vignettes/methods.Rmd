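---
title: "Methods: cohort Markov cost-effectiveness modelling of mandibular rehabilitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort Markov cost-effectiveness modelling of mandibular rehabilitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralcea)
```

## The decision problem

`oralcea` evaluates rehabilitation strategies for complete mandibular
edentulism with a cohort Markov state-transition model. A decision problem
couples a shared, ordered list of mutually exclusive health states, two or
more strategy arms (each with its own annual transition matrix, cost
schedule and base utility), and shared economic settings. The bundled
reference scenario, `sus_edentulism_problem()`, compares the conventional
complete denture (CTP) with a two-implant-supported overdenture (ISTP)
from the budget perspective of the Brazilian Unified Health System (SUS),
with four states:

| state | meaning | utility multiplier |
|---|---|---|
| A | rehabilitated without complications | 1.00 |
| B | rehabilitated with repairable damage | 0.75 |
| C | treatment failure (fracture/abandonment for CTP, implant loss for ISTP) | 0.50 |
| D | non-treatment-related death (absorbing) | 0.00 |

Effectiveness is measured in quality-adjusted prosthesis years (QAPY): a
cycle in state *s* under a strategy with base QAPY *u* contributes
*u·m_s*, so the 25% and 50% decrements for damaged and failed treatment
are encoded as state multipliers and the strategy-specific quality of a
perfect prosthesis-year (0.79 CTP, 0.94 ISTP) as *u*. State C is alive —
failed or abandoned treatment is not re-treated, and only death is
absorbing. Background mortality is a flat 0.0075 per year from every
living state, appropriate for a cohort entering at age 55 over a 20-year
horizon, and is not a treatment parameter.

## Parameters that matter

* `discount_rate_costs`, `discount_rate_effects` (fraction/year, default
  0.05 each): standard health-technology-assessment discounting applied to
  both dimensions.
* `horizon` (years, default 20): matches the assumed durability of the
  implants; replacement of the acrylic prosthesis itself occurs every
  `replacement_interval` (default 5) years at `replacement_cost` (default:
  the full initial procedure cost — the SUS tariff table prices the whole
  procedure, not a part exchange; a cheaper prosthesis-only replacement
  can be set per arm).
* `cohort_size` (default 1,000,000): the trace scales linearly, so this
  only sets the reporting scale; per-patient quantities are invariant.
* `wtp_thresholds` (BRL/QAPY, default 250/450/750/3,050): 3,050 is 10% of
  Brazilian per-capita GDP, by analogy with WHO per-QALY guidance, and is
  the decision threshold; the smaller values trace out the acceptability
  curve near the ICER.

Transition matrices are validated with a row-sum tolerance of 0.005 —
probabilities printed to four decimals can sum to 0.9999 — and rows are
rescaled *proportionally*, which preserves the printed ratios and changes
the 0.0075 mortality by under 0.01%. After normalization every row sums
to 1 within 1e-12, and absorbing rows must be exact identity rows.

## Cycle accounting conventions

An annual-cycle spreadsheet model underdetermines several timing choices,
and discounted totals are only comparable across implementations when the
conventions match. `cycle_conventions()` therefore exposes them
explicitly rather than hard-coding any single choice:

* **`effect_timing`** — `"end"` (default) values each prosthesis-year on
  the state occupied once the year has been lived, discounted at
  `(1+r)^-t`, `t = 1..H`; `"start"` uses cycle-start occupancy at
  `t = 0..H-1`. `half_cycle_correction = TRUE` averages the two occupancy
  snapshots, the textbook correction.
* **`replacement_payers`** — who pays the scheduled replacement at cycles
  5, 10, 15: `"alive"` (default) keeps every living patient on the public
  provision schedule, the reading most consistent with how the SUS
  dispenses prostheses on a fixed calendar; `"prosthesis"` restricts
  payment to states still bearing a functional prosthesis (A and B),
  consistent with failure/abandonment never being re-treated;
  `"cohort"` charges the whole initial cohort regardless of state, the
  bluntest spreadsheet convention.

The defaults (`"end"`, `"alive"`) are the combination under which the
bundled scenario's per-patient totals line up with the reference results
this scenario is distributed to reproduce; the deterministic ICER of the
bundled scenario varies only between about BRL 433 and 489 per QAPY
across the full grid (`run_conventions_grid()`), so the cost-effectiveness
verdict at λ = 3,050 is convention-independent. Analyses that hinge on a
particular convention should report the grid, not a single row.

The initial procedure cost is always incurred at cycle 0, undiscounted.
ICERs are computed from unrounded per-patient totals; rounding happens
only at presentation. Ties (`ICER == λ`) count as cost-effective; the
CEAC uses the strict inequality `λ·ΔE − ΔC > 0`, so a degenerate
zero-variance PSA at `λ` exactly equal to the ICER would report 0 — an
intentional asymmetry at a measure-zero boundary.

## Probabilistic sensitivity analysis

Second-order parameter uncertainty follows standard health-economics
practice, with all defaults overridable in `psa_spec()`:

* **Transition rows** — Dirichlet with concentration
  `ess × point estimates` (default effective sample size `ess = 100`,
  reflecting transition evidence pooled from cohort studies of roughly
  that size). The death column is held fixed (`fix_death = TRUE`) and the
  live sub-row rescaled to the remaining mass, so mortality is not
  resampled; structurally impossible transitions (probability 0) stay
  impossible because their Dirichlet mass is 0.
* **Costs** — Gamma with the mean at the point estimate and coefficient
  of variation 0.20; tariffs of exactly BRL 0 stay fixed (no Gamma on a
  zero mean), and a replacement cost equal to the initial cost is treated
  as the same parameter (one draw).
* **Utilities** — Beta matched to mean and CV 0.10, with the variance
  clipped just below the Beta-feasible maximum where needed; multipliers
  of exactly 0 or 1 are degenerate and stay fixed. State multipliers are
  shared between arms and drawn once per iteration; the base QAPYs are
  arm-specific draws.

Each `run_psa()` call owns one RNG stream seeded from `spec$seed` (the
caller's RNG state is restored), draws parameters in a fixed order, runs
both cohort arms on the sampled problem, and records (ΔC, ΔE).
Iterations whose sampled problem fails validation are counted in
`$failures` and carried as `NA`, never silently dropped; in practice the
samplers respect their domains by construction and the count is 0. The
default desk-scale iteration count is 10,000: the CEAC probability at
λ = 3,050 is ≈ 0.99, so its Monte-Carlo standard error is about
`sqrt(0.99 × 0.01 / 10000)` ≈ 0.001 — three decimal digits of the curve,
ample for the saturation statement; raise `iterations` for publication-
grade interior values. Interior CEAC values are sensitive to the (here
conventional) distributional defaults and should be read as illustrating
the curve's shape, not as sharp probabilities.

## The synthetic-data layer and what it does (not) show

`random_problem()` draws structurally valid decision problems — one
absorbing state, transition rows uniform on the simplex, costs uniform on
[50, 2000] BRL, utilities in (0, 1], horizons of 5–40 years — and
`simulate_patients()` runs individual-level trajectories under any
scenario. The microsimulation deliberately randomizes *only* the state
path: costs and utilities are accrued deterministically from the visited
states under the identical timing conventions as the cohort engine, so
its mean estimates exactly the quantity the cohort engine computes and
the comparison isolates the propagation logic. Agreement is asserted at
50,000 patients within 3 standard errors for per-patient cost and effect;
for per-state per-cycle occupancy — thousands of discrete binomial
comparisons — cells beyond the 3-SE band are additionally tested against
the exact binomial tail (p > 1e-6), because the normal band undercovers
at expectations of a few patients.

Passing these checks shows the deterministic engine and the stochastic
model agree with each other and with closed forms (e.g. cumulative
mortality `1 − (1−p)^t` when death is the only exit). It does not
validate the scenario against clinical reality: the generator has no
patient heterogeneity, no age- or time-dependent transitions, no
correlation between costs and disease course — all features real
populations have and this homogeneous-cohort model abstracts away.

## Numerical and design notes

* Cohort propagation is plain dense matrix-vector iteration; with K ≤ 6
  states and horizons ≤ 40 there is nothing to optimize.
* Conservation of cohort mass (rows of the trace sum to `cohort_size`
  within 1e-9 relative) and monotone death occupancy are asserted in the
  property suite for batches of random problems.
* The CER is defined as cost divided by effectiveness of a single arm and
  requires strictly positive effectiveness; the ICER is undefined (NA)
  when ΔE = 0, and when one arm dominates, dominance — not the ratio — is
  the decision quantity.
* Serialization round-trips (`write_problem()` / `read_problem()`, YAML
  or JSON) are lossless for any valid problem; the bundled scenario file
  stores the *printed* four-decimal probabilities so loading exercises the
  same normalization path as the in-code builder.
* The analysis entry points are the numbered scripts under `analysis/`
  plus the exported functions; the package intentionally ships no separate
  command-line binary.

## Known limitations

* No tunnel states, time-varying matrices, or age-dependent background
  mortality; the flat 0.0075 understates mortality late in the horizon
  for a cohort entering at 55.
* Repeat treatment after failure is excluded by assumption, so state C
  accrues halved utility indefinitely at zero cost — conservative against
  ISTP, whose failure probability is far lower.
* Costs are 2018 BRL from the federal tariff table, with no inflation
  indexing or municipal co-financing; results are specific to the SUS
  payer perspective.
* The PSA distribution family (Dirichlet/Gamma/Beta with the defaults
  above) is an assumption, not an estimate; interior CEAC probabilities
  move with it.
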