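# oralcea

Decision-analytic cost-effectiveness modelling of prosthetic rehabilitation
for mandibular edentulism, built around an annual-cycle cohort Markov
engine. The package ships a fully parameterized reference scenario
comparing the two rehabilitation strategies financed by the Brazilian
Unified Health System (SUS):

* **CTP** — conventional (removable) complete mandibular denture;
* **ISTP** — implant-supported total prosthesis (overdenture retained by
  two osseointegrated implants).

Effectiveness is measured in **quality-adjusted prosthesis years (QAPY)**,
a QALY-derived utility ranging from 0 (absent tooth) to 1 (a year with a
prosthesis in perfect condition).

## The model

A closed cohort moves each year among four mutually exclusive health
states — A: rehabilitated without complications, B: rehabilitated with
repairable damage, C: treatment failure, D: non-treatment-related death
(absorbing) — according to a strategy-specific row-stochastic matrix *M*:

```
n(t+1) = n(t) M,     n(0) = (N, 0, 0, 0)
```

Per-patient discounted cost and effectiveness over a 20-year horizon are

```
C = c0 + Σ_t (1+r)^-t · [replacement payments at t = 5, 10, 15]
E = Σ_t (1+r)^-t · Σ_s n_s(t)/N · u · m_s
```

with `c0` the initial procedure cost (2018 SIGTAP tariffs: BRL 196.83 for
CTP, BRL 1,050.40 for ISTP), `u` the strategy's base QAPY (0.79 CTP, 0.94
ISTP), `m_s` the state utility multiplier (1 / 0.75 / 0.50 / 0), and
`r = 5%` per year for both costs and effects. Strategies are compared by
the incremental cost-effectiveness ratio `ICER = ΔC / ΔE` against a
willingness-to-pay threshold of λ = BRL 3,050 per QAPY, and parameter
uncertainty is propagated by Monte-Carlo probabilistic sensitivity
analysis (Dirichlet transition rows, Gamma costs, Beta utilities) into a
cost-effectiveness plane and acceptability curve (CEAC).

An individual-level microsimulation (`simulate_patients()`) and a random
scenario generator (`random_problem()`) provide an independent brute-force
oracle against which the cohort engine is validated in the test suite.

## Worked example

```r
library(oralcea)

problem <- sus_edentulism_problem()   # or read_problem("scenario.yaml")
det <- run_deterministic(problem)
det
#> <deterministic_result>
#>  strategy    cost incremental_cost effect incremental_effect    cer   icer
#>       CTP  542.00             0.00   5.21               0.00 104.08     NA
#>      ISTP 2892.41          2350.41  10.50               5.29 275.46 444.11
```

Per patient and discounted at 5%, CTP costs BRL 542 and yields 5.21 QAPY;
ISTP costs BRL 2,892 and yields 10.50 QAPY. ISTP is costlier *and* more
effective (a trade-off, no dominance), at roughly BRL 444 per additional
QAPY — far below the λ = 3,050 threshold, so ISTP is judged very
cost-effective. Accounting-convention sensitivity
(`run_conventions_grid(problem)`) moves the ICER only within ≈ 433–489.

```r
psa <- run_psa(problem, psa_spec(iterations = 10000, seed = 42))
ceac(psa, c(250, 450, 750, 3050))
#>   lambda probability
#> 1    250      0.0509
#> 2    450      0.5566
#> 3    750      0.9233
#> 4   3050      0.9902
```

At the adopted threshold the probability that ISTP is cost-effective is
≈ 99%; `ce_plane_summary(psa)` shows 99.5% of the Monte-Carlo cloud in the
north-east quadrant (more effective, more costly).

## Analysis workflow

The `analysis/` scripts re-run the full study end to end and write their
tables under `results/`:

```sh
Rscript analysis/01_build_scenario.R    # tariff tables, validated scenario
Rscript analysis/02_deterministic.R     # per-arm totals, ICER, convention grid
Rscript analysis/03_psa.R               # PSA samples, CE plane, CEAC (+ figures)
Rscript analysis/04_microsim_check.R    # cohort engine vs microsimulation oracle
```

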