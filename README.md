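# egfrcea

Health-economic decision modelling for first-line treatment of advanced
EGFR-mutant non-small cell lung cancer, for analysts who need a tested,
scriptable alternative to point-and-click decision-tree software. The
package implements a three-state Markov cohort model — progression-free
(PFS), progressive disease (PD), death — calibrated from digitized
Kaplan-Meier curves, with full regimen-level costing, QALY accrual with
discounting, cost-effectiveness statistics, and deterministic plus
probabilistic sensitivity analysis. Six first-line trial configurations
ship as ready-made fixtures (ARCHER 1050, FLAURA, JO25567, NEJ026,
NEJ009, NCT02148380), and a synthetic-data generator produces
digitized-curve inputs with known ground truth so every pipeline stage
is testable without external data.

## The model

Survival in each arm follows Weibull laws `S(t) = exp(-λ t^γ)` fitted
separately to the PFS and OS endpoints (default: least squares on the
linearisation `ln(-ln S) = ln λ + γ ln t` over the digitized points).
The per-cycle transition probability conditional on surviving to the
cycle start is

    Pt = 1 - exp[λ((t-u)^γ - t^γ)],   u = cycle length (months)

which compounds exactly back to `S(t)`. Death in every state is driven
by the OS law (so cumulative deaths track `1 - S_OS` identically), and
PFS→PD receives the residual exit probability. Per cycle, the PFS
fraction accrues drug costs (oral drugs pro-rata per day, IV drugs in
whole vials against a 65 kg / 1.72 m² reference patient), fixed care
and expected adverse-event costs; the PD fraction accrues a weekly PD
cost; deaths incur a one-time terminal-care cost. Costs and QALYs are
discounted at 3%/year. Comparisons report

* ICER = (cost_t − cost_c) / (QALY_t − QALY_c), with a dominance
  annotation on negative values,
* ACER = cost / QALY per arm,
* net monetary benefit = QALY × WTP − cost at WTP $30,828/QALY,
* the drug-price concession fraction needed to reach the threshold,
* tornado (one-way, ±30% costs / ±20% utilities and probabilities) and
  probabilistic sensitivity analysis (gamma costs, beta
  utilities/probabilities, moment-matched to the one-way ranges; CEAC
  over a WTP grid).

## Worked example

Build a FLAURA-shaped synthetic trial (Weibull medians equal to the
published 18.9 / 10.2 month PFS and 38.6 / 31.8 month OS medians),
calibrate from its digitized curves, and run the 5-year model:

```r
library(egfrcea)

fx    <- make_reference_fixture("flaura", seed = 7, n = 1e5, n_points = 100)
model <- calibrate_model(fx$model, fx$curves)
res   <- run_model(model)
res$summary
#> # A tibble: 2 × 3
#>   arm           cost  qaly
#>   <chr>        <dbl> <dbl>
#> 1 osimertinib 83475.  2.24
#> 2 egfr_tki    45440.  1.90

s <- res$summary
compare_arms(list(arm = "osimertinib", cost = s$cost[1], qaly = s$qaly[1]),
             list(arm = "egfr_tki",    cost = s$cost[2], qaly = s$qaly[2]),
             wtp = 30828)
#> <cea_result> osimertinib vs egfr_tki (WTP 30828/QALY)
#>   IC 38035.11, IE 0.3425, ICER 111062.63
#>   ACER 37222.49 vs 23914.15; NB -14340.31 vs 13137.28

cost_reduction_to_threshold(model, "osimertinib", "egfr_tki")
#> [1] 0.587  (drug-cost reduction of ~59% reaches the threshold)
```

Read: over five years the osimertinib arm costs $38,035 more and gains
0.34 QALYs, an ICER of ~$111,000/QALY — far above the $30,828 threshold,
with a negative net benefit versus a comfortably positive one for the
first-generation comparator; the arm would need its drug price cut by
roughly 59% to become cost-effective under these synthetic survival
curves. (These are synthetic-fixture numbers: the generator matches the
published medians with shape 1.3, not the originally fitted transition
parameters.)

Sensitivity analysis and plots:

```r
tor   <- one_way_sensitivity(model, "osimertinib", "egfr_tki")
draws <- psa_run(model, n = 1000, seed = 1)
curve <- ceac(draws, "osimertinib", "egfr_tki")
autoplot(tor); autoplot(curve); plot_psa_scatter(draws, "osimertinib", "egfr_tki")
```

A command-line front end wraps the same functions
(`system.file("cli/cea.R", package = "egfrcea")`) with `fit`, `run`,
`psa`, `dsa` and `simulate` subcommands, delimited-text outputs and a
JSON run manifest.

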