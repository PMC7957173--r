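---
title: "A three-state Markov model for first-line EGFR-TKI cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state Markov model for first-line EGFR-TKI cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egfrcea)
```

## The decision problem

Several first-line strategies compete for advanced EGFR-mutant non-small
cell lung cancer: newer-generation tyrosine kinase inhibitors
(dacomitinib, osimertinib), anti-angiogenic combinations
(bevacizumab + erlotinib), and chemotherapy combinations
(platinum–pemetrexed with gefitinib). All prolong progression-free
survival; their prices differ by an order of magnitude. `egfrcea`
implements a cohort-level decision model that turns published survival
curves, unit prices and health-state utilities into incremental
cost-effectiveness ratios (ICERs), average ratios (ACERs), net monetary
benefit, and deterministic plus probabilistic sensitivity analyses, from
the payer perspective of the Chinese healthcare system (USD, WTP
threshold $30,828/QALY — three times per-capita GDP).

Six trial configurations ship with the package (`trial_fixtures()`),
each pairing the trial's regimen, cycle length, grade ≥3 adverse-event
rate and median PFS/OS with the published unit costs and utilities.

## Model structure

Patients occupy one of three mutually exclusive states: progression-free
on treatment (PFS), progressive disease (PD), and death. Everyone starts
in PFS. Time advances in cycles of the trial's treatment cycle length
(21 or 28 days); one month is 365.25/12 days throughout, and horizons of
5 and 10 years are truncated to whole cycles (floor division, no partial
final cycle).

Survival follows the Weibull survivor function

$$S(t) = \exp(-\lambda t^{\gamma}),$$

with scale $\lambda$ (per month$^{\gamma}$) and shape $\gamma$. The
conditional probability that the event occurs in the cycle ending at $t$
given event-free at $t-u$ (cycle length $u$ in months) is

$$P_t = 1 - \exp\!\left[\lambda\big((t-u)^{\gamma} - t^{\gamma}\big)\right],$$

which telescopes exactly: compounding $1 - P_t$ over cycles recovers
$S(t)$ (asserted to $10^{-12}$ in the tests). For $\gamma = 1$ this
reduces to the constant-rate form $P = 1 - e^{-rt}$, which
`rate_to_probability()` exposes as a utility for exponential special
cases.

Two Weibull laws drive each arm: one fitted to the PFS endpoint
(progression **or** death) and one to overall survival. The published
material does not say how exits from PFS split between PD and death, so
the engine makes the one choice that keeps both marginal curves
consistent with their fitted laws: the per-cycle death probability in
*every* alive state comes from the OS law, and PFS→PD receives the
residual $\max(0, P^{\text{PFS}}_t - P^{\text{OS}}_t)$. Death occupancy
therefore equals $1 - S_{\text{OS}}(t_k)$ identically, and PFS occupancy
equals $S_{\text{PFS}}(t_k)$ whenever the PFS curve lies below the OS
curve (both are asserted in the test suite). PD has no state-specific
hazard: none is published.

Occupancy is evaluated at cycle end with no half-cycle correction by
default — the source analyses do not state one — and
`run_cohort(half_cycle = TRUE)` enables the standard start/end average
for sensitivity.

## Calibration from digitized curves

Published Kaplan-Meier figures arrive as digitized (time, survival)
points. The default calibration is ordinary least squares on the
linearisation

$$\ln(-\ln S(t)) = \ln\lambda + \gamma \ln t,$$

using interior points only; points with $S \le 0.01$ are dropped because
the double-log transform amplifies noise there, and digitized points are
treated as exact (no measurement-error model). An alternative
`fit_weibull(method = "mle")` reconstructs pseudo-individual event times
from the survival drops and fits by maximum likelihood via
`survival::survreg()`.

One identifiability caveat matters in practice: on digitized curves
$\hat\lambda$ and $\hat\gamma$ are strongly anti-correlated
($\Delta\ln\hat\lambda \approx -\ln(\text{median})\cdot\Delta\hat\gamma$
on the month scale), so the individual coordinates carry far more
sampling error than the survivor function itself. The fitted *median*
and the fitted survivor curve over the data range are well identified at
realistic digitization sizes; the raw $(\lambda, \gamma)$ pair is not.
The package's correctness checks therefore focus on the survivor
functional and on noiseless curves (where recovery is exact to
$10^{-6}$), and `fit_weibull()` reports the $R^2$ of the linearised fit
so poorly identified inputs are visible. Pre-fitted parameters can
bypass fitting entirely via `read_parameter_table()` (layout: arm,
endpoint, lambda, gamma, r_squared).

```{r fit-example}
tt <- seq(2, 40, by = 2)
curve <- km_curve(c(0, tt), c(1, exp(-0.03 * tt^1.2)), endpoint = "PFS")
fit_weibull(curve)
```

## Costs

Per cycle, the progression-free fraction accrues drug acquisition cost
plus fixed care costs (follow-up $55.60 and supportive care $337.50 per
cycle) plus the expected adverse-event cost (grade ≥3 rate × $507.40 per
cycle; AE costs and disutilities are treatment-emergent and apply only
in PFS). The PD fraction accrues $276.75 per week. Entry to death incurs
a one-time terminal-care cost of $1412.92 per week over a configurable
duration; the published material prices terminal care per week but never
states a duration, so the default bills one cycle length
(`terminal_care_weeks`). Examination unit prices (CT, MRI, labs) are
published without a schedule; the model exposes an optional
`examination_per_cycle` amount and defaults to none, treating them as
folded into the lumped follow-up/supportive totals.

Drug costing follows hospital billing practice:

* oral drugs (`fixed_daily`) are priced pro-rata per mg-day times the
  days dosed that cycle (e.g. gefitinib 250 mg/d in a 28-day cycle:
  28 × $22.65);
* intravenous drugs (`per_kg`, `per_bsa`, `auc_dose`) are billed in
  whole vials, `ceiling(dose / vial content) × vial price`, once per
  cycle (bevacizumab 15 mg/kg × 65 kg = 975 mg → 10 × 100 mg vials);
* the reference patient is 1.64 m, 65 kg, BSA 1.72 m²;
* carboplatin is dosed by AUC, for which no GFR is published; the
  fixtures use a configured 500 mg per administration, and the value is
  a plain config field;
* components past their `max_cycles` stop unless flagged `maintenance`
  (platinum doublets cap at 6 cycles; maintenance pemetrexed ±
  gefitinib continues; in the NCT02148380 combination arm gefitinib is
  dosed days 5–21 — 17 of 28 days — during the doublet phase and daily
  thereafter).

No dose reductions, discontinuations or relative dose intensity are
modelled; the sources provide none.

## Utilities, QALYs and discounting

Each arm's PFS utility is drug-specific for oral monotherapy
(gefitinib 0.800, erlotinib 0.810, dacomitinib 0.827, osimertinib
0.840, first-generation TKI class 0.805 for the FLAURA comparator, which
mixes gefitinib and erlotinib and is priced as gefitinib); regimens
containing an intravenous component use the single published
intravenous-therapy utility 0.760. PD utility is 0.700; the grade ≥3
adverse-event disutility −0.0731 is applied in PFS weighted by the
trial's AE rate. Cycle QALYs are utility × cycle length in years. Both
costs and QALYs are discounted at 3% per annum at each cycle's end time,
$(1.03)^{-k u_{\text{years}}}$.

## Cost-effectiveness metrics

`compare_arms()` computes IC, IE, ICER = IC/IE, per-arm ACER =
cost/QALY, and net monetary benefit = QALY × WTP − cost. A negative ICER
is reported with its sign plus a dominance annotation, because a bare
negative ratio cannot distinguish "cheaper and more effective" from
"dearer and less effective". When IE = 0 the ICER is flagged undefined;
net benefit remains usable. `rank_by_net_benefit()` orders arms with
deterministic tie-breaks (lower cost, then name).

`cost_reduction_to_threshold()` answers the price-negotiation question:
the smallest fraction $f$ such that scaling the treatment arm's **drug
acquisition** costs by $1-f$ brings the ICER to the threshold. Only drug
costs are scaled — the question is about price concessions, not about
care costs — and the solver bisects to |ICER − WTP| ≤ $0.01/QALY. On a
model whose only cost is the drug, the answer has the closed form
$(IC - WTP \cdot IE)/C_{\text{drug}}$, which the test suite uses as an
oracle for the bisection.

## Sensitivity analysis

One-way analysis perturbs each registered parameter to base × (1 ±
range) — 30% for costs, 20% for utilities and probabilities, with
utilities capped at 1 — holding all else fixed, and reports a tornado
tibble sorted by bar width. The outcome metric is the ICER for two-arm
comparisons, with incremental net benefit available by flag (and used
automatically when IE = 0).

The probabilistic analysis draws every cost parameter from a gamma
distribution and every utility/probability parameter from a beta
distribution (1000 iterations by default, one seeded generator per run).
Neither family's variance is published, so both are moment-matched to
the one-way ranges: mean equal to the base value and central 95%
interval spanning ±30% (costs) or ±20% (others), which couples the two
analyses coherently; beta variances are capped inside the feasible
region of the (0,1) support. Transition probabilities are sampled on the
scale the model actually uses: the first-cycle conditional event
probability $p_1 = 1 - \exp(-\lambda u^{\gamma})$ per arm and endpoint
gets the beta draw and $\lambda$ is backed out with $\gamma$ held fixed.
`ceac()` evaluates the acceptability curve on a willingness-to-pay grid
(default $0–2{,}000{,}000/QALY in 201 points), counting strict
net-benefit wins so the treatment and comparator curves sum to one up to
ties.

## The synthetic-data generator

No individual-level data accompany the published curves, so the
generator stands in for figure digitization with known ground truth:
Weibull event times, independent uniform censoring on [0, horizon]
applied to a configurable fraction of patients (administrative-censoring
stand-in; 20% by default), a product-limit estimate
(`survival::survfit`), and read-off at an evenly spaced time grid — the
synthetic analogue of clicking points off a printed figure.
`make_paired_arm()` draws PFS and OS for the same patients with a
comonotone coupling so progression never follows death, and
`make_reference_fixture()` builds a full trial-shaped model whose
Weibull laws hit the published medians by construction (shape 1.3 by
default — a mild increasing hazard typical of advanced-NSCLC
survival — with the scale solved from the median).

What the generator does **not** emulate: the pixel coordinates of real
figures, digitization measurement error, informative censoring, and
number-at-risk annotations. Passing tests therefore demonstrate that the
pipeline is correct for curves that genuinely follow Weibull laws, not
that any published figure was digitized faithfully.

## Numerical choices and verification sizes

Choices a maintainer should know, all asserted in the test suite:

* telescoping consistency of per-cycle probabilities to $10^{-12}$;
  occupancy conservation to $10^{-12}$ per cycle; death occupancy equal
  to $1 - S_{\text{OS}}$ to $10^{-9}$;
* the cohort engine is validated against an independent individual-level
  microsimulation (10⁵ patients stepped with identical per-cycle
  probabilities) to within 3 Monte Carlo standard errors on discounted
  cost and QALY;
* the end-to-end consistency check (simulate → fit → run → ICER vs. an
  oracle that evaluates the true survivor functions directly) uses 10⁵
  patients and 100 digitized points with a 5% band. The size is chosen
  so the check detects pipeline *bias*: the ICER divides by a small QALY
  difference, and at realistic digitization sizes (hundreds of patients)
  its sampling noise alone exceeds 5%;
* closed-form limits (zero-transition QALY accrual, geometric-series PFS
  time under constant hazard) are exercised on configurations whose
  cycle length divides the horizon exactly, so the identities hold
  without truncation remainders;
* bisection tolerance for the price-concession solver: $0.01/QALY on
  the ICER; degenerate cases (already cost-effective → 0; unattainable
  at $f=1$ → flagged) are explicit.

## Limitations

* The three-state structure has no tunnel states and no post-progression
  treatment modelling; everything after progression is one lumped
  weekly cost and one utility.
* The PFS→PD/death split and the PD death hazard are modelling choices
  (OS-law-driven), not published quantities.
* Fitted $(\lambda, \gamma)$ from digitized curves are reported with
  their $R^2$ but remain ill-conditioned individually; conclusions
  should rest on the fitted survivor functions.
* Published per-arm results can be reproduced at the arithmetic layer
  (incremental rows from printed per-arm rows, to the printed cent);
  full desk reproduction of the published ICERs requires the original
  fitted transition parameters and digitized curves, which are not
  redistributable here. The packaged medians with shape 1.3 give
  trial-shaped, not trial-identical, base cases.
* Currency is USD throughout; the CNY exchange rate (7.0459) is
  provenance metadata only.
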