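---
title: "The cropshock model: assumptions, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cropshock model: assumptions, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropshock)
```

## The model

cropshock simulates a region of `N` farming units over discrete seasons. A
unit owns `P` plots of fixed acreage; each plot carries at most one crop per
season and is planted in its entirety. Units are identical apart from a
cropping strategy fixed for the whole simulation: *monocropped* (one crop on
every plot) or *diversified* (two or more crops, each on at least one plot).
A season is one cycle of planting, harvesting, price formation and funds
accounting.

Three equations drive everything.

**Price law.** The end-of-season market price of crop *i* is
$V_t = a_i Y_t^{\varepsilon_i}$, where $Y_t$ is the total mass (kg) of the
crop harvested by *all* units that season and $\varepsilon_i < 0$ is the
demand elasticity. Aggregate scarcity raises the price; glut lowers it. This
is the sole interaction channel between units: there is no trade, storage,
contracting, or strategic reasoning.

**Planting objective.** At the start of a season each unit maximizes
$\Psi(x) = \sum_{ij} (V_i Y_{ij} h_i L_{ij} - C_L L_{ij} - a_{ij})\,x_{ij}$
over binary crop-to-plot assignments $x_{ij}$ with $\sum_i x_{ij} \le 1$,
where $h_i$ (acres/laborer) is the reciprocal of the per-acre labor
requirement, $C_L$ is the per-laborer seasonal wage and $a_{ij}$ is the
plot's non-labor production cost. Prices entering this objective are the
previous season's realized prices — units have perfect knowledge of the price
law's history but do not anticipate shocks or solve for the current season's
equilibrium.

**Harvest objective.** At harvest the assignment is fixed and the unit
optimizes labor: maximize $\sum_{ij} (V_i Y_{ij} h_i - C_L) L_{ij}$ subject
to $\sum L_{ij} \le$ its labor share and $0 \le L_{ij} \le S_j / h_i$. Labor
is divisible, so partial harvests arise naturally; plots whose marginal
value per laborer is below the wage are left standing.

Realized revenue is then booked at the *new* prices implied by the aggregate
harvest, while the decisions above were taken at the lagged expected prices.
This two-price contract is deliberate: it reproduces the classic cobweb-like
mechanism where collectively abundant harvests disappoint individually
optimizing farms.

Labor shocks scale the regional pool: baseline labor is the most
labor-intensive crop's per-acre requirement times the region's total acreage
(so an unshocked region can fully harvest even the hungriest crop
everywhere), and during a shock of intensity $i$ for $d$ seasons only the
fraction $i$ is available, split equally across units. Replication runs last
$\tau = d + 1$ seasons with the shock starting in season 1, ending on one
recovery season.

## Solving the two optimizations exactly

Both decision problems are small and are solved exactly rather than
heuristically:

* The planting objective is additive over plots, so without coverage
  constraints it decomposes into independent per-plot argmaxes (fallow
  allowed when every option loses money — only relevant in `free` mode).
  The diversified requirement "each strategy crop on at least one plot" is
  handled by dynamic programming over plots with a bitmask of covered crops,
  which is exact for any number of plots and crops. The test suite
  certifies both modes against exhaustive enumeration of all feasible
  assignments on hundreds of randomized instances.
* The harvest problem is a single-resource LP with box constraints, whose
  optimum is the greedy fill in descending marginal profit per laborer.
  Tests certify it against an independent dense LP solve (`boot::simplex`).

Equal-objective optima are resolved by fixed (crop index, plot index)
lexicographic order, which makes every run bit-reproducible; the
`shock_sim` object carries an MD5 fingerprint of its full configuration.
Units with identical strategy and plots face identical decision problems
(decisions never depend on funds), so within a season their optimizations
are solved once and shared — accounting stays per unit.

## Parameters and calibration

The Florida case (`florida_fixture()`) encodes the published per-acre
budgets: strawberries at 12,305 USD/acre production cost, 7,788 USD/acre
harvest labor and 0.95 laborers/acre; tomatoes at 10,078, 2,408 and 0.29;
elasticities −0.66 and −0.58; two 100-acre plots per unit; 1,871,571 USD
initial funds. Two derived economy-wide quantities deserve comment:

* **Wage $C_L$** — the harvest objective charges a single per-laborer wage,
  but budgets report labor cost per acre. Dividing by the labor requirement
  gives 8,197.9 USD/laborer from the strawberry budget and 8,303.4 from the
  tomato budget — a ~1.3% discrepancy with no single reconciliation. The
  default is their mean (≈ 8,250.7); pass `labor_cost_per_laborer` to
  `florida_fixture()` to override.
* **Price constants $a_i$ and plot yields** — the public budgets do not
  include kg/acre yields, and the original case's calibrated constants are
  not recoverable. The fixture therefore ships *placeholder* calibration
  anchors on the scale of public USDA statistics for Florida in the 2000s:
  strawberry 2.65 USD/kg at 10,000 kg/acre, tomato 1.00 USD/kg at
  14,500 kg/acre. They are flagged as placeholders in the documentation,
  and `load_price_yield_csv()` turns any annual price/yield series into
  replacement anchors.

Calibration is **self-consistent at the region scale**: $a_i$ is derived
against the composed region's expected harvest at its baseline composition
(mean yield/acre × acres structurally planted to the crop), so that a
full-labor season is an exact fixed point — prices sit at the anchor means
and funds grow linearly at the hand-computable full-harvest profit. This
makes model behavior invariant to the (unknown) absolute scale of the
historical series and is verified to 10⁻⁹ relative accuracy in the tests.

Because $\varepsilon < 0$, the price law diverges as the harvest goes to
zero. The aggregate harvest entering the law is clamped below at a floor of
1% of the crop's calibration harvest (`price_floor_frac` in
`economy_params()`): a zero-harvest season is priced as a 99% shortfall
rather than at infinity. The floor only binds in near-blackout seasons
(regional harvest below 1% of baseline) and leaves the reported sweep
regime untouched elsewhere.

Season-1 expectations are initialized at the calibration means — consistent
with the fixed point, but it means the first shocked season is a transient:
units plant and staff as if labor were plentiful and prices normal, and only
from season 2 do scarcity prices steer diversified units' labor toward the
scarce, price-inflated crop.

## The experiment grid

`sweep_config()` defaults to the replication design: 30 units; 2–28
diversified units in steps of 2 (monocropped remainder split evenly between
the two crops, balancing their price effects); intensities 0.1–1.0 in steps
of 0.1; durations 1–10 — 1,400 deterministic runs. The description of the
original design is internally inconsistent about whether $i = 0$ is included
(11 × 10 combinations vs a stated count of 100); the default grid matches
the stated count of 100 and `include_zero_intensity = TRUE` restores the
blackout column. "Advantage percentage" for a (composition, intensity) cell
is interpreted as the share of *durations* for which diversified mean funds
exceed a monocrop's, durations being the remaining free axis; aggregate
crossover intensities are computed from mean funds per intensity averaged
over durations and compositions, and reported in the "advantage begins
strictly above $i$" form.

## What the synthetic generator does and does not emulate

`generate_synthetic_region()` samples regions spanning the structural
invariant space — 2–3 crops with negative elasticities, 2–3 plots per unit,
mixed strategies, positive costs and labor requirements — for property
testing: every sampled region must validate, run, conserve mass and satisfy
the accounting identity. It makes no attempt at agronomic realism: yields,
prices and costs are drawn independently, so sampled economies can be
wildly unprofitable or implausibly lucrative. Passing property tests
therefore demonstrates the *mechanics* (optimality, conservation,
determinism, invariant enforcement) on arbitrary valid inputs, not that the
model's *conclusions* transfer to any particular real production system.

## Known limitations

* **Calibration dependence of the headline patterns.** The crossover
  intensities at which diversification starts to pay, the
  duration-invariance of strategy rankings, and the stability of regional
  wealth across compositions all depend on the relative per-acre
  profitability of the two crops, which the published inputs do not pin
  down. Under the shipped placeholder anchors the tomato margin is thin, so
  tomato monocroppers never dominate diversified units the way the original
  case reports for extreme shocks, and the acceptance checks that encode
  those case-specific patterns fail in part — deliberately left visible
  rather than recalibrated away. Users with access to the original annual
  series should recalibrate via `load_price_yield_csv()`.
* **Season-1 transient.** Because expectations start at the calibration
  means, short extreme shocks ($d \le 2$, small $i$) are dominated by the
  misallocation of the first season, and end-of-run rankings can depend on
  duration at low intensity.
* No yield stochasticity, weather, crop seasonality, rotation constraints,
  credit constraints, or within-season labor dynamics; demand follows the
  static power law with no supply-side dynamics. Farm exit is available as
  an off-by-default hook (`exit_floor` in `run_simulation()`) but no exits
  occur under the Florida parameterization.

## Problem sizes used in the checks

The test suite certifies the optimizers on 500 randomized instances of up
to 3 crops × 3 plots, validates 300 synthetic regions, and runs the full
1,400-run sweep once; `scripts/acceptance.R` reruns the sweep and reports
the labor anchors, fixed-point profits, crossovers, advantage fractions and
regional wealth spread. The whole suite completes in well under a minute on
a single CPU.
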