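---
title: "Simulating food taxes and subsidies with conditional price elasticities and TFEe rescaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating food taxes and subsidies with conditional price elasticities and TFEe rescaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elastax)
```

## The problem

Health-impact models of food taxes and subsidies translate a price change
into a change in diet with a price-elasticity (PE) matrix: entry
$\varepsilon_{ij}$ is the percent change in the quantity of food $i$ per 1%
change in the price of food $j$. Almost all published food PE matrices are
*Marshallian conditional* matrices: they were estimated under the assumption
that total food expenditure does not change. When such a matrix is
transplanted to a setting with different baseline consumption or prices —
the normal situation, because estimating a matrix for every study
population is impractical — that assumption silently breaks, and the model
produces total food expenditure shifts that are economically implausible:
spending that *falls* after a tax, or *rises* after a subsidy.

`elastax` implements a two-step repair. Step 1 applies the PE matrix and
then rescales all quantities by a common ratio so that total food
expenditure is exactly unchanged — restoring the conditional assumption.
Step 2 then moves total food expenditure by the economically expected
amount, governed by the **total food expenditure elasticity (TFEe)**: the
percent change in total food spending per 1% change in the food price index
(FPI). The change is allocated across foods with food-group expenditure
elasticities and closed with a final scalar so the target is hit exactly.

## The model

Let $q_i^B$, $p_i^B$ be baseline quantities (g/day) and prices (per 100 g),
and $X^B=\sum_i q_i^B p_i^B$ (we compute expenditure as $q/100 \cdot p$ so
units cancel). A policy produces post-policy prices $p_i^A$: a specific
nutrient tax adds `rate * content / 100` to the shelf price (100%
pass-through, producer prices fixed), then any ad valorem change applies
multiplicatively.

**Step 1.** The raw response is
$\%\Delta q_{i,PE}=\sum_j \%\Delta p_j\,\varepsilon_{ij}$. The implied
expenditure $X_{PE}=\sum_i (1+\%\Delta q_{i,PE})\,q_i^B p_i^A$ generally
differs from $X^B$, so every food is rescaled by the same ratio:

$$\%\Delta q_{i,PES}=\frac{X^B}{X_{PE}}\,(1+\%\Delta q_{i,PE})-1,$$

which restores $\sum_i (1+\%\Delta q_{i,PES})\,q_i^B p_i^A = X^B$ exactly
(to 1e-9 relative, enforced by tests over random systems).

**Step 2.** The FPI change is Laspeyres,
$\%\Delta FPI = 100(\sum_i q_i^B p_i^A / X^B - 1)$, and the expenditure
target is $\Delta X = \%\Delta FPI \cdot TFEe \cdot X^B$. Preliminary
per-food changes $\Delta q_{i,EE} = \%\Delta FPI \cdot TFEe \cdot \eta_i
\,(1+\%\Delta q_{i,PES})\,q_i^B$ (with $\eta_i$ the food's expenditure
elasticity) are rescaled by $\Delta X / \sum_i \Delta q_{i,EE} p_i^A$, so
that the final quantities satisfy $X^A = X^B + \Delta X$ *identically*.
A useful diagnostic falls out: the **revealed TFEe**, the ratio of percent
expenditure change to percent FPI change that any model run implies post
hoc. For an adjusted run it returns the input TFEe exactly (a fixed point,
tested to 1e-9); for a conventional run it exposes the implausibility
(e.g. a negative value for a tax).

`run_policy_scenario(..., mode = "conventional")` deliberately applies the
matrix raw — no Step-1 rescale, no TFEe — because that is what the
unadjusted analyses this method criticises do: their reported expenditure
shifts are only possible without the rescale.

## Parameters that matter

* **TFEe** (dimensionless, theoretically in $[0,1]$): default uncertainty
  distribution Beta(6, 2) — mean 0.75, 95% interval about 0.42–0.96 —
  chosen to cover published national estimates (0.46–0.90, one outlier
  near 0). A fixed value can be supplied instead (`tfee_spec(fixed =)`).
  The Michelini-style conversion `own_pe_to_tfee()` maps an unconditional
  all-food own-PE $e$ to $1+e$ (e.g. $-0.168 \to 0.832$).
* **Disaggregation scalar $s$** (fraction per sub-food, default 0.025, SD
  0.0125 truncated at 0): when an aggregate group (e.g. "dairy") is split
  into $k$ sub-foods, each sub-food's own-PE strengthens to
  $\varepsilon_{own}(1+ks)$ — sub-foods are substitutes, so finer foods
  respond more. The freed response returns as positive within-group
  cross-PEs $\varepsilon_{ij} = \frac{w_j}{1-w_i}(|\varepsilon_{own,sub}| -
  |\varepsilon_{own,agg}|)$, which makes each row of the block sum exactly
  to the aggregate own-PE. With $s=0.025$, $k=5$ and an aggregate own-PE
  of $-1$, every sub-food gets $-1.125$ and the cross-PEs onto a 20%-share
  food are 0.0625 / 0.03125 / 0.015625 / 0.015625 for shares 40/20/10/10%.
* **Energy-to-weight constant** (94 kJ/day per kg, configurable): the
  steady-state rule of thumb replacing a dynamic weight model — a
  sustained 94 kJ/day deficit lowers equilibrium weight by about 1 kg, so
  $\Delta BMI = (\Delta kJ / 94)/h^2$.
* **Discount rate** (0 or 0.03/year): applied to HALYs at accrual year.

## Design choices where the method is genuinely open

* **Own-PE increment**: multiplicative ($|\varepsilon|(1+ks)$) by default,
  additive ($|\varepsilon|+ks$) available. The canonical worked example
  sits at $\varepsilon=-1$ where both coincide; the phrase "increases in
  absolute value terms by 2.5%" reads most naturally as multiplicative.
* **Between-group cross-PE disaggregation**: uniform replication of the
  aggregate cross-PE to every sub-pair. Any share-weighted re-aggregation
  of such a block returns the aggregate value exactly. Note the two block
  types therefore conserve *different* functionals — diagonal blocks
  conserve unweighted row sums, off-diagonal blocks conserve share-weighted
  means — and `check_adding_up()` checks each block against its own law;
  no single weighting is conserved by both, which we verified directly on
  the worked example.
* **Conventional mode** skips the Step-1 rescale entirely (see above).
* **Negative quantities**: elasticities are local (percent-change)
  objects; a large price shock can push $1+\%\Delta q$ below zero, where
  the equations stop being meaningful. The package clamps at zero
  consumption with a warning and re-runs the Step-1 rescale once. Tests of
  oracle equivalence restrict to the domain where no clamping occurs.
* **Degenerate Step 2**: if the expenditure-elasticity pathway is null
  ($\sum \Delta q_{i,EE} p_i^A = 0$) while the target $\Delta X$ is not,
  the run errors rather than silently missing its target; a zero target
  sets the closing scalar to 0.
* **PIF combination across risk factors**: multiplicative in $(1-PIF)$,
  noted as an assumption.
* **Monte-Carlo PE draws** are *not* re-projected onto the adding-up
  constraint (no such re-projection is part of the method);
  `cournot_residuals()` reports the violation magnitude instead. Own-PE
  draws are capped at 0 so sampling can never make a good its own
  substitute.

## The health chain

The lifetable is a generic proportional multistate engine with annual
cycles, not a reproduction of any national model. Each disease carries
incidence, case fatality, remission, a disability weight and an optional
lag (hard step by default; linear phase-in available). A potential impact
fraction (PIF) scales intervention incidence; prevalence evolves as
$p' = p + inc(1-p) - (cf+rem)p$; the prevalence *difference* between arms
perturbs all-cause mortality (via case fatality) and morbidity (via
disability weights) relative to business as usual; HALYs accrue as
discounted, morbidity-weighted life years with a half-cycle correction for
deaths. The engine is verified against an independently coded
cycle-by-cycle recomputation to 1e-9 on toy populations.

## What the synthetic generator emulates — and what it does not

`make_food_system()` and friends stand in for national consumption
surveys, price databases and burden-of-disease inputs, none of which are
shipped. The generated world has: 23 food groups by default (optionally
split into sub-foods, 23 x 15 = 345 for the fine fixture); prices 0.2–3
currency units per 100 g; consumption 5–300 g/day per food; right-skewed
nutrient content (Beta(1, 4) scaled to 40 g/100 g for saturated fat, 60
for sugar — most foods lean, a few concentrated); energy floored at
17 kJ/g sugar + 37 kJ/g fat for plausibility; own-PEs in [-1.5, -0.2];
cross-PEs drawn small and column-corrected so Cournot aggregation
$\sum_i w_i \varepsilon_{ij} = -w_j$ holds to 1e-9 (the only demand-theory
constraint the method invokes; the correction is spread uniformly over a
column's off-diagonal entries to keep magnitudes realistic); expenditure
elasticities scaled so the Engel condition $\sum_i w_i \eta_i = 1$ holds
exactly.

It does **not** emulate: realistic correlation between a food's
consumption and its composition (so synthetic per-capita energy runs high
relative to a real basket); survey weighting; named foods; Slutsky
symmetry; or any real matrix's SD structure. A green test therefore
establishes that the *mechanics* — conservation laws, fixed points,
adding-up, oracle equivalence, reproducibility — are correct, not that any
particular national result is reproduced. The published national HALY
totals are out of reach by construction and are used only as printed
inputs to arithmetic identities (see `nz_case_studies()`).

The three-food demonstration (`box_demo_systems()`) is a synthetic
reconstruction: the original demonstration's input tables are only
published as images, so we solved for a system consistent with every
number the surrounding text states (the fruit PE column, zero expenditure
change and +0.51% energy in the original setting, +2.38% energy in the
transplanted one). The vegetable and cereal price columns are never
exercised by a fruit-only subsidy and are filled with arbitrary
negative-diagonal values.

## Numerical conventions

Percent-change quantities are fractions internally and percentages at I/O
(JSON results carry a `units` block). Expenditure is `sum(q/100 * p)`.
Conservation guarantees are enforced to 1e-9 relative; oracle equivalence
to 1e-12; the 95% z-multiplier is 1.959964. Monte-Carlo runs derive one
substream seed per iteration from the master seed, so iteration $k$ is
reproducible in isolation; empirical percentiles use R's default quantile
type 7. Failed iterations are logged, excluded and counted, never fatal.

## Known limitations

* Pass-through is fixed at 100% with constant producer prices.
* The steady-state energy-to-weight rule ignores adaptation dynamics; it
  is a deliberate simplification of dynamic weight models.
* Sampled PE matrices may violate adding-up (diagnostic only, see above).
* The between-group disaggregation rule means a simultaneous 1% price rise
  in *all* sub-foods of another group produces a response of (group size)
  x (aggregate cross-PE); uniform replication conserves weighted
  re-aggregation, not uniform-price-shock response. This mirrors the
  method's focus on nutrient-targeted (within-group differentiated)
  price changes.
* Lifetable cohorts do not accrue newborns; the model covers the
  population alive at baseline, as the method intends.

## A complete run

```{r example}
cfg <- synthetic_config(n_groups = 23, seed = 42)
fs  <- make_food_system(cfg)
w   <- expenditure_shares(fs)
pe  <- make_pe_matrix(w, cfg)
ee  <- make_ee_vector(w, cfg)
tax <- policy_spec("SAFA tax $2/100g", nutrient_taxes = c(safa = 2))

conv <- run_policy_scenario(fs, tax, pe, mode = "conventional")
adj  <- run_policy_scenario(fs, tax, pe, ee, tfee = 0.75)

c(fpi = adj$fpi_pct,
  revealed_conventional = revealed_tfee(conv),
  revealed_adjusted     = revealed_tfee(adj))
```

```{r uncertainty}
spec <- uncertainty_spec(pe = pe, n_iter = 200, seed = 1)
fn <- function(params) {
  pe_k <- if (is.null(params$pe)) pe else params$pe
  res <- suppressWarnings(run_policy_scenario(fs, tax, pe_k, ee, params$tfee))
  c(expenditure_pct = 100 * (res$x_a / res$x_b - 1),
    energy_pct = res$summaries$pct_change[2])
}
monte_carlo(fn, spec)$summary
```
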