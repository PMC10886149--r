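---
title: "Model-based enzymatic glucose release: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based enzymatic glucose release: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzfeed)
```

## The problem

Mini-bioreactors (~10 mL) in robotic cultivation facilities usually have no
pumps, so the carbon-limited fed-batch mode that dominates industrial
bioprocessing cannot be run as a continuous feed. An alternative is
enzyme-mediated glucose release: glucoamylase (EC 3.2.1.3) cleaves glucose
monomers from the non-reducing ends of soluble maltodextrin, so the vessel
feeds itself at a rate set by the enzyme and substrate concentrations.
The difficulty is control: the hydrolysis kinetics are non-linear and depend
on the substrate composition, so realizing a *defined* feed profile — e.g.
an exponential profile that holds the specific growth rate at a setpoint —
requires a calibrated kinetic model and a planner that converts target
release rates into timed enzyme additions. `enzfeed` implements that
pipeline: kinetic model, event-driven simulator, multi-experiment parameter
estimation, feed planner, and a growth coupling for end-to-end simulation.

## The release model

The state of a vessel is (P, S, WS, E, V): free glucose (g/L), total
dextrin (g/L), the susceptible proportion of the dextrin, enzyme activity
(U/L) and volume (L). The dextrin is partitioned into a *susceptible* pool
SS = WS·S hydrolysed quickly and a *resistant* pool SR = (1−WS)·S hydrolysed
slowly. Both compete for the same enzyme with a shared Michaelis constant:

$$r_S = \frac{k_S\,E\,SS}{SS+SR+K}, \qquad r_R = \frac{k_R\,E\,SR}{SS+SR+K}$$

$$\frac{dP}{dt} = \nu\,(r_S+r_R) - \frac{\dot V}{V}P,\qquad
  \frac{dS}{dt} = -(r_S+r_R) - \frac{\dot V}{V}S,\qquad
  \frac{dW_S}{dt} = \frac{-r_S + W_S\,(r_S+r_R)}{S}$$

with $\dot V = -r_{evap}$ (evaporation removes water only) and
$dE/dt = -(\dot V/V)E$. The factor $\nu = 1.111$ converts anhydroglucose in
the polymer into free glucose (hydration mass gain: 1 g polymerized glucose
yields 1.111 g glucose), so complete hydrolysis of D g/L dextrin yields
`max_release(D)` $= \nu D$ g/L. The WS equation follows from the quotient
rule applied to WS = SS/S; its boundary values 0 and 1 are fixed points, so
WS stays in [0, 1] along any trajectory.

Default parameters are the reference fit for DE≤5 maltodextrin at 30 °C and
pH 7.0: kS = 0.134 g/(U h), kR = 0.00212 g/(U h) (the resistant pool is
~60-fold slower), WS0 = 0.464, K = 0.001 g/L. K is *fixed*, not estimated:
at working substrate concentrations of tens of g/L the kinetics are
effectively zero order in substrate and K is not identifiable; the low
value is consistent with the saccharification literature.

Seven model variants are available for model selection
(`model_variants()`): single- vs two-substrate kinetics, optionally with
product inhibition and/or substrate inhibition. The inhibition forms are
this package's choice of the standard extensions — competitive product
inhibition replaces K by $K(1+P/K_{iP})$, substrate inhibition adds
$S^2/K_{iS}$ to the denominator. They are stated here explicitly because
different saccharification papers use slightly different forms; tests rely
only on their limiting behaviour (they reduce to the parent model as
$P \to 0$ resp. $K_{iS} \to \infty$).

### Numerical choices

* Integration uses `deSolve::lsoda` with rtol 1e−8 / atol 1e−10; the
  right-hand side is compiled (C) and an equivalent R implementation
  (`release_rhs()`) defines the model readably — a test pins both to each
  other.
* Events (boluses, samples) are realized by *segmenting* the integration,
  never by root-finding: the solver is stopped at the event time, the
  volume-dependent states are recomputed from the mixing mass balance, and
  the solver is restarted. Values recorded at an event time are the
  pre-event (left-limit) states, matching the convention that a sample is
  drawn before liquid is added.
* A zero-substrate threshold of 1e−12 g/L guards the WS equation against
  division by zero; below it $dW_S/dt := 0$. Negative concentrations from
  solver round-off are clipped to zero after each segment.
* During estimation, all vessels sharing a clock are stacked into one ODE
  system with shared kinetic parameters, so one solver call integrates the
  whole campaign segment; this is purely a performance device and a test
  pins it against the single-vessel path.

## Events and the mixing mass balance

A bolus of volume v at stock concentration $C_{stock}$ updates every
concentration by the per-species mass balance
$C' = (CV + C_{stock}v)/(V+v)$, where the stock term is non-zero only for
the added species (ideal instantaneous mixing — the only physically
consistent rule for a stirred vessel). Added dextrin is split between the
pools with the stock's susceptible fraction WS0: fresh stock replenishes
the susceptible pool, which is what makes resistant dextrin accumulate over
a long feeding phase. A sample removes volume at unchanged concentrations.
pH-control reagents and water are modelled as pure dilution (their
chemistry is out of scope). Default stocks: 3000 U/L enzyme, 150 g/L
dextrin, 600 g/L glucose.

Two conservation laws make good end-to-end checks and are asserted in the
test suite: the glucose-equivalent mass $V(P/\nu + S)$ is a first integral
of the reaction (evaporation removes only water), and per-species ledgers
(added stock − sampled mass) close across arbitrary event sequences.

## Parameter estimation

All experiments of a campaign are fitted *simultaneously*: the objective is
the sum of squared glucose residuals over every experiment and sampling
time (glucose is the only measured species in the cell-free stage;
residuals are unweighted by default, per-point weights are supported).
`WS0` is an initial-condition parameter — each candidate value resets the
initial susceptible proportion of every vessel and of added dextrin stock.

The global stage (`fit_global()`) is a self-adaptive differential
evolution (jDE scheme: per-member F and CR, resampled with probability 0.1)
with population 20 over 200 generations, deterministic for a given seed,
followed by a bounded Levenberg–Marquardt polish (`minpack.lm`) that also
supplies linearized standard deviations,
$\sqrt{\mathrm{diag}(RSS/(n-p)\,(J^TJ)^{-1})}$. Default bounds span the
literature by orders of magnitude: catalytic constants in [1e−5, 1]
g/(U h), WS0 in [0, 1], inhibition constants in [0.1, 1000] g/L.

One structural subtlety: the two-pool model is exactly invariant under
relabelling the pools, $(k_S, k_R, W_{S,0}) \leftrightarrow
(k_R, k_S, 1-W_{S,0})$. The likelihood therefore has two mirrored global
optima, and a population-based search that straddles both basins mixes
useless difference vectors. The fit resolves this with the standard
identifiability convention that the susceptible pool is the fast one
($k_S \ge k_R$): every candidate is folded onto that half-space before
evaluation.

`compare_variants()` runs one global+local fit per variant and tabulates
RSS in the canonical order. Because the variants are nested, an inhibition
term can never worsen the attainable RSS; the test suite asserts this up to
optimizer tolerance.

## Feed planning

Enzyme (and dextrin) additions happen on a fixed temporal grid
(Δt = 10 min by default — the cadence at which a liquid handler can visit a
vessel between its other duties). For a target release rate $r_{target}$ at
grid time $t_i$, the enzyme increment follows from the rate law's
linearity in E:

$$E_{add,i} = \left(r_{target} - \frac{dP}{dt}\Big|_{t_i}\right)
  \frac{S+K}{\nu\,(k_S SS + k_R SR)}, \quad \text{clamped at } 0,$$

where the current rate uses the reaction term only (dilution and
evaporation excluded — the expression derives from the reaction kinetics,
and the dilution contribution over 10 min is negligible). The increment is
converted to a pipetting volume by inverting the mixing balance, so the
post-bolus concentration hits $E + E_{add}$ exactly. The clamp reflects a
hard physical constraint: the release rate cannot be reduced actively, only
by substrate depletion. After a downward setpoint step (e.g. at induction)
the realized rate therefore exceeds the target until the susceptible pool
has decayed; `realized_rates()` marks such intervals `clamped`.

The planner is closed-loop over the model: each interval is integrated
exactly from the current state, so the difference-quotient approximation
error made in one interval does not propagate — the cumulative relative
error never exceeds the worst single-interval relative error (asserted
numerically). The approximation regime is quantified by the guard
$r_S\,\Delta t / S$: where it is below 0.01 and the planner is not clamped,
per-interval tracking is within 2 %. An optional single-interval shooting
refinement (minimize the squared end-of-interval release error over
$E_{add,i}$, initialized at the closed-form value) is available but off by
default; in the guard regime it changes doses only marginally.

Growth-rate setpoints are converted to release-rate targets by the standard
exponential fed-batch law
$r(t) = (\mu_{set}/Y_{XS})\,X_0\,e^{\mu_{set}(t-t_0)}$, with the biomass
carried over at phase switches. The yield $Y_{XS}$ (default 0.5 g/g) is a
user-calibrated constant of the strain and medium, not a package-fitted
value. Dextrin maintenance defaults to 40 µL of 150 g/L stock every
10 min, keeping the substrate concentration high so that the zero-order
regime (and the guard) holds.

## Growth coupling

The cultivation simulator couples the release model to a macro-kinetic
*E. coli* model of the standard overflow-metabolism family: Monod glucose
uptake ($q_{S,max}$ = 1.4 g/(g h), Ks = 0.05 g/L, so $\mu_{max} =
Y_{XS} q_{S,max} \approx 0.7$ 1/h), a critical specific uptake above which
the excess goes to acetate, acetate re-uptake with spare capacity, an
oxygen balance with kLa transfer driving the dissolved-oxygen tension
(DOT), and, after induction, a reduced uptake capacity (metabolic load)
with first-order product formation. All growth-side coefficients are
illustrative defaults to be calibrated per strain; the growth module is
deliberately property-tested (reduction to cell-free dynamics at X = 0,
carbon-ledger closure, qualitative DOT signatures: sawtooth under bolus
feeding vs a smooth steady decrease under enzymatic feeding, setpoint
tracking within 15 %), never against quantitative literature trajectories.

The specific growth rate is estimated by `observed_mu()` as the
least-squares slope of ln X vs t. In fed-batch, repeated feed boluses
dilute the biomass *concentration*, so the tracking tests and the
acceptance script apply the estimator to the total biomass X·V
(dilution-corrected), the standard practice for fed-batch growth-rate
estimation.

## The synthetic campaign generator

`dataset1_designs()` emulates the cell-free calibration campaign: 24 runs
of 11 mL over 30 h, full factorial in initial dextrin {15, 30} g/L,
glucose {0, 3.75, 7.5, 15} g/L and enzyme {10, 20} U/L (16 runs), plus 8
runs carrying the non-zero dextrin/glucose addition patterns
({5.25, 10.5} / {3.75, 7.5} g/L) applied at 6 h, so that every factor
level occurs. The exact run-by-run allocation of additions is this
package's deterministic choice; a user design table can replace it.
Sampling is on a fixed 2 h grid. The 200 µL sample removals are not
inserted as events by default — they leave concentrations unchanged and
perturb later dilution ratios at the sub-percent level on 11 mL
(`include_sampling = TRUE` restores them). Measurement noise is additive
Gaussian truncated at zero with σ = 0.2 g/L by default; the analyzer's
true precision is not a published constant, so σ is a documented stand-in,
and seeds make every generated set reproducible.
`dataset23_designs()` provides the fed-batch campaign descriptors
(conditions in triplicate: bolus-fed controls, enzymatic feeds at several
$\mu_{set}$ pairs switching at induction 6 h into feeding, and cell-free
controls) from which plans and cultivation simulations are built.

What passing the synthetic loop shows — and what it does not: recovering
the generating parameters from noisy synthetic data demonstrates the
estimator and the identifiability of (kS, kR, WS0) under the campaign's
design, but it cannot detect model misspecification against real dextrin
(lot-to-lot variation of the susceptible fraction, pH/temperature
dependence, mass-transfer effects at high substrate). The recommended
practice mirrors the experimental one: recalibrate kS (and WS0) against
cell-free control vessels run alongside each cultivation campaign — under
cultivation aeration the effective kS has been observed markedly lower
(0.076 vs 0.134 g/(U h)) — and the fitting entry points accept any
user-supplied measurement table for exactly this purpose.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full pipeline at the
study's native scale: 24 vessels × 15 sampling times (360 observations)
per fit, DE population 20 × 200 generations plus polish per variant, 10-min
planning grids over 6–10 h horizons, and 6 h cultivation simulations.
Every stochastic step (noise generation, DE) consumes an explicit seed;
repeated runs are bit-for-bit identical.

## Known limitations

* Temperature and pH dependence of the kinetics are not modelled; the
  parameters are valid for the calibration conditions only.
* Enzyme inactivation is not modelled (the stock was found stable under
  incubation; high shear/aeration can nonetheless lower effective
  activity — recalibrate rather than extrapolate).
* Release rates cannot be decreased actively; plans with decreasing
  setpoints are met only as fast as the susceptible pool decays.
* The growth module is a structurally plausible stand-in with
  illustrative coefficients; quantitative reproduction of real cultivation
  trajectories requires strain-specific calibration.
* Resistant dextrin accumulates over long feeding phases, which bounds the
  achievable release and the useful cultivation length.
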