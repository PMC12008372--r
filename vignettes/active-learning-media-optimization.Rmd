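---
title: "Active-learning optimization of culture media: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-learning optimization of culture media: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Culture-media optimization is a high-dimensional search problem: a defined
medium has a dozen or more components whose concentrations can plausibly vary
over one to two orders of magnitude, and production responds to them jointly
and non-linearly. `medialearn` implements the machine-learning-led
Design-Build-Test-Learn (DBTL) loop for this problem: space-filling initial
designs, a probabilistic surrogate trained on all observations so far, batch
recommendation of the next designs by balancing exploration against
exploitation, Shapley-value attribution of the fitted surrogate, and the
bench-level plumbing (stock calculation, plate layout, liquid-handler
worklists) that turns recommended concentration vectors into pipetting
instructions. A synthetic flaviolin-response simulator stands in for the
wet-lab Test step so the entire pipeline can be exercised and scored against
a known ground truth.

```{r setup}
library(medialearn)
```

## The phase space and initial designs

A `phase_space` is an ordered list of media components, each with a base
concentration (the starting recipe), lower/upper search bounds, a solubility
limit, and a fixed/variable flag. The bundled `mops_phase_space()` is a
15-component MOPS-like medium — glucose, MOPS buffer and Tricine fixed, 12
variable components — whose bounds span roughly 1.5 orders of magnitude
around the base recipe. The base values are plausible MOPS-medium
concentrations recorded as package defaults; they are synthetic parameters,
not a published recipe.

Initial cycles use Latin hypercube sampling (`lhs_design()`): for each
variable component the n designs occupy n distinct equal-probability strata,
one design per stratum. Because the bounds span orders of magnitude, strata
are laid out in log concentration by default (a component with a zero lower
bound falls back to linear strata; a linear layout is also selectable).
Sampling in log space means low, middle and high decades are explored evenly
rather than crowding the top decade, and the same transform is used when
scaling inputs for the surrogate, so model and design agree about the
geometry of the space.

Each plate also carries control wells: replicates of the base medium with up
to ±10% uniform multiplicative jitter on every variable component
(`jitter_control()`). Controls probe between-cycle repeatability and expose
the model to small perturbations around the incumbent recipe. Jitter is
clipped only at solubility, not at the search bounds, because controls
represent the base medium rather than the search box.

## The media compiler

`stock_table()` derives two stock concentrations per component: the high
stock delivers the upper bound at a reference transfer volume (150 µL into a
1500 µL well), capped at the solubility limit; the low stock is a 1:20
dilution, diluted further if the lower bound would otherwise need less than
the 5 µL instrument minimum. `compile_plate()` then emits one transfer per
nonzero component per well — high stock if its volume clears the minimum,
otherwise low stock — plus a 2% inoculum transfer and a water top-up to
exactly 1500 µL. Volumes are exact in the plan (re-simulating the mixing
reproduces every target concentration to 1e-9 relative) and are rounded to
0.01 µL only when `write_worklist()` prints the CSV. A full triplicate plate
(15 designs + control, 12 variable + 3 fixed components) compiles to roughly
800 transfers, which is why this step is automated at all.

`layout_plate()` assigns wells row-major on the 48-well plate: 15 designs ×
3 replicates + 1 control (48 = 16 × 3), or 11 × 4 + control (48 = 12 × 4),
with the control block in the final wells.

## The ensemble surrogate

`fit_ensemble()` fits four base learners on unit-scaled inputs and a
standardized response: a Gaussian-process regressor (isotropic RBF kernel,
unit signal variance; lengthscale from the median heuristic refined over a
small multiplier grid, nugget from a small grid, both chosen by marginal
likelihood), a random forest (200 trees), gradient-boosted trees (60 rounds,
depth 3, learning rate 0.1), and ridge regression. The GP is implemented in
closed form inside the package so that its noise floor can be arbitrarily
small — on noiseless data its posterior variance collapses at the training
points and grows back to the prior away from them, which the acquisition
relies on.

Member weights come from grouped k-fold cross-validation (k = 5; replicates
of one design always share a fold, so the model is never scored on a
replicate of a design it trained on): `w ∝ exp(-RMSE_cv / τ)` with
temperature τ set to the median member RMSE. The softmax keeps every member
in play while letting the data decide how much to trust trees versus smooth
interpolators on each campaign. Predictions are mixture moments:
`E = Σ w_i μ_i` and `Var = Σ w_i (σ_i² + μ_i²) − E²`. Members without a
native predictive variance (forest, boosted trees, ridge) contribute their
out-of-fold residual variance as σ_i². A response with zero variance
triggers a constant-model fallback with a warning rather than an error.

`cross_validated_r2()` reports the pooled out-of-fold R² under the same
grouped folds — the per-cycle predictive-power metric a campaign logs. It
can be negative; with fewer replicate groups than folds, k is reduced with a
warning.

## Acquisition, schedule, and batch recommendation

Recommendations maximize `G(x) = (1 − α) E(y) + α Var(y)` over the
phase-space box. At α = 1 this is pure exploration (seek the model's most
uncertain region), at α = 0 pure exploitation (seek the highest predicted
response). The default schedule is linear and decreasing,
`α(N) = (total − N) / (total − 1)`, so the first cycle maximizes variance
only and the final cycle maximizes the mean only; an increasing
`α = 0.1 N` variant is selectable (`alpha_schedule(..., variant =
"literal")`). We default to the decreasing schedule because only it makes
the endpoints self-consistent: exploration has its value early, when the
surrogate knows least, while the final cycle should cash in.

The maximization itself is differential evolution (rand/1/bin, crossover
0.9, weight 0.8) over the unit-scaled box, with the objective evaluated on
the whole population per generation so surrogate predictions are batched.
For a standalone `optimize_acquisition()` call the defaults are a population
of 15·d and up to 500 generations with a relative fitness-spread stopping
tolerance of 1e-6. Inside campaign and benchmark loops, where hundreds of
maximizations run back-to-back, the package uses a reduced budget
(population 20, 40–60 generations); the acquisition surfaces there are
surrogate-smooth and the loss from a slightly inexact argmax is far smaller
than the replicate noise being optimized against.

`recommend_batch()` draws K designs sequentially: the first
`round(K · explore_fraction)` at α = 1, the rest at the scheduled α. Each
accepted design excludes an ε-ball (ε = 0.05 in unit space) around itself
via a penalty added to the objective, which is what keeps 11–15
recommendations distinct rather than 15 copies of the same argmax. The
campaign default explore fraction declines linearly from 2/3 in the first
active-learning cycle to 1/3 in the last: exploration keeps a foothold in
every cycle, but the emphasis shifts to exploitation as data accumulate.

## Shapley attribution

`shapley_values()` attributes the ensemble's mean prediction to the
components. The baseline is a single reference point — the column means of
the training observations — and an "absent" feature is set to its reference
value. The exact method enumerates all 2^d coalitions (feasible for d ≤ 15;
one batched model call per explained point) with the standard Shapley
weights; the sampled method averages marginal contributions over uniformly
random feature permutations and flags results built from fewer than 10
permutations. Efficiency (per-point attributions sum to prediction minus
baseline), the dummy axiom, symmetry, and the linear-model closed form are
all tested. The single-reference baseline is deliberate: it matches the
"set the component to its average observed concentration" semantics; a full
background-distribution expectation would average over a reference sample
instead and is left as an extension.

`rank_features()` orders components by mean |φ|, ties broken by component
order. On simulated campaigns this ranking is a parameter-recovery check:
the simulator's dominant component must come out first.

## The synthetic flaviolin simulator

`make_default_simulator()` builds a hidden response surface over the
MOPS-like space with the statistical structure the analysis assumes:

- **Five active components.** NaCl (dominant), K2HPO4 and K2SO4 with peaked
  log-Gaussian response factors (optima at 450 mM = 9× base, 5× base, 3×
  base; widths 1.0–1.5 decades), NH4Cl and FeSO4 with saturating Hill
  curves (coefficient 2). All other variable components are exactly inert.
  Effect weights are exponents on the factors; NaCl's (1.5) is strictly the
  largest, so the attribution test has a unique correct answer.
- **Calibration.** The factors multiply into `max_titer`, calibrated so the
  unmodified base medium produces exactly 95 mg/L; the composed optimum is
  ≈ 260 mg/L, i.e. a ≈ 2.7× headroom consistent with the titer-proxy gains
  the approach is expected to find.
- **Measurement model.** The optical proxy is linear in true titer with a
  positive intercept, `Abs340 = 0.004 · titer + 0.05`, multiplied by
  lognormal noise with 10% coefficient of variation (an additive-Gaussian
  option exists for robustness checks). Yield mode divides the proxy by the
  design's initial glucose.
- **Titer-yield tradeoff.** True titer scales as `(glucose/base)^0.4`, so
  when glucose is variable, titer rises with glucose while proxy yield
  falls — reproducing the tradeoff a yield campaign must navigate.

What the simulator does *not* emulate: mechanistic osmotic-stress or
precursor-flux effects, component interactions (the surface is separable by
construction), batch effects between cycles, or heteroscedastic noise.
Passing the end-to-end tests therefore shows that the learning loop can
find a known optimum and recover a known dominant component under realistic
noise — not that it would behave identically on a real organism.

## Campaign orchestration

`run_campaign()` wires the loop together: one LHS batch split across the
first two cycles, then fit → recommend → simulate per cycle, with jittered
controls on every plate. Before each fit, `filter_outliers()` drops whole
designs whose replicate sets betray liquid-handling failures: any replicate
below 0.2× the design's replicate median in Abs340 or OD600 (a well that
never grew), or above 2.0× the median in Abs340 (carried-over cells). The
failure modes these rules encode have no canonical numeric thresholds, so
the 0.2/2.0 defaults are the package's own choice and both are
configurable. Recommendations for cycle N are computed strictly from
cycles 1..N−1 — the accumulated record is the only input — and fixed seeds
make entire campaigns bit-reproducible.

The default desk-scale study runs 5 cycles of 15 designs × 3 replicates
(2 LHS + 3 active-learning), attribution on the final model capped at 100
explained points, and per-cycle cross-validated R² optional. These sizes
are the package's reference configuration for simulation studies; larger
campaigns only change runtime.

## The synthetic-function benchmark

`run_simulated_campaign()` runs the comparison protocol: 16
LHS starting observations in 15 dimensions, 10 cycles of 16
recommendations, repeated with independent seeds, all optimizers sharing
bit-identical starting data within a repeat, and performance tracked as
`Y*` — the best response so far normalized by the function's true optimum
(computed by per-dimension brute force for the separable functions). Three
optimizers are built in: the package's ensemble + DE recommender, a plain
GP with the same acquisition, and a quadratic response-surface (RSM)
baseline that has no predictive variance and therefore always exploits.
The RSM and GP baselines are internal stand-ins for the commercial DoE and
GP-autonomous-experimentation tools they represent, not reimplementations
of them.

The benchmark functions' variable domain is not something the functions
themselves fix, and it decides the comparison's character. We use
`[-4, 4]^15` for the easy and medium functions and `[0, 10]^15` for the
difficult one. The choice is principled: the L2-optimal quadratic
approximation of the quartic term `x⁴ − 16x²` on `[-L, L]` has curvature
`6L²/7 − 16`, which is negative exactly when `L < 4.32`. At `L = 4` a
second-order response surface therefore fits a downward parabola, is drawn
into the (negative-valued) interior of the medium function, and never finds
the `x = 4` corner optimum — while on the easy function the optimum *is* a
corner of the box and the quadratic fit identifies it exactly. On wider
boxes the quadratic approximation turns convex and the RSM trivially
corner-seeks every function, which would erase the very difficulty ordering
the three functions exist to create.

## Numerical choices and degenerate inputs

- Input scaling: per-component log transform to `[0,1]` when the lower
  bound is positive, linear otherwise; queries outside the box are
  predicted but flagged as extrapolation.
- GP: Cholesky solves with a nugget ≥ 1e-6; non-PD grid candidates are
  discarded during hyperparameter selection; posterior variances clamped at
  zero.
- DE: at least one mutated coordinate per trial vector; mutants clipped to
  the box, so bound optima are exactly reachable.
- Ties in feature ranking break by component order; ties in stock selection
  go to the high stock.
- Worklist volumes print at 0.01 µL; the plan retains full precision and is
  validated pre-rounding.
- Degenerate inputs: zero-variance responses (constant-model fallback with
  warning), fewer replicate groups than folds (k reduced with warning),
  batches that cannot place K ε-separated designs (shorter batch with
  warning flag), non-convergent DE (best-so-far with flag).

## Known limitations

The surrogate roster is fixed; automated model search over member types is
out of scope. The acquisition handles box bounds only — no mixture
constraints (e.g. total osmolarity) and no multi-objective titer/yield
Pareto recommendation. The sampled Shapley estimator uses independent
permutations per point rather than antithetic or stratified sampling. The
benchmark's parallel-tempering recommender variant is not implemented;
differential evolution is the recommendation engine throughout. Observation
I/O is a local flat-CSV dialect; talking to an experiment-data service is
deliberately not included.
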