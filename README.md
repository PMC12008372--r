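# medialearn

Machine-learning-guided optimization of microbial culture media.

Finding the medium that maximizes production of a target metabolite is a
search over a phase space with 12–13 variable components, each spanning one
to two orders of magnitude — far beyond one-factor-at-a-time
experimentation. `medialearn` implements the active-learning
Design-Build-Test-Learn (DBTL) loop for this problem end to end:

- **Design** — Latin hypercube initial designs over the bounded
  concentration box (log-scale strata), plus ±10%-jittered control designs
  on every plate;
- **Build** — a media compiler that derives high/low stock concentrations
  per component, lays out 48-well plates (15 designs × 3 replicates + 1
  control, or 11 × 4 + 1), and emits liquid-handler worklists (~800
  transfers per plate);
- **Test** — a synthetic flaviolin-response simulator (separable response
  surface, 5 active components with NaCl dominant, 10% replicate CV,
  optical proxy linear in titer) standing in for cultivation and
  absorbance measurement, so the full loop is testable against known
  ground truth;
- **Learn** — a probabilistic ensemble surrogate (Gaussian process, random
  forest, gradient-boosted trees, ridge; weights from grouped
  cross-validation) predicting response mean `E(y)` and variance `Var(y)`;
- **Recommend** — batch maximization of the acquisition

  `G(x) = (1 − α) E(y) + α Var(y)`

  by differential evolution, with α scheduled from 1 (pure exploration,
  first cycle) to 0 (pure exploitation, final cycle) and an ε-separation
  rule keeping the batch diverse;
- **Explain** — exact (2^d-coalition) or permutation-sampled Shapley
  values of the fitted surrogate, attributing predicted production to
  individual media components;
- **Benchmark** — a synthetic-function comparison harness (easy /
  medium / difficult objectives, 16 starts, 16 recommendations × 10
  cycles, `Y*` = best-so-far normalized by the true optimum) pitting the
  ensemble recommender against quadratic response-surface and plain-GP
  baselines.

## Worked example

A five-cycle simulated campaign on the bundled MOPS-like phase space
(12 variable components; glucose, MOPS and Tricine fixed):

```r
library(medialearn)

space <- mops_phase_space()
sim   <- make_default_simulator(space)   # hidden truth: NaCl optimum 450 mM
cfg   <- campaign_config(space, cycles = 5, designs_per_cycle = 15,
                         replicates = 3, seed = 11)
res   <- run_campaign(cfg, sim)
res
#> DBTL campaign: 5 cycles, objective titer_proxy
#>  cycle n_obs n_removed     cv_r2 best_response
#>      1    48         0        NA      1.019048
#>      2    96         0 0.3818250      1.019048
#>      3   144         0 0.7830275      1.085379
#>      4   192         0 0.8610879      1.097389
#>      5   240         0        NA      1.138817
#> Best design: c5_rec_c5_10 mean response 1.139

head(rank_features(res$attribution), 3)
#>   feature mean_abs_phi rank
#> 1    NaCl   0.12716688    1
#> 2   NH4Cl   0.06836475    2
#> 3   FeSO4   0.05789823    3
```

Reading the output: `best_response` is the best per-design mean Abs340 so
far (the base medium reads ≈ 0.43, so 1.14 is a ≈ 165% proxy gain);
cross-validated R² grows from 0.38 after the two Latin-hypercube cycles to
0.86 as active learning concentrates data in informative regions; and the
Shapley ranking recovers NaCl — the simulator's dominant hidden driver —
as the most important component. Checking against the hidden truth:

```r
opt <- simulator_optimum(sim)
best <- max(true_titer(sim, as.matrix(
  res$records[res$records$role != "control", space$components$name])))
best / opt$titer
#> [1] 0.9495414
```

i.e. the campaign found a medium within ~5% of the true optimum of the
hidden surface after testing 75 designs.

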