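# carousel

Mass-action modelling of how a G-protein-coupled receptor (GPCR) pathway can
respond to the **fraction** of occupied receptors rather than their absolute
number.

Classical receptor theory says the stimulus is proportional to the amount of
agonist–receptor complex, `S = ε[LR]`, so changing receptor abundance must
change the dose-response curve. Yet the yeast pheromone pathway (Ste2
receptor → Gpa1/Ste4/Ste18 G protein, with the RGS protein Sst2 bound to the
receptor) responds nearly identically over a 100-fold range of receptor
abundance. The *carousel* model explains this: it composes the ternary
complex model with the three-state G-protein cycle,

* receptors bind ligand (clamped `[L]`; `Kd = 5.6 nM`) and couple
  reversibly to Gα in every nucleotide state (`Kd = 33 nM`),
* ligand-occupied receptors are GEFs: they accelerate GDP/GTP exchange and
  the release of free Gβγ (`kE·LRG = 1.5/s` vs a basal `6.2e-4/s`),
* the receptor-bound RGS is a GAP: GTP hydrolysis is fast on
  receptor-coupled Gα·GTP (`0.11/s`) and slow on free Gα·GTP (`0.002/s`).

Occupied receptor–RGS complexes therefore *push* (activate the Gα they
meet) while unoccupied ones *pull* (deactivate them). When Gα subunits visit
many receptors, the active fraction of G protein equilibrates to the
fraction of occupied receptors — a ratiometric measurement that is robust to
receptor abundance by construction, and (in the right rate regime) aligns
the output EC50 with the occupancy EC50 (dose-response alignment, DoRA).

The package provides:

* the reaction network in three variants — the 12-species simplified model,
  an extended model with explicit RGS–receptor binding, and a two-pool
  model for dominant-negative receptor mixtures (`build_network()`);
* a steady-state solver stable across 8-decade parameter variation
  (`solve_steady_state()`, compiled kernel + independent deSolve route);
* dose-response simulation and summaries (`simulate_dor()`, `amplitude()`,
  `ec50()`, `dora_ratio()`), plus the classical receptor-theory baseline
  (`receptor_theory_effect()`);
* log-uniform Latin hypercube sampling of the kinetic parameter space
  (`lhs_spec()`, `lhs_sample()`);
* a global robustness scan — per-point classification (robust amplitude /
  robust EC50 / robust response / DoRA), 2D histogram matrices, and
  automatic mining of pairwise parameter restrictions (`run_scan()`,
  `classify_point()`, `histogram_matrix()`, `mine_restrictions()`,
  `dora_subanalysis()`);
* a YAML-configured end-to-end pipeline with plain-text, diffable outputs
  (`load_config()`, `run_pipeline()`).

## Worked example

```r
library(carousel)

p  <- carousel_params()        # reference rates (nM, s)
cv <- simulate_dor(p)          # steady-state dose-response, 26-point grid

amplitude(cv)
#> [1] 0.9241
dora_ratio(cv)[c("ec50_output", "ec50_occupancy", "ratio")]
#> $ec50_output    3.12
#> $ec50_occupancy 5.62
#> $ratio          0.555

classify_point(p)
#>   normal_amplitude robust_amplitude robust_ec50 robust_response dora
#> 1             TRUE             TRUE        TRUE            TRUE TRUE
```

Read: at the reference parameters the pathway turns on 92% of its G protein
at saturating pheromone from a basal activation of 0.7%, with an output
EC50 (3.1 nM) within 2-fold of the receptor occupancy EC50 (5.6 nM ligand
Kd) — aligned transfer. `classify_point()` re-simulates the curve at 0.1×,
1× and 10× receptor abundance and finds amplitude and EC50 essentially
unchanged: a robust, fraction-measuring response. Single-parameter changes
switch the regime — `koff_RG = 0.001` (precoupling) loses robustness to
receptor decrease, `koff_RG = 10` sensitizes the output, and
`kH_Gt = kH_RGt = 0.11` (GAP activity no longer receptor-localized)
abolishes robustness, which is the package's in-silico version of replacing
the receptor-binding RGS with a delocalized one.

A scan over parameter space:

```r
draws <- lhs_sample(lhs_spec(n = 1000, seed = 1))  # 12 params, 8 decades
scan  <- run_scan(draws)
scan$fractions                                     # % of sampled points
robust <- draws[scan$labels$robust_response, ]
mine_restrictions(robust)                          # pairwise inequalities
```

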