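# tiplinkmech

Single-molecule mechanics of the hair-cell tip-link — the Cdh23–Pcdh15
adhesion complex that conveys sound-driven force to mechanotransduction
channels — analysed three ways, with synthetic-data generators that make
every stage testable against known ground truth:

1. **smFRET conformations**: donor/acceptor trace correction, per-trace
   efficiency with acceptor-bleach detection, histogram peak fitting,
   and Förster inversion `d = R0*((1-E)/E)^(1/6)` with `R0` calibrated
   from a reference efficiency–distance pair.
2. **Dynamic force spectroscopy (AFM)**: classification of specific
   events by their PEG-tether signature (FJC fit,
   `L(F) = Lc[coth(F·Lk/kBT) − kBT/(F·Lk)]`), rupture forces,
   tether-corrected per-event loading rates, and Bell–Evans regression
   `F_mp = (kBT/xβ)·ln(vF·xβ/(koff0·kBT))` yielding the intrinsic
   off-rate `koff0` and distance to the transition state `xβ`.
3. **Force-propagation networks**: residue graphs from contact
   occupancy (4.5 Å / 75% rule) weighted by `w = −log|c|` from
   dynamical cross-correlations; Girvan–Newman communities,
   Floyd–Warshall optimal paths, bounded suboptimal-path enumeration,
   edge-usage ranking, orthogonal-component analysis, RMSF, and
   interdomain angles.

The package is aimed at single-molecule biophysicists who want these
estimators as tested building blocks, and at anyone who needs a
desk-scale closure harness for this class of experiment.

## Worked example

Simulate a dynamic force spectroscopy experiment at the wild-type
landscape parameters and recover them with the full pipeline:

```r
library(tiplinkmech)

cfg <- curve_gen_config(n_curves = 1800, specific_fraction = 1,
                        bell = bell_evans_params(4.5e-3, 0.18), seed = 30)
ana <- dfs_analysis(gen_force_curves(cfg))
ana$points
#>   velocity     F_mp  F_sigma      LR_mp n_events
#> 1      200 240.0918 18.72185   4480.383      290
#> 2      500 263.4393 17.44541  11386.531      293
#> 3     1000 277.0505 30.27849  22938.527      295
#> 4     2000 301.0276 18.19859  46379.307      296
#> 5     3000 305.7142 18.66969  69753.856      293
#> 6     5000 313.4044 18.09427 116799.393      290
ana$bell
#> Bell-Evans: koff0 = 0.0061 /s, x_beta = 0.177 nm, theta = 0 rad
#>   SE: koff0 0.0038, x_beta 0.0099
```

Each row is one retraction velocity: the Gaussian peak of its
unbinding-force histogram (`F_mp`, pN) and of its log loading-rate
histogram (`LR_mp`, pN/s). The regression slope `kBT/xβ` recovers the
generating transition distance (0.18 nm) within its standard error, and
the intercept the off-rate (4.5e-3 /s) within the honest
factor-of-~1.5 uncertainty of a 1.4-decade extrapolation.

FRET distances from the calibrated Förster inversion:

```r
cal <- calibrate_R0(E_ref = 0.68, d_ref = 4.62)   # wild-type reference
cal$R0
#> [1] 5.238438
efficiency_to_distance(c(0.48, 0.40), cal)
#> [1] 5.308789 5.604674
```

A planted force-propagation path recovered from a synthetic trajectory:

```r
n <- 14
cfg <- traj_gen_config(
  n_residues_per_chain = n, n_frames = 2000,
  community_blocks = list(list(nodes = 1:n, rho = 0.3),
                          list(nodes = (n + 1):(2 * n), rho = 0.3)),
  background_correlation = 0.08,
  planted_path = list(nodes = c(seq(1, 7, 2), seq(7, 13, 2) + n), rho = 0.9),
  seed = 401)
g  <- residue_network(gen_trajectory(cfg), trim_termini = 0)
ps <- suboptimal_paths(g, "A:1", "B:13", edge_slack = 6, max_paths = 500)
paste(ps$optimal$path, collapse = " -> ")
#> [1] "A:1 -> A:3 -> A:5 -> B:7 -> B:9 -> B:11 -> B:13"
```

The `analysis/` directory holds the narrative drivers
(`01_simulate_smfs.R` … `04_force_network.R`); each regenerates its
inputs from fixed seeds, prints what it found, and writes tables under
`results/`.

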