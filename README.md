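# queenwalk

Movement analysis of honeybee queens in confined two-comb observation
arenas.

A honeybee queen spends her life walking a nearly square (~33 x 33 cm)
comb surface. Camera tracking of a tagged queen yields *tracklets* —
dense 10 Hz position segments in cm, broken by occlusions — and the
question is what kind of walker she is: how fast she diffuses over the
comb, how quickly she covers it with her ~2.5 cm perceptive range, how
often she recrosses her own path, and whether a step-and-turn random
walk (von Mises turning angles, one of five step-length tail families:
exponential, squared exponential, Pareto, truncated Pareto,
exponentially truncated Pareto) can reproduce the observed movement
once the confinement of the comb is taken into account.

`queenwalk` implements that entire analysis as tidyverse-style R:

* tracklet I/O, constant-velocity Kalman (RTS) smoothing, splitting at
  gaps, and walking / resting / short-stop segmentation
  (`read_tracklets()`, `kalman_smooth()`, `split_tracklets()`,
  `segment_activity()`);
* eigenvalue-ratio changepoint detection and step/turn extraction with
  per-step feasible lengths to the arena boundary
  (`detect_changepoints()`, `steps_and_turns()`);
* ensemble spatial dynamics against walked distance — diffusivity
  `<X^2>(s)` fitted as `a s^b`, mean first passage `MFP(D) = a D^b`,
  areal coverage and self-crossings as `a s^b + c`, box-counting
  fractal dimension — with interdecile bands and theoretical bounds
  (`diffusivity_curve()`, `mfp_curve()`, `coverage_curve()`,
  `selfcross_curve()`, `fractal_dimension()`, `theoretical_bounds()`);
* occupancy heatmaps, circular orientation distributions, per-cell
  flow maps and a permutation-tested directional Moran's I
  (`occupancy_heatmap()`, `orientation_distribution()`, `flow_map()`,
  `morans_directional()`);
* confinement-aware maximum likelihood for turning angles (von Mises,
  `fit_vonmises()`) and step-length tails, where each step's density is
  renormalized to the feasible interval `[l_min, L]` so the walker
  cannot exit the comb (`fit_tail()`), KS-based tail-start selection
  (`scan_lmin()`), AIC / Akaike-weight comparison on common support
  (`compare_families()`, `select_best_family()`), bootstrap
  uncertainty, the sub-`l_min` body (`fit_body()`), inter-short-stop
  Pareto fitting and the daily short-stop uniformity test;
* confined walker simulation matched to empirical tracklet lengths,
  compared back to the empirical curves (`simulate_walk()`,
  `simulate_matched_ensemble()`, `compare_to_empirical()`);
* a ground-truth-labelled synthetic data generator emulating the whole
  observation process (`synthetic_config()`, `generate_synthetic()`,
  `recovery_report()`), and a one-call pipeline (`run_pipeline()`).

Fitted objects have broom-style `tidy()` / `glance()` methods and
result types have `autoplot()` methods.

## A worked example

Generate six synthetic hours of queen tracking (known ground truth),
run it through segmentation and model fitting:

```r
library(queenwalk)

cfg <- synthetic_config(n_days = 0.25, seed = 42)   # six hours at 10 Hz
syn <- generate_synthetic(cfg)
syn
#> <synthetic_dataset> 0.25 days, 166004 observed samples in 78 tracklets (77% visible)

seg <- segment_activity(kalman_smooth(syn$observed))
table(seg$state)
#>    resting short_stop    walking
#>      61698      44363      59943

steps <- steps_and_turns(detect_changepoints(seg))
fit_vonmises(steps$turn)
#> <vonmises_fit> rho = -0.0214 rad, kappa = 0.7460 (R = 0.3492, n = 1045)
```

The step-length tail is compared across families on common support:

```r
compare_families(steps)[, 1:6]
#> # A tibble: 5 x 6
#>   selected family               l_min   logL   AIC akaike_weight
#>   <lgl>    <chr>                <dbl>  <dbl> <dbl>         <dbl>
#> 1 TRUE     exponential           1.61  -94.6  191.       0.556
#> 2 FALSE    squared_exponential   1.61  -95.5  193.       0.236
#> 3 FALSE    exp_truncated_pareto  1.61  -94.6  193.       0.205
#> 4 FALSE    truncated_pareto      1.61 -101.   203.       0.00135
#> 5 FALSE    pareto                1.61 -101.   203.       0.00135
```

The turning concentration (0.746 against a generating 0.7) and the
winning exponential tail both recover the generator: a queen-like
anisotropic correlated walk with a thin-tailed step distribution. Two
competitors sit within two AIC units — an exponentially truncated
Pareto degenerates to the exponential as its power-law exponent
vanishes — and the selection breaks such ties by parsimony. Ensemble
metrics and the matched-simulation comparison run the same way on real
or synthetic tracklets; `run_pipeline()` chains the whole analysis
with one seed.

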