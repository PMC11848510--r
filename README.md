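# adcr

Spatial capture–recapture (SCR) with mechanistic home ranges: **adcr**
implements the advection–diffusion capture–recapture model (ADCR), which
estimates animal population density *and* landscape permeability from
capture–recapture data collected by count detectors (e.g. camera traps with
individual identification).

## Who this is for, and what it does

Classical SCR assumes a bivariate-normal home range, which cannot express
movement barriers or corridors. ADCR instead derives the home range from an
animal-movement model: an individual drifts toward its activity centre
$\mu$ with intensity $c = e^{\alpha_0}$ and random-walks with a spatially
varying permeability (diffusion coefficient)

$$\ln D(x,y) = \beta_0 + \boldsymbol{\beta}\cdot \mathbf z(x,y),$$

log-linear in raster landscape covariates $\mathbf z$. The utilization
distribution $p^*(s\mid\mu)$ is the equilibrium of the corresponding
advection–diffusion equation with reflecting boundaries, detections at
detector $j$ are Poisson with intensity
$\lambda_j = e^{g_0} p^*(s_j\mid\mu)$ per time step, and activity centres
follow a homogeneous Poisson process with log density $\rho$. Maximizing
the full likelihood (activity centres integrated over the raster,
never-detected individuals accounted for) yields
$(\hat\rho, \hat g_0, \hat\gamma_0, \hat{\boldsymbol\beta})$ with standard
errors, where $\gamma_0 = \beta_0 - \alpha_0$ sets home-range size
($e^{\gamma_0}$ is the Gaussian-limit variance) and $\boldsymbol\beta$
measures how the landscape shapes connectivity — positive for corridors,
negative for barriers.

The package also provides, under the same likelihood machinery:

* the two standard comparison estimators — basic SCR (Gaussian detection
  function) and SCR with least-cost-path distance (`fit_scr()`);
* the study's data generator: patch landscapes
  (`generate_patch_landscape()`) and an individual-based movement/detection
  simulator (`simulate_dataset()`) producing temporally autocorrelated
  tracks, not i.i.d. draws;
* home-range metrics (`overlap_coefficient()`, `hda90()`,
  `mean_overlap_over_array()`) and accuracy summaries
  (`accuracy_summary()`);
* a simulation-study harness (`experiment_config()`, `run_experiment()`,
  `summarize_report()`) with per-iteration seeding and JSON checkpointing;
* ESRI ASCII raster and secr-style trap/capture text I/O, JSON fit files,
  and a thin command-line interface (`inst/cli/adcr`).

## Worked example

Simulate one dataset from the movement model on a patchy landscape, then
fit ADCR:

```r
library(adcr)

land <- generate_patch_landscape(20, 20, n_patches = 3,
                                 area_range = c(16, 40), seed = 1)
scn <- sim_scenario(rho = -2, alpha0 = -0.5, beta0 = 1, beta = 1.5,
                    g0 = -3, n_steps = 1000, burn_in = 100, land = land,
                    detectors = baseline_detectors(land, spacing = 3,
                                                   margin = 4))
sim <- simulate_dataset(scn, seed = 2)
sim$data
#> <adcr_capture_data> 41 individuals, 25 detectors, 1 occasion(s), 159 detections

fit <- fit_adcr(sim$data, land)
fit
#> <adcr_fit> model = adcr, logLik = -330.1907, converged
#>    term estimate std.error conf.low conf.high
#>     rho   -2.151   0.15774  -2.4606    -1.842
#>      g0   -2.883   0.09708  -3.0728    -2.692
#>  gamma0    1.621   0.11357   1.3985     1.844
#>    beta    1.290   0.20008   0.8982     1.683
```

The true values were $\rho = -2$, $g_0 = -3$, $\gamma_0 = 1.5$,
$\beta = 1.5$: each estimate lands within its 95% interval of the truth.
`exp(rho)` is density per cell area (here 0.116 individuals per unit
square, i.e. ≈46 over the 400-cell region against a realized population of
47); positive `beta` says the patch covariate increases permeability, so
home ranges skew into patches. Downstream helpers consume the fit directly:

```r
tidy(fit)                                   # broom-style coefficients
mean_overlap_over_array(homerange_params(1.5, 1.5), fit, land)
#> [1] 0.9333303                             # fitted vs true home ranges
hda90(predict_homerange(fit, mu = c(10.5, 10.5)))
#> [1] 40                                    # 90% highest-density area, cells
autoplot(predict_homerange(fit, mu = c(10.5, 10.5)))
```

Comparison fits are one call away
(`fit_scr(sim$data, land, mode = "lcp")`), and
`run_experiment(experiment_config(preset = "desk"))` reruns the whole
simulation-study loop (the `"paper"` preset is the full 100-iteration,
50 × 50 design — an overnight run).

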