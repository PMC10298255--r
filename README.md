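# capsuledry

Drying kinetics of thin polysaccharide gel films — the shells of
HPMC-based hard capsules — with a moisture- and temperature-dependent
effective diffusivity.

Hot-air drying of dip-molded capsule shells happens in the falling-rate
period: internal moisture diffusion limits the rate, and getting the
conditions wrong produces cracked, blistered, layered shells. The standard
description is Fick's second law for the dry-basis moisture content
`M(x, t)` across the ~0.2 mm film,

    ∂M/∂t = ∂/∂x ( D_eff(M, T) ∂M/∂x ),   0 < x < L,

with the inner face sealed against the preparation pin (zero flux), the
air-side face pinned at the equilibrium moisture `M_e`, and an effective
diffusivity that is anything but constant in a hydrogel:

    D_eff(M, T) = D0 · exp( −Ea/(R·T) + a·M − b·M² ).

`capsuledry` provides, as plain R functions over small S3 objects:

* an explicit finite-difference solver for this PDE on the layered shell
  grid (`shell_grid`, `simulate_drying`, `step_variable`), with
  stability-bounded adaptive time stepping, the drying literature's coefficient-6
  inner-node scheme and a textbook ghost-node variant, planar/cylindrical/spherical
  geometry options, and an independent analytic-series oracle
  (`analytic_slab_ratio`);
* least-squares estimation of `(D0, Ea, a, b)` from drying curves by
  Latin-hypercube multi-start bounded optimization (`fit_variable`), the
  per-condition constant-diffusivity benchmark (`fit_constant`), and
  goodness-of-fit comparison via `R²`/`RMSE` (`r_squared`, `rmse`,
  `compare_models`);
* proton-density (spin-echo) image quantification of moisture the way
  LF-MRI drying studies do (`signal_intensity`, `moisture_percentage`,
  `layer_profile`), operating on synthetic annular phantoms;
* a seeded synthetic-data generator reproducing the structure of the
  emulated study — initial moisture 8.44 g/g, five drying conditions
  (35/40/45 °C at RH 60 %, RH 40/50/60 % at 35 °C), 20-min sampling over
  140 min, multiplicative noise under 10 % (`generator_config`,
  `generate_drying_experiment`, `generate_mri_series`);
* an end-to-end pipeline with hashed, byte-reproducible outputs
  (`run_drying_analysis`) and numbered analysis drivers under `analysis/`.

The methods vignette (`vignettes/capsule-drying-model.Rmd`) documents the
model, the numerical scheme and every design decision, including the
deliberate internal-consistency choice for the synthetic diffusivity
scale.

## Worked example

Simulate the slowest study condition under the default generating law,
then fit both models to the full five-condition synthetic experiment:

```r
library(capsuledry)

params <- default_true_params()        # D0 = 1.2e-7, Ea = 2.5e4, a = 0.04, b = 0.025
cond   <- default_conditions()[[3]]    # 35 degC, RH 60 %, Me = 0.10 g/g
grid   <- shell_grid(L = 2e-4, Z = 4)

hist <- simulate_drying(8.44, params, cond, grid,
                        t_end = 140 * 60, output_times = seq(0, 140, 20) * 60,
                        stop_tol = 0)
round(hist$M_avg, 3)
#> [1] 7.398 4.675 2.842 1.620 0.922 0.543 0.339 0.229
```

The film dries from 8.44 g/g (the `t = 0` average reflects the instantly
equilibrated surface node) to a residual 0.23 g/g in 140 minutes. Fitting
both models to the noisy five-condition experiment (`analysis/02_fit_models.R`
prints exactly this):

```
Goodness of fit:
 condition R2_variable R2_constant RMSE_variable RMSE_constant
  35C_RH40   0.9998744   0.9930835    0.03018036     0.2239972
  35C_RH50   0.9970034   0.9831919    0.15048272     0.3563374
  35C_RH60   0.9983442   0.9972670    0.10801739     0.1387757
  40C_RH60   0.9989253   0.9968275    0.08846441     0.1520034
  45C_RH60   0.9995677   0.9916955    0.05717842     0.2506177

Max relative prediction error at t >= 30 min: 13.9% (variable) vs 61.0% (constant)
```

The variable-diffusivity model tracks every condition within ~14 % after
the warm-up period while the constant benchmark drifts badly at late
times — the variability of `D_eff` is what makes the forecast accurate.
The per-condition constant fits themselves (5.2–7.2 × 10⁻¹² m²/s,
increasing with temperature) show the Arrhenius trend the law encodes.

Quantifying the matching image phantom (`analysis/04_mri_quantification.R`):

```
 time_min moisture_pct
        0       100.00
       20        55.71
       40        33.27
       60        17.95
       80         9.01
      100         4.07
      120         1.41
      140         0.00
```

100 % at the initial frame and 0 % at the equilibrium frame are exact by
construction of the normalization; intermediate values track the
area-weighted shell moisture to within the 1 % background noise.

## The analysis workflow

The numbered drivers reproduce the study's analyses on synthetic data,
each writing tables under `results/`:

```sh
Rscript analysis/01_simulate_experiment.R   # five-condition experiment + truth
Rscript analysis/02_fit_models.R            # variable vs constant fits, comparison
Rscript analysis/03_layer_profiles.R        # per-layer moisture and D_eff tables
Rscript analysis/04_mri_quantification.R    # phantom rendering + quantification
```

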