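# soctau

Turnover times of soil mineral-associated (MAOC) and particulate organic
carbon (POC) from depth profiles, by Bayesian data–model integration.

Soil organic carbon persistence is governed largely by mineral protection,
so the slow MAOC fraction (<53 µm, mineral-bound) and the fast POC
fraction respond very differently to warming. Given observed MAOC/POC
pool sizes over five soil layers (0–100 cm) and the NPP input allocated
to each layer, `soctau` infers how fast each fraction cycles — per layer
and for the whole profile — for researchers working on soil carbon
models, digital soil mapping, and model benchmarking.

## The model

Each layer *i* carries a linear two-pool balance:

    dPOC_i/dt  = I_i + MAOC_i·KM_i·T_MAOCtoPOC − POC_i·KP_i + POC_{i+1}·D − POC_i·A
    dMAOC_i/dt = POC_i·KP_i·T_POCtoMAOC − MAOC_i·KM_i + MAOC_{i+1}·D − MAOC_i·A

with depth-attenuated decomposition rates

    KM_i = KM1·exp(−(z_i − 10)/zM),   KP_i = KP1·exp(−(z_i − 10)/zP)

(z_i = layer midpoint in cm; zM, zP = e-folding depths). Assuming soils
near steady state, the pools solve a 10-unknown linear system directly —
no iterative spin-up. The eight parameters per grid cell (KM1, KP1, zM,
zP, two transfer fractions, D, A) are sampled by Metropolis–Hastings
under a uniform prior box with a Gaussian misfit likelihood; layer
turnover is τ = 1/K and the 0–100 cm turnover is the pool-weighted mean
of layer turnovers. A synthetic-data generator (steady-state profiles +
Gaussian noise + spatially structured covariates), random-forest mapping
support statistics (dual importance normalization, wrapper selection,
10-fold CV, bootstrap uncertainty, Moran's I, semivariograms, stock
aggregation) and an end-to-end pipeline round out the package. See
`vignettes/soc-turnover-methods.Rmd` for the full account.

## Worked example

Forward model, then inversion of a noiseless profile:

```r
library(soctau)
g  <- soil_profile_grid()                       # 0-20 ... 80-100 cm
p  <- model_parameters(KM1 = 0.01, KP1 = 0.2, zM = 60, zP = 100,
                       T_MAOCtoPOC = 0.1, T_POCtoMAOC = 0.3,
                       D = 0.002, A = 0.002)
I  <- allocate_npp_by_depth(600, g)             # 600 g C m-2 yr-1 NPP
st <- steady_state(p, I, g)
st
#>   layer       POC      MAOC
#> 1     1 989.31531 5376.9131
#> 2     2 432.16960 2582.0191
#> 3     3 188.65852 1217.5904
#> 4     4  82.24630  549.4015
#> 5     5  35.39557  205.8372

obs <- observation_profile("demo", st$MAOC, st$POC, I, g)
fit <- metropolis_hastings(obs, cfg = mcmc_config(20000, seed = 42))
turnover_times(fit)$profile
#>   pool median    q05    q95
#> 1 MAOC 23.611 13.822 87.353
#> 2  POC  3.053  1.889  4.746
```

Pools are g C m⁻² per layer: under these parameters the column stores
most carbon as MAOC near the surface, decaying with depth. The turnover
table gives the posterior median and 5%/95% quantiles of the 0–100 cm
pool-weighted turnover in years. For this profile the parameters that
generated the data imply profile turnovers of 137 yr (MAOC) and 5.9 yr
(POC); the posterior concentrates on faster-cycling parameter
combinations that fit the same profile — many parameter sets reproduce
one noiseless profile (equifinality), and the fixed-step sampler explores
that ridge only locally. The methods vignette quantifies this and the
package's recovery experiments measure it explicitly.

The whole pipeline in one call:

```r
cfg <- run_config("run1", stages = c("synth", "invert", "report"),
                  n_cells = 5, base_seed = 1)
run_pipeline(cfg)
cat(summarize_run("run1")$text, sep = "\n")
```

A thin command-line front end with `synth`, `invert`, `map`, `report`,
`all` subcommands lives at `inst/cli/soctau.R`.

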