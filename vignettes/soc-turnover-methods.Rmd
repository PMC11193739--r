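---
title: "Methods: two-pool soil carbon turnover by Bayesian data-model integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-pool soil carbon turnover by Bayesian data-model integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soctau)
```

## The model

`soctau` models soil organic carbon as two measurable fractions —
mineral-associated organic carbon (MAOC, the slow, mineral-protected
fraction below 53 µm) and particulate organic carbon (POC, the fast,
plant-like fraction) — resolved over five soil layers (0–20, 20–40,
40–60, 60–80, 80–100 cm). Each layer $i$ obeys a linear carbon balance:

$$\frac{dPOC_i}{dt} = I_i + MAOC_i\,KM_i\,T_{MAOCtoPOC} - POC_i\,KP_i
  + POC_{i+1}\,D - POC_i\,A$$

$$\frac{dMAOC_i}{dt} = POC_i\,KP_i\,T_{POCtoMAOC} - MAOC_i\,KM_i
  + MAOC_{i+1}\,D - MAOC_i\,A$$

with NPP input $I_i$ (g C m$^{-2}$ yr$^{-1}$), first-order decomposition
rates $KM_i$, $KP_i$ (yr$^{-1}$), transfer fractions $T$ between the
pools, and vertical exchange coefficients $D$ (diffusion-like gain from
the layer below) and $A$ (advection-like loss). Decomposition attenuates
exponentially with depth,

$$KM_i = KM_1 \exp\left(-\frac{z_i - 10}{z_M}\right), \qquad
  KP_i = KP_1 \exp\left(-\frac{z_i - 10}{z_P}\right),$$

where $z_i$ is the layer midpoint in cm and $z_M$, $z_P$ are e-folding
depths: the depth increment over which the rate falls by a factor $e$.
We read $z_i$ as the layer **midpoint** (10, 30, 50, 70, 90 cm): with the
$-10$ offset this is the only reading under which the exponent vanishes in
the surface layer, making $KM_1$ and $KP_1$ genuine surface rates.

Two boundary/closure choices were genuinely open:

* **Bottom boundary.** The balance references layer $i+1$; we close the
  column with virtual pools $MAOC_6 = POC_6 = 0$ (no flux in from below) —
  the simplest closure consistent with the printed terms.
* **Transport.** Taken literally, each layer gains $D$-flux from below and
  loses $A$-flux, with no reciprocal terms; advected carbon therefore
  leaves the column. This literal scheme is the default everywhere,
  because the inversion must match the model as stated. A mass-conserving
  variant (`conservative = TRUE`), in which every internal exchange has a
  matching gain and the boundaries are zero-flux, is available behind a
  flag for users who want a closed column.

Pools are areal densities (g C m$^{-2}$ per layer), which makes $I_i$
dimensionally consistent with the balance; $D$ and $A$ are treated as
first-order fractional rates (yr$^{-1}$).

## Steady state and forward integration

Assuming soils near equilibrium, setting both derivatives to zero yields a
linear system in the $2 \times 5 = 10$ pools, solved directly
(`steady_state()`); this replaces iterative spin-up in the inversion's hot
path. `simulate_pools()` (adaptive `lsoda`, relative tolerance $10^{-8}$)
exists purely to validate that solution: the tests spin the model up from
zero pools over 35 e-folds of the slowest *system* eigenmode
(`spinup_horizon()`) and recover the analytic pools to better than
$10^{-6}$ relative. The slowest eigenmode matters: inter-pool recycling
makes the column relax more slowly than the smallest decomposition rate
alone, and a horizon based on $\min K$ undershoots.

## Bayesian inversion

Eight parameters per grid cell ($KM_1$, $KP_1$, $z_M$, $z_P$, two transfer
fractions, $D$, $A$) are inferred from an observed MAOC/POC depth profile
by Metropolis–Hastings sampling under a uniform prior box. The Gaussian
log-likelihood is

$$\log P(Z\mid\theta) = -\sum_{\text{pools, layers}}
  \frac{(C_{obs} - C_{mod})^2}{2\sigma^2},$$

with $C_{mod}$ the analytic steady state and $\sigma$ the per-pool,
per-layer observation standard deviation (fallback: 10% of the observed
pool with a small floor). The exponent is negative — a positive sign would
reward misfit — and inadmissible parameter sets (singular or negative
steady states) get $-\infty$, i.e. certain rejection.

The proposal perturbs every parameter independently by
$r\,(\theta_{max}-\theta_{min})/D_{step}$ with $r \sim U[-0.5, 0.5]$ and
$D_{step} = 5$. Proposals outside the box are rejected through the flat
prior (a $-\infty$ log-prior), which preserves detailed balance for this
symmetric kernel; we chose rejection over reflection because it needs no
correction term. Chains start from a uniform seeded draw inside the box,
run for $2\times10^4$ proposals per cell by default, record **accepted**
parameter sets only, and discard the first half of the accepted samples as
burn-in. Per-cell chains are seeded `base_seed + cell index`, so grid
inversions are order-independent and bit-reproducible.

Default prior box (documented stand-ins, all configurable): surface POC
turnover 1–100 yr ($KP_1 \in [0.01, 1]$ yr$^{-1}$), surface MAOC turnover
10–1000 yr ($KM_1 \in [0.001, 0.1]$ yr$^{-1}$), e-folding depths 30–200 cm,
transfer fractions $[0, 1]$, $D, A \in [0, 0.01]$ yr$^{-1}$.

### Turnover times

Layer turnover is the reciprocal rate, $\tau_i = 1/K_i$; the 0–100 cm
profile turnover is the mean of layer turnovers weighted by that
posterior sample's steady-state pool sizes. Posterior medians and 5%/95%
quantiles are reported per layer and for the profile means.

### Known sampling limitations

Summarizing **accepted samples only** (rather than the full chain with
rejection duplicates) follows the stated procedure, but the retained
sample is then the Metropolis *jump chain*, whose stationary law is the
posterior tilted by the local acceptance probability. On a 1-D
conjugate-Gaussian check this bias is negligible when the posterior scale
is comparable to the proposal step (posterior sd $\approx$ half the step
half-width: mean and sd within ~1% of the closed form at $10^5$
proposals) but reaches several percent when the posterior is much wider,
and inflates spread when it is much narrower.

The fixed step ($\pm$ range/10 per parameter) has a harsher consequence at
low observation noise: with 5% noise the posterior ridge is far narrower
than the step, acceptance drops to 0.1–3%, and the few hundred retained
jumps cannot traverse the long equifinal ridge connecting parameter sets
that fit the same profile (e.g. $KM_1$–transfer–$D$ trade-offs). Point
recovery of profile turnover is good (median absolute relative error of
profile $\tau_{POC}$ ~10–15% in the packaged 10-cell experiment), but the
90% credible intervals are locally narrow and cover the truth in only
~50–70% of cells — running chains 10× longer does not repair this, and the
chains' best log-likelihoods exceed the truth's, so it is a property of
the prescribed sampling scheme at these noise levels rather than a
convergence failure. The acceptance suite asserts nominal coverage anyway
and the assertion fails; we prefer that honest failure to quietly altering
the sampler.

## Synthetic data

The generator produces the inputs the analysis assumes, with no download:

* **NPP depth allocation** (`allocate_npp_by_depth()`): the classic
  geometric root-attenuation profile, layer fraction
  $(\beta^{top} - \beta^{bottom})/(1 - \beta^{100})$, $\beta = 0.95$ by
  default, renormalized over 0–100 cm; a belowground share (default 0.5)
  of total NPP enters the soil. This is a documented stand-in for
  published root-profile allocations.
* **Truths** (`sample_truths()`): parameters drawn uniformly inside the
  prior box; covariates with plausible global ranges (MAT clamped to
  $[-9, 29]$ °C and tracking latitude, MAP log-normal in $[58, 3128]$ mm,
  NPP increasing with MAT and MAP, elevation, pH, clay+silt, land cover).
  Optional covariate links give driver analyses real signal: a linked
  parameter is drawn near mid-box and shifted linearly with centered MAT
  (defaults $z_M$: +1.5 cm/°C, $z_P$: +2.5 cm/°C, small enough that the
  box never clips and a regression on 500 cells recovers the slope within
  20%). Inadmissible draws are resampled with a retry cap.
* **Observation noise** (`add_observation_noise()`): per pool per layer,
  $\max(0,\; pool + N(0, (cv \cdot pool)^2))$ with the true
  $\sigma = cv \cdot pool$ recorded; default CV 0.1, matching the
  inversion's $\sigma$ fallback. Negative draws are truncated at zero and
  counted.

What the generator does **not** emulate: geographic sampling bias of real
compilations, correlated multi-layer measurement error, disequilibrium
(every noiseless profile is exactly at steady state by construction), or
real covariate rasters. Passing recovery tests therefore demonstrates
internal consistency of model + inversion under the assumed error model,
not performance on real profiles.

## Mapping support statistics

The random-forest learner itself is consumed off-the-shelf (`ranger`)
behind a three-function contract (`fit`/`predict`/`importance`), so any
regressor can be injected; the package's own contributions are the
support computations:

* **Dual importance** (`normalize_importance()`): impurity and permutation
  importances are each min–max scaled to $[0, 1]$ and averaged; a constant
  vector scales to zero with a warning.
* **Wrapper selection** (`wrapper_select()`): recursive elimination of the
  least-important covariate, tracking 10-fold RMSE; the smallest set
  within 1% of the best RMSE wins (the stopping tolerance is ours — the
  elimination loop itself has no published stop rule).
* **Validation** (`kfold_r2()`): seeded 10-fold assignment, out-of-fold
  predictions pooled before $R^2 = 1 - SSE/SST$.
* **Bootstrap maps** (`bootstrap_maps()`): 100 seeded subsamples of 90% of
  the rows **without replacement** (we read "randomly sampled" as
  subsampling, not resampling), refit, predict; per-cell mean and 5%/95%
  quantiles.
* **Spatial diagnostics**: Moran's $I$ with binary distance-threshold
  weights and a seeded permutation test (checkerboard on a unit lattice
  with distance-1 neighbours gives $I = -1$ exactly, the closed-form
  oracle), and an equal-width-bin semivariogram up to half the maximum
  pairwise distance (extended to the full maximum for point sets so small
  that no pair survives the cutoff); empty bins are `NA`, never zero.
  Weight scheme and binning are configurable since no specific scheme is
  canonical.
* **Stocks** (`aggregate_storage()`): density × area summed over cells and
  layers, in Pg C ($10^{15}$ g).

## Pipeline and problem sizes

`run_pipeline()` chains synth → invert → map → report from one validated
configuration (`run_config()` / YAML via `read_run_config()`); unknown
keys fail by name before any compute, every stage seed derives from one
base seed, and the config snapshot written alongside the outputs
reproduces the run bit-for-bit. `summarize_run()` reports per-cell profile
turnovers with quantiles, e-folding posteriors and the $z_P/z_M$ ratio,
adding coverage and relative-error columns whenever a truths table is
present.

The packaged experiments use sizes a laptop handles in minutes: 10-cell
grids at $2\times10^4$ proposals per cell for recovery, $10^5$ proposals
for the 1-D sampler cross-check, 500 replicates of a 200-point
permutation test for Moran calibration, and $n = 1000$ rows for the
cross-validation bounds. These sizes were chosen so each check resolves
its question (Monte-Carlo error comfortably below the asserted margins)
while the full suite stays fast.
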