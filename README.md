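# demosync

Spatial synchrony in the breeding demographic structure of wild
populations: do spatially separate populations get "younger" and "older"
together, and over what distances?

`demosync` is built for multi-site, individual-based monitoring schemes
(the motivating system is European nest-box studies of the great tit,
*Parus major*). It turns individual capture records into annual
demographic-structure descriptors — chiefly the proportion of breeders
that are subadult (first-year) — then quantifies how strongly those
descriptors fluctuate in step across populations as a function of the
distance between them, and asks which reproductive and environmental
variables covary with, and potentially synchronise, those fluctuations.

## The model

Normalised descriptor values of the populations observed in year *t* are
modelled as multivariate normal, **y**ₜ ~ MVN(**0**, Σₜ), independent
across years, with unit variances and cross-population correlations
following a Gaussian distance-decay correlogram

ρ(d) = ρ∞ + (ρ₀ − ρ∞) · exp(−d² / 2l²)

with 0 ≤ ρ∞ ≤ ρ₀ < 1 and l > 0: ρ₀ is synchrony at vanishing distance,
ρ∞ the large-distance floor, and l (km) the characteristic spatial scale
of synchrony. Parameters are estimated by maximising the summed annual
log-likelihoods (populations with longer overlapping series thereby weigh
more), and uncertainty comes from a parametric bootstrap that re-simulates
the panel from the fitted model — preserving exactly which populations
were observed each year — and refits. Covariate effects on the descriptor
are estimated with per-covariate random-intercept + random-slope mixed
models; covariate effects on *synchrony* are assessed by refitting the
correlogram to per-population residuals after regressing the descriptor
on the covariate.

## Worked example

Simulate a study with known truth (ρ₀, ρ∞, l) = (0.35, 0, 650 km) — 32
populations over 1956–2022 with staggered observation windows — then run
the full chain from individual records back to a fitted synchrony curve:

```r
library(demosync)
cfg      <- simulation_config(seed = 7)
study    <- simulate_study(cfg)
summaries <- summarise_structure(study$records)   # ages, filters, descriptors
panel    <- build_panel(summaries)                # per-population normalisation
geometry <- haversine_matrix(study$sites)
fit      <- fit_synchrony(panel, geometry, seed = 7)
fit
#> synchrony_fit: rho0 = 0.353, rho_inf = 0.024, l = 498 km (logLik -1253.4)
#>   32 populations, 65 years used
boot <- synchrony_bootstrap(fit, B = 200, seed = 8)
boot
#> synchrony_boot: 200 replicates (0 dropped)
#>   rho0     median   0.361  [  0.253,   0.508]
#>   rho_inf  median   0.018  [  0.000,   0.086]
#>   l        median 491.972  [338.231, 721.872]
#>   rho100   median   0.354  [  0.247,   0.490]
#>   rho500   median   0.218  [  0.149,   0.296]
#>   rho1000  median   0.072  [  0.016,   0.143]
#>   rho2500  median   0.019  [  0.000,   0.086]
```

The point estimate recovers the generating truth (ρ̂₀ = 0.353 vs 0.35;
l̂ = 498 km vs 650 km, inside the 95% interval), and the bootstrap medians
give the distance-specific synchrony a reader would report: populations
100 km apart correlate at ≈ 0.35, falling to ≈ 0.07 by 1000 km.
`synchrony_curve(boot)` returns the median curve with its 95% band on a
distance grid, and `pairwise_synchrony(panel, geometry)` the pairwise
correlation scatter with overlap-year weights for plotting.

Evaluating the correlogram directly, e.g. at published parameter values:

```r
synchrony_rho(100, synchrony_params(0.344, 0, 641))
#> [1] 0.3398392
```

For real data, `run_pipeline()` (or the thin CLI in `inst/cli/demosync.R`)
consumes CSVs of breeding records, clutches, daily climate, mast records
and site coordinates, and writes summaries, covariates, the per-covariate
mixed-model table, raw and covariate-adjusted synchrony fits, curve data
and a run manifest. `adjust_for_covariate()` exposes the residualisation
step on its own.

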