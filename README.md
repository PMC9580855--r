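# smlmkit

Headless analysis toolkit for single-molecule localization microscopy
(SMLM) point clouds and 3D single-particle-tracking data.

Modern 3D single-molecule experiments — multifocus-microscopy tracking of
nanoparticles in the cell nucleus, super-resolution reconstructions built
from blinking fluorophores — produce tables of localizations: 3D
coordinates plus time stamps, intensities and trajectory ids. smlmkit
provides the quantitative backend for working with such tables without any
graphical front end: reading them from arbitrary delimited text, selecting
subsets with geometric primitives, measuring, and estimating the physical
quantities biologists actually want from them — local density, diffusion
coefficients, anomalous exponents, and spatial maps of diffusivity and
force.

## What it computes

**Diffusion and drift from translocations.** Each observed displacement
Δrᵢ over Δtᵢ is modelled as Gaussian with mean vΔtᵢ and per-coordinate
variance 2(D + σ²/Δtᵢ)Δtᵢ, where σ is the static localization precision.
`mle_diffusion_drift()` maximizes the joint likelihood

    log L = Σᵢ [ −‖Δrᵢ − vΔtᵢ‖² / (4(D + σ²/Δtᵢ)Δtᵢ)
                 − (d/2) ln(4π(D + σ²/Δtᵢ)Δtᵢ) ]

in (D, v). For σ = 0 the maximum is closed-form (v̂ = ΣΔr/ΣΔt,
D̂ = Σ‖Δrᵢ − v̂Δtᵢ‖²/Δtᵢ / (2dn)); for σ > 0 the drift is profiled out and
D found by root-finding on the analytic profile-likelihood gradient. This
removes the well-known σ²/Δt inflation that localization error adds to
naive estimates.

**MSD analysis.** `msd()` computes the time-averaged mean squared
displacement MSD(nΔt) = ⟨‖r(t+nΔt) − r(t)‖²⟩; `fit_diffusion()` fits
MSD(τ) = 2dDτ + b over the first lags (b = 2dσ² absorbs the noise floor)
and `fit_alpha()` fits the anomalous exponent α from the log-log slope
(MSD ∝ τ^α; α < 1 sub-diffusive, α = 1 Brownian).

**3D diffusivity/force maps.** `partition_kmeans()` tessellates the
localizations into compact regions (k-means, assuming D and force are
locally constant), `infer_map()` runs the translocation MLE per region and
converts drift to force via F = v·kT/D, and `build_region_meshes()` /
`export_map()` turn each region into a closed convex-hull surface colored
by its D for PLY/OBJ export into any 3D viewer.

**Point-cloud operations.** `local_density()` (k-NN or fixed-radius, in
points/µm³), `merge_blinking()` (connected-component merging of
localizations produced by the same blinking molecule), selection shapes
(sphere, landmark convex hull, clipping plane, column threshold) with set
algebra, distance/angle measurement and segment bin-count profiles.

**Simulators for validation.** Overdamped-Langevin walks (homogeneous or
on a heterogeneous D/force landscape with ground-truth labels), exact
fractional Brownian motion, and blinking emitters — so every estimator is
tested against known truth. A camera-waypoint module
(`parse_waypoints()`, `interpolate_path()`) converts timed fly-through
scripts into renderer-ready pose sequences.

## Worked example

```r
library(smlmkit)

# 50 trajectories, D = 0.5 um^2/s at 30 ms frames, 30 nm localization noise
trajs <- simulate_brownian(n_trajectories = 50, n_steps = 200, dt = 0.03,
                           D = 0.5, sigma = 0.03, seed = 42)
tl <- translocations(trajs)
mle_diffusion_drift(tl$dr, tl$dt, sigma = 0.03)
#> <diffusion_mle> D = 0.5028 um^2/s, |v| = 0.0792 um/s (n = 10000, sigma = 0.03, ok)

curve <- msd_ensemble(trajs, max_lag = 10)
fit_diffusion(curve, n_fit = 4)
#> <diffusion_fit> D = 0.5059 um^2/s, b = 0.004381 um^2 (d = 3, 4 lags)
fit_alpha(curve)
#> <diffusion_fit> alpha = 0.9868, K = 0.502 (d = 3, 10 lags)

cloud <- trajectories_to_cloud(trajs, metadata = list(dt = 0.03))
part <- partition_kmeans(cloud, k = 20, seed = 1)
infer_map(cloud, trajs, part, sigma = 0.03)
#> <diffusion_map> 20 regions (20 estimated)
#>   D range: 0.4541 - 0.5358 um^2/s
```

The noise-aware MLE recovers D to 0.6%; the MSD fit's intercept
b ≈ 0.0044 µm² sits at the expected localization-noise floor (2dσ² =
0.0054 µm² in theory, reduced slightly by time averaging); and the
20-region map scatters tightly around the homogeneous truth — the
baseline against which real heterogeneity is read.

A command-line wrapper over the same functions is installed at
`system.file("cli/smlmkit", package = "smlmkit")`, with subcommands
`simulate`, `density`, `merge-blinks`, `msd`, `fit-d`, `fit-alpha`,
`map3d`, `profile`, `select` and `campath`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's end-to-end pipeline from
scratch: it simulates Brownian ensembles (with and without localization
noise) and a two-region diffusivity landscape, recomputes the pooled and
noise-corrected diffusion estimates, tessellates and infers the
two-region map, exports the colored region meshes, and writes the
result JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/smlmkit-methods.Rmd` documents the models and their
assumptions, the estimator details and numerical choices, what the
simulators do and do not emulate, and known limitations.
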