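---
title: "smlmkit: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{smlmkit: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmkit)
```

smlmkit is a headless toolkit for single-molecule localization microscopy
(SMLM) point clouds and 3D single-particle tracking. This vignette is the
package's own account of the science it implements: the data model, each
estimator and its assumptions, the numerical choices, what the synthetic
generators do and do not emulate, and the design decisions that were
genuinely open.

## Data model and units

A `point_cloud` is a table of N localizations: positions (micrometres by
default; a `scale` argument at read time converts nm tables), a time stamp
per point (seconds, or a frame index with the frame interval `dt` kept in
metadata), and arbitrary named numeric columns (intensity, trajectory id,
computed properties). Tables are read from any delimited text — tab,
comma, semicolon or whitespace are auto-detected — and the first row is
treated as a header if and only if any of its fields fails numeric
parsing. That rule needs no dialect flag and can never swallow a numeric
data row. Malformed rows fail fast with the offending line number; a
permissive `skip_malformed` flag exists because silently dropping data is
the wrong default. Rows with non-numeric (NaN-like) fields follow the same
fail-fast policy.

Trajectories are groups of localizations sharing an id, sorted by time;
duplicate (id, time) pairs are rejected because their ordering — and hence
the translocation set — would be ambiguous. All dynamics work on
translocations: displacement vectors Δr over intervals Δt > 0.

Analysis runs serialize to JSON records (tool name, fully resolved
parameters including seeds, outputs), which is what makes any run
reproducible from its record alone.

## Geometric selection and measurement

Four shapes select subsets: a sphere (closed ball), the convex hull of at
least four non-coplanar landmarks, a clipping half-space, and a value
threshold on a named column. All selections are *closed*: boundary points
are kept, which makes results deterministic under exact arithmetic and
matches the intuition that a landmark placed on a point captures it.
Whether a clipping plane keeps or hides exactly-on-plane points was an
open choice; keeping them is consistent with the other shapes.

No 3D convex-hull routine exists in the dependency set, so the hull is
built from first principles by incremental (quickhull-style) insertion:
seed tetrahedron from extreme points, then per point delete visible
facets and stitch new ones along the horizon. Membership tests use the
facet half-space equations with a tolerance of 1e-9 relative to the hull
scale on the inner side. The tests cross-check membership against an
independent tetrahedron-decomposition barycentric oracle and hull volumes
against Monte-Carlo integration.

Segment profiles project every point onto the axis through two endpoints,
keep projection parameters in [0, 1] (optionally within a cylinder
radius), and histogram them into equal bins, the last bin right-closed so
that the counts conserve the in-range total.

## Local density

`local_density()` reports points per µm³ either from the k-th-neighbour
distance, d = k / ((4/3)π r_k³), or by counting neighbours within a fixed
radius R. The point itself is excluded in both modes, which makes the
radius mode unbiased for a homogeneous process. Two documented biases
remain, deliberately uncorrected because the tool mirrors a simple
colouring aid rather than a calibrated density estimator:

* **Edge bias.** Near the cloud boundary part of the ball is empty, so
  densities are underestimated. No edge correction is applied.
* **Small-k bias.** For a uniform (Poisson-like) cloud the k-NN volume is
  Erlang-distributed, so E[k/V_k] = λ·k/(k−1): the k-NN estimator reads
  ~11% high at k = 10 even far from edges. The test suite checks interior
  means against this exact expectation, (N−1)·k/(k−1), not against the
  naive λ = N.

Duplicate points make r_k = 0 and the density infinite; the strict mode
turns that into an error.

## Blinking-localization merging

A blinking fluorophore yields several localizations of one molecule
spread over frames. The merge rule links two localizations when their
distance is at most `eps` *and* their time gap is positive and at most
`max_gap`; two localizations in the same frame are never linked, since a
single emitter produces at most one localization per frame. Merged
molecules are the *connected components* of the link graph: the gap
criterion applies between consecutive members, not first-to-last, so a
long-lived emitter with short dark gaps — or a slowly drifting blink
chain — still merges into one point. The merged position is the centroid
of the members (intensity-weighted on request). The published tools this
mirrors do not state their exact rule; distance-plus-gap transitive
closure is the ledgered default, and a stricter seed-point mode would be
a separate flag rather than a change to this one.

## MSD, apparent D and the anomalous exponent

`msd()` is the time-averaged, overlapping-pair MSD of one trajectory —
appropriate because the analyses target *selected* trajectories; an
ensemble variant pools pairs across a set. It requires a uniform frame
interval (relative tolerance 1e-6) because time averaging mixes lags
otherwise.

`fit_diffusion()` fits MSD(τ) = 2dDτ + b by ordinary least squares over
the first `n_fit = 4` lags — standard short-lag practice balancing bias
from confinement/anomaly against variance at long lags. The intercept
b = 2dσ² absorbs static localization error. A negative slope clamps to
D = 0 with a flag rather than silently.

`fit_alpha()` fits log MSD = α log τ + log(2dK) over a lag range (default
the first 10 lags): α = 1 is Brownian, α < 1 sub-diffusive. The
generalized coefficient K comes from the intercept.

## The translocation likelihood

The core estimator models each translocation as Gaussian under overdamped
Langevin dynamics with constant local D and drift v, plus *static*
localization noise σ entering as variance σ²/Δt per translocation and
coordinate:

log L = Σᵢ [ −‖Δrᵢ − vΔtᵢ‖² / (4(D + σ²/Δtᵢ)Δtᵢ) − (d/2) ln(4π(D + σ²/Δtᵢ)Δtᵢ) ]

With a flat prior on (D, v) the posterior mode equals this MLE, which is
what the regional mapping pipeline uses; a Jeffreys-type prior would
shift small-n estimates and is left as future work since the per-region
counts used here (≥ 20, typically thousands) make the prior negligible.

Numerics: for σ = 0 the maximizer is closed-form (v̂ = ΣΔr/ΣΔt,
D̂ = Σ‖Δrᵢ − v̂Δtᵢ‖²/Δtᵢ /(2dn)). For σ > 0, v is profiled out at fixed D
by the precision-weighted mean v̂(D) = Σ wᵢΔtᵢΔrᵢ / Σ wᵢΔtᵢ², wᵢ =
1/((D + σ²/Δtᵢ)Δtᵢ), and D̂ is the root of the analytic
profile-likelihood gradient (the envelope theorem makes the profiled
gradient exact), found by bisection-safe `uniroot` to ~1e-13. This is why
the numeric path agrees with the σ = 0 closed form to better than 1e-9,
a property the tests assert directly, and why a 2000-point grid search
can only confirm, not refine, the optimum. If the gradient is non-positive
at D = 0 the likelihood peaks on the boundary: D̂ = 0 is returned with a
`boundary` flag (`degenerate` when σ = 0 and all residuals vanish).

Two corrections are *not* applied, deliberately: motion blur (camera
integration during exposure deflates short-lag variance) and the
anti-correlation of consecutive translocations induced by shared
localization noise. Both are documented limitations; the second leaves
the estimator consistent but slightly understates its information
content.

## The 3D diffusivity/force map

The mapping pipeline assumes D and force are constant within small
regions. Regions come from k-means on the localization positions —
k-means++ style seeding, Lloyd iteration, best of `n_init` restarts,
empty clusters re-seeded at the farthest point, fully deterministic for a
fixed seed. `stats::kmeans` was not used because its Lloyd path can abort
on empty clusters and its seeding is not k-means++; it serves instead as
an independent cross-check in the tests. `points_per_region` converts a
target occupancy into k.

Each translocation is attributed to the region of its *starting* point
(the standard convention in diffusivity mapping); regions with fewer than
20 translocations are flagged `insufficient_data` and carry no estimate —
flags propagate, they never abort the map. Per region the translocation
MLE yields D and v, and the force is F = v·kT/D, reported in kT/µm with
kT defaulting to 1 so no temperature input is needed.

Region borders are rendered as the convex hull of each region's member
points rather than the Voronoi cell of its center: hulls are closed,
watertight, and built from the same code path as the selection tool.
Voronoi polytopes would tile space exactly but need clipped unbounded
cells; they are noted as a future option. Mesh colours map each region's
value through a min-max normalized colormap (viridis by default,
colour-blind safe); degenerate regions (fewer than four points, or
coplanar) are skipped with a warning. Export is PLY (ascii or
binary-little-endian, per-vertex RGBA) or OBJ (one group per region).

## Simulators: the stated world

The generators emulate the experimental regime the toolkit targets —
nanoparticles of tens of nm diffusing in a nucleus-like closed volume,
imaged volumetrically at 30 ms frames — and provide ground truth for
every estimator:

* **Langevin walks** use Euler–Maruyama stepping,
  Δr = vΔt + (D F/kT)Δt + √(2DΔt)·η, with reflecting box walls
  (a closed, nucleus-like volume, not periodic). Localization noise is
  added to the recorded positions afterwards, which is exactly the static
  σ²/Δt error the estimators correct. Default dt = 0.03 s and D of order
  0.1–1 µm²/s match that regime. A single-region landscape is
  sample-path identical to the homogeneous generator under the same seed
  because both share one stepping routine and RNG stream.
* **Heterogeneous landscapes** switch D and force by the region of the
  *current* position (Itô convention). A physical consequence, visible in
  the tests: particles accumulate on the slow side of a D interface, so
  the acceptance landscape is elongated (80 × 4 × 4 µm) to keep that
  interface layer a small volume fraction; with 800 trajectories the
  k-means bisector then sits close enough to the true interface that
  cross-contamination of step sets stays well inside the 15% recovery
  tolerance. Trajectory counts are chosen to give ≥ 2000 translocations
  per region.
* **fBm** is generated exactly per axis by Cholesky factorization of the
  increment covariance (Hurst H = α/2), capped at 5000 steps because the
  covariance is dense; one factor is reused across trajectories. Its
  lag-1 increment autocorrelation 2^(α−1) − 1 and ensemble MSD ∝ τ^α are
  the closed forms the tests check.
* **Blinking emitters** follow a per-frame on/off Markov chain with an
  absorbing bleached state; every on-frame emits one localization with
  isotropic Gaussian noise. The chain's occupancy recursion gives the
  expected localization count used as the test oracle.

All generators derive their stream from (seed, generator name) and
restore the caller's RNG state, so runs are reproducible and generators
are independent of each other and of user code.

What the simulators do **not** emulate: camera motion blur, anisotropic
(axially inflated) localization error, photophysics beyond the two-state
chain, tracking errors (mislinked trajectories), and CTRW/Lévy-type
anomalous models. A green recovery test therefore establishes estimator
correctness under the stated model, not robustness to those effects.

## Camera paths

Waypoint scripts are JSON (the original VR tool's grammar is unpublished;
this schema is a re-specification, not a reverse-engineering claim): a
`waypoints` array of {position, look_at, dwell_s, transit_s, visual}.
Timeline semantics: dwell at each waypoint, then transit to the next;
duration = Σ dwell + Σ transit. Frames sit at t = (j−1)/fps with the
final frame snapped to the exact duration — the only grid for which the
frame count is exactly round(duration·fps) *and* both endpoints coincide
with waypoints *and* a 1 s transit at 10 fps has a frame exactly at its
midpoint. Orientation is the look-at quaternion with world up +z (+y
fallback for axial views). Catmull-Rom interpolation uses *reflected*
endpoint phantoms (p₀ = 2p₁ − p₂): duplicated phantoms would bend the
first and last segments, breaking the requirement that collinear evenly
spaced waypoints reproduce linear motion exactly.

## Command line

`run_cli()` dispatches ten subcommands, each a thin shell over one module
function — the CLI layer contains no analysis logic, so module unit tests
cover everything it can do. Every run writes its resolved configuration
as an analysis record, sufficient to re-run it identically. A wrapper
script ships in `inst/cli/`.

## Known limitations

* Hull-based region borders overlap slightly for interlocking point sets;
  Voronoi cells would not.
* The density tool is a colouring aid: no edge or small-k correction.
* The MLE ignores motion blur and noise-induced step anti-correlation.
* The PLY/OBJ readers support the layouts this package writes, not the
  full format zoo.
* k-means regions are compact and convex-ish by construction; genuinely
  non-convex diffusivity domains will be split across regions.
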