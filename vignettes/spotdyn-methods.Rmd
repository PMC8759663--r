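---
title: "Models and methods behind spotdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spotdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotdyn)
```

spotdyn studies macroscopic bacterial aggregates ("spots"): millimetre-scale
clusters of immotile cells, surrounded by swimming cells, that form in soft
agar from an initially uniform chemotactic population, migrate over distances
of several diameters, and sometimes merge. The package has two halves that
meet in the middle: a 2D agent-based model that produces this phenomenology
from microscopic rules, and a quantification pipeline (segmentation,
tracking, spatial statistics, kinematics) that is applied identically to
simulated snapshots and to experimental tracking exports.

## The agent-based model

`n_agents` point agents live on a square periodic domain of `grid_size`
pixels. Each agent secretes a chemoattractant that diffuses and decays on a
pixel grid; motile agents perform Brownian motion with a chemotactic drift up
the local gradient. Writing $c(\mathbf{x},t)$ for the concentration field,
the field obeys

$$\partial_t c = D_c \nabla^2 c - k\,c + s \sum_i \delta(\mathbf{x} - \mathbf{x}_i),$$

and a motile agent moves as

$$d\mathbf{x} = \chi(c)\,\nabla c\,dt + \sqrt{2 D_a}\,d\mathbf{W}, \qquad
  \chi(c) = \frac{\chi_0}{(1 + c/c_{1/2})^2}.$$

The saturating prefactor is the receptor-law sensitivity: drift grows with
the gradient but weakens with the absolute concentration, as bacterial
surface receptors saturate. The exact closed form of the receptor law is a
package choice (the classical $(1+c/c_{1/2})^{-2}$ form); any form that is
monotone in $|\nabla c|$ and decreasing in $c$ produces the same qualitative
behavior, and the choice is isolated in `chemotactic_drift()`.

This is a Keller–Segel-type aggregation mechanism: above a density threshold
set by the balance of chemotactic flux against agent diffusion, uniform
populations are unstable and collapse into spots whose spacing is governed by
the chemoattractant screening length $\sqrt{D_c/k}$.

### The transient motility switch

On top of chemotaxis, agents carry a four-state motility cycle

`MOTILE -> IMMOTILE_FIXED -> IMMOTILE_STOCHASTIC -> BLIND -> MOTILE`:

* a motile agent whose local concentration reaches the threshold `c_star`
  becomes immotile (concentration is proportional to local cell density
  inside spots, so this is a density-dependent transition);
* it stays immotile for the fixed refractory time `t_refractory`, then
  regains motility with constant probability `p_reactivate` per step
  (a geometric wait with mean `dt / p_reactivate`);
* on reactivation it ignores the gradient for `t_blind` time units,
  performing pure Brownian motion, which lets it actually leave the high
  concentration region instead of being immediately recaptured.

The three timescales are calibrated against wall-clock values of 3 min
(fixed immotile), 30 min (expected stochastic wait; together 33 min to
regain motility) and 15 min (gradient-blind walk). Internally the defaults
are 0.6, 6 and 3 time units — the same 3:30:15 ratio — and the mapping of
time units to hours is set a posteriori with `calibrate_scales()` (below).
The blind interval is half the immotile expectation so that a substantial
fraction of the population is motile at any time; with the shipped control
parameters the long-run motile fraction settles in the 0.4–0.5 band while
spots persist.

Without the reactivation rule virtually every agent ends up absorbed in a
spot; without the blind interval reactivated agents are recaptured at once
and spots are effectively frozen. The switch is what makes spots dynamic:
a spot whose chemoattractant falls below `c_star` collectively remobilizes
and its cells stream toward a neighbor, which is the microscopic mechanism
of merging in the model.

### Numerics

* **Field**: explicit FTCS step — 5-point-stencil diffusion with periodic
  wrap, multiplicative decay $(1 - k\,\Delta t)$, then deposition of
  $s\,\Delta t$ into each agent's containing pixel. Periodic diffusion
  conserves mass exactly, so the per-step mass balance
  $\sum c' = (1-k \Delta t)\sum c + n\,s\,\Delta t$ is a hard invariant
  (tested to $10^{-12}$). The stability condition $D_c \Delta t \le 0.25$
  (pixel spacing 1) is enforced at construction, not discovered as blow-up.
* **Agents**: Euler–Maruyama with the same $\Delta t$. Concentration and
  gradient are sampled off-lattice by bilinear interpolation (gradient by
  central differences on the grid, then interpolation).
* **Finite size**: after the stochastic move, pairs closer than `r_agent`
  are pushed apart along their axis by half the overlap each (a soft,
  single-pass repulsion). Immotile agents are anchored — only the
  motile/blind member of a pair is displaced — because "immotile agents do
  not move" is a state contract of the model; the alternative occupancy-cap
  formulation would be rule-equivalent at these densities. Coincident pairs
  are separated along a fixed axis so runs stay deterministic.
* **RNG**: one seeded generator per run; all draws happen in fixed agent
  order, so identical `(params, seed)` give bit-identical runs — tested.
* **Step order**: field update, state update (using the updated field at
  current positions), position update.

### Control parameters and scale calibration

The reference conditions fix `n_agents = 100000`,
`grid_size = 384`, `dt = 0.005`, `t_final = 2000`, plus the three switch
timescales. The remaining constants (diffusivities, secretion, decay,
sensitivity, thresholds) are not printed; the shipped defaults were chosen
once — to recover spot formation with
experiment-like relative spot size and spacing — and are all exposed in
`sim_params()` and the config file:

| parameter | default | role |
|---|---|---|
| `D_agent` | 1 px²/t | agent diffusion |
| `D_chem` | 10 px²/t | chemoattractant diffusion (CFL: $10 \cdot 0.005 \le 0.25$) |
| `secretion_rate` | 1 /agent/t | source strength |
| `decay_rate` | 0.05 /t | screening length $\sqrt{D_c/k} = 14$ px |
| `chi0` | 25 | chemotactic sensitivity |
| `c_half` | 15 | receptor saturation (uniform steady state is $\rho s / k \approx 12$ at control density) |
| `c_star` | 30 | immobilization threshold (≈ 2.5× the uniform background) |
| `r_agent` | 0.25 px | finite-size radius |

Physical units are attached afterwards: `calibrate_scales()` sets
`mm_per_px` by equating the mean segmented spot area with a reference area
(≈ 1 mm² experimentally) and `hr_per_time_unit` by equating the mean motile
agent speed (mean per-snapshot displacement rate of agents motile in
consecutive snapshots) with a reference single-cell speed. Minute-valued
switch parameters can then be re-expressed in internal units and the run
repeated once — the calibration is a fixed point after one iteration in
practice.

## Aggregate detection and tracking

Segmentation follows the density rules used for simulated spots: for every
pixel, count agents within a 3 px radius of the pixel center
(`local_density_map()`, periodic metric); pixels with counts **strictly
above** 40 are foreground; 8-connected components (periodic wrap) smaller
than 10 pixels are discarded; surviving components report pixel-count area
and mean-of-pixel-centers centroid (`segment_aggregates()`). A radius of 0
means containing-pixel binning, whose counts sum to the agent number.

`link_tracks()` is deliberately simple, deterministic linking for sparse,
slow aggregates: every live track claims its nearest next-frame detection
within a gate (default 3× the mean frame-to-frame nearest-neighbor
displacement of the detections themselves); when several tracks claim one
detection, the nearest claimant survives and the others are recorded as
merging into it; unclaimed detections open new tracks. Merge events carry
all participants, so the bookkeeping identity
(final tracks = initial − Σ(participants − 1)) is testable.
`classify_merging()` then counts, per track, the distinct partners across
its merge events — survivor chains accumulate partners, so a spot that
absorbs one neighbor and later another is a three-spot merger — giving the
non-merger / two-spot / three-spot cohorts and the fractional reduction in
spot count.

## Spatial statistics

`voronoi_neighbor_distances()` computes "all nearest neighbors" distances:
the tessellation is built and the distance of every pair of points whose
cells share a positive-length Voronoi edge is pooled, each unordered pair
once. Degenerate point-contact adjacencies (e.g. the diagonals of a square
lattice, where four circumcenters coincide) are excluded, which is exactly
the "shares an edge" semantics. All pairs are pooled by default, including
those involving unbounded (hull) cells: validation against an independent
Delaunay oracle showed that this pooling — not an interior-only variant —
reproduces the reference moments of the uniform-random null ensemble
(pooled mean 3.35 mm, sd 3.00 mm for 1340 points in a 100 mm square); the
heavy right tail comes from long hull-to-hull adjacencies. The
implementation clips each cell by bisector half-planes (stopping once no
remaining bisector can reach the cell) and decides remote hull-pair ridges
with an exact 1-D feasibility test on the bisector, so it needs no
triangulation library and excludes degenerate contacts by construction.

`pair_correlation()` implements the annulus estimator with the focal-point
edge rule: points closer than `r_max` to a boundary are never focal (their
distances to interior focal points still count); bin counts are divided by
the pattern density $\rho = N/L^2$ and the annulus area
$\pi (r_{out}^2 - r_{in}^2)$ and averaged over focal points. There is no
periodic wrap — experimental plates are not periodic — and the defaults
`dr = 0.1` mm, `r_max = 20` mm (for 100 mm regions) resolve the exclusion
gap and first peak while keeping every annulus well populated.

`structure_factor()` integrates, by the trapezoidal rule over the g(r)
bins,

$$s(k) = 1 + \frac{2\pi\rho}{k} \int_0^{r_{max}} (g(r) - 1)\,\sin(kr)\,dr,$$

the sine-kernel form used in the reference analysis. The exact isotropic 2D
transform uses a Bessel kernel, $1 + 2\pi\rho\int (g-1) J_0(kr)\, r\,dr$;
it is available via `kernel = "bessel"`, but the sine form is the default
for comparability. $g \equiv 1$ gives $s \equiv 1$ identically, and the
quadrature agrees with a fine Simpson oracle to $10^{-6}$ on smooth inputs.

Null models: `random_pattern()` (binomial/CSR) and `hard_sphere_pattern()`
(sequential insertion with a minimum separation; 10⁶ consecutive rejections
raise a saturation error). `gen_polydisperse_packing()` generalizes the
latter with Gaussian radii at a given coefficient of variation (0.3 matches
the observed spot-size CV) and collapses exactly onto the hard-sphere
generator at cv = 0. Distribution comparisons use the two-sided two-sample
Kolmogorov–Smirnov test (`stats::ks.test`, asymptotic p).

## Trajectory kinematics

* `average_speed()`: path length / elapsed time (the reference analysis reports only
  "average speed"; a mean-frame-speed mode is provided because the two
  differ on noisy tracks).
* `distance_over_displacement()`: path directness, ≥ 1, undefined (NA, not
  infinite) for closed tracks.
* `msd_exponent()`: ensemble MSD from each track's first point at common
  lags (not time-averaged within tracks — tracks are short and
  heterogeneous), log-log least squares over lags up to half the shortest
  track. Brownian and ballistic generators recover α = 1 and 2 within 0.1
  and 0.05.
* `merging_kinematics()`: the constant-acceleration model. The relative
  distance $d_{rel}(t) = |\mathbf{r}_A - \mathbf{r}_B|$ of a merging pair
  is fit by least squares to a quadratic; the closing acceleration is
  reported as $-2 b_2$ so an accelerating approach is positive. Series
  shorter than 20 points are excluded (they do not constrain curvature) —
  the same inclusion rule as the reference analysis.
* `force_law_fit()`: acceleration versus distance under
  $a = A_0 e^{-n d}$ or $a = A_0 / d^n$, with acceleration estimated by
  central second differences of a 3-point moving average (the reference
  analysis leaves the differentiation scheme unstated; this is the
  least-committal one). Fits whose exponent SE reaches half the exponent's
  magnitude are flagged excluded rather than silently reported.
* `cohort_summary()`: per-class fractions and means, Student's
  equal-variance t-test of merger vs non-merger speeds ("unpaired t-test"
  as printed; Welch via flag), Spearman correlations of acceleration vs
  total merged area and of speed vs mean minimum nearest-neighbor distance
  (per frame: distance to the nearest co-existing track; minima averaged
  over the track's frames). No multiple-testing correction is applied, to
  match the reference analysis.

## Synthetic data and what tests do and do not show

Every analysis stage has a generator whose ground truth it must recover:
`gen_merger_pair()` (exact quadratic approach, optional Gaussian jitter,
truncated at the analytic contact time), `gen_scaling_tracks()` (Brownian /
ballistic ensembles), `gen_planted_aggregates()` (dense discs plus free
agents, known centroids), `gen_polydisperse_packing()`. The generators
produce the same CSV schemas as real data, so the I/O layer is exercised
too.

These fixtures emulate the *statistical structure* of real tracking data —
not its imperfections. Real tracking exports have detection dropouts, gap
closing, segmentation noise correlated with spot brightness, and drift;
none of that is generated here, so green round-trip tests certify the
estimators, not robustness to instrument artifacts. Similarly, the reduced
simulation used in the test suite (10,000 agents on a 128² grid for 10⁴
steps, preserving the control agent density of ~0.68 agents/px²) is sized
to show spot formation, a persistent motile fraction and merging within a
test run; full-scale phenomenology (motile fraction plateau near 40%,
merger fraction near 6%) is a property of long full-scale runs.

## Known limitations

* The model deliberately omits growth, death, nutrient fields and
  chemoattractant uptake; it cannot describe the late dissolution of the
  spot pattern.
* Linking is greedy nearest-neighbor without gap closing; heavily
  occluded or dense detection sets deserve a global assignment linker.
* The sine-kernel structure factor is kept for comparability even though
  the Bessel kernel is the mathematically exact 2D transform.
* The pooled Voronoi statistic's standard deviation is tail-dominated
  (longest hull adjacencies), so single-ensemble values scatter by ~1%
  around their expectation; comparisons tighter than that need pooled
  replicate ensembles.
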