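# spotdyn

Chemotactic bacteria that secrete their own attractant can collapse from a
uniform culture into a pattern of macroscopic aggregates — millimetre-scale
spots of immotile cells surrounded by swimming cells — which then migrate
over several diameters and sometimes merge. spotdyn is an R package for
scientists studying this phenomenon from both ends:

* **forward**: a 2D agent-based model in which Brownian agents drift up a
  self-secreted chemoattractant gradient under receptor-law sensitivity
  (`v = chi0 * grad(c) / (1 + c/c_half)^2`), while a transient,
  density-dependent motility switch (immobilization above a concentration
  threshold `c*`, a fixed refractory interval, stochastic reactivation, and
  a gradient-blind Brownian interval) turns static Keller–Segel spots into
  dynamic, merging ones;
* **inverse**: the quantification pipeline used on time-lapse data —
  density-based segmentation, frame-to-frame track linking with merge-event
  classification, spatial point-pattern statistics (Voronoi "all nearest
  neighbors" distances, radial pair correlation g(r), structure factor
  s(k), random and hard-sphere null patterns), and merging kinematics
  (constant-acceleration fits of the pair separation
  d_rel(t) = d0 + b1 t + b2 t^2, force-law fits, MSD scaling exponents,
  cohort statistics).

Simulated snapshots and experimental tracking exports flow through the same
functions, so model and experiment are compared with identical estimators.

## Worked example

A reduced-scale run (10,000 agents on a 128² periodic grid for 10⁴ steps,
at the control agent density) forms spots, keeps a motile population, and
already shows merging during coarsening:

```r
library(spotdyn)
p   <- sim_params(n_agents = 10000L, grid_size = 128L, t_final = 50,
                  snapshot_every = 1000L)
sim <- run_simulation(p, seed = 424242, keep_fields = FALSE)
print(sim)
#> spotdyn simulation: 10000 agents, 128 x 128 grid, 11 snapshots (t = 0 .. 50)
#>   final motile fraction: 0.632

det    <- detect_aggregates(sim)            # radius 3 px, counts > 40, area >= 10 px
linked <- link_tracks(det[, c("frame", "time", "x", "y", "area")])
cls    <- classify_merging(linked$tracks, linked$merge_events)
round(cls$fractions, 3)
#>        non_merger   two_spot_merger three_spot_merger
#>             0.178             0.478             0.344
```

The final motile fraction (0.63, still relaxing toward its long-run band)
shows the motility switch at work: without it virtually every agent ends up
bound in a spot. The merge-class fractions at this scale are dominated by
formation-phase coarsening; the non-merger share grows as the pattern
stabilizes in longer, full-scale runs. Cohort statistics come from the same
tracks:

```r
trajs <- tracks_to_trajectories(linked$tracks, cls$classes, min_points = 5)
cohort_summary(trajs)
#> cohort summary over 29 trajectories
#>   non_merger         n =   6 (20.7%)  mean speed 0.244  mean dist/disp 2.06
#>   two_spot_merger    n =   6 (20.7%)  mean speed 0.382  mean dist/disp 1.47
#>   three_spot_merger  n =  17 (58.6%)  mean speed 0.292  mean dist/disp 1.99
#>   merger vs non-merger speed: diff 0.07084, t-test p = 0.129
```

Speeds here are in px per time unit; `calibrate_scales()` converts to
mm/hr by matching the mean spot area and mean motile-agent speed to
reference values, and `unit_context()` does the same for tracking exports
(default frame interval 0.25 hr, the 15-minute imaging cadence).

Spatial statistics of a null pattern, the package's reference check:

```r
set.seed(1)
pat <- random_pattern(1340, 100)            # 1340 points in a 100x100 mm square
d   <- voronoi_neighbor_distances(pat)      # all Voronoi-adjacent pairs, pooled
sprintf("%d neighbor pairs, mean %.2f mm, sd %.2f mm", length(d), mean(d), sd(d))
#> [1] "4004 neighbor pairs, mean 3.42 mm, sd 3.49 mm"
```

A command-line front end wrapping these functions ships at
`inst/cli/spotdyn.R` (`simulate`, `segment`, `track`, `spatial`,
`kinematics`, `synth`, `sweep`).

## Documentation

The methods vignette (`vignettes/spotdyn-methods.Rmd`) describes the model
and its assumptions, every tunable parameter with units and defaults, the
numerical schemes and their invariants, the estimator conventions, and what
the synthetic fixtures do and do not emulate.
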