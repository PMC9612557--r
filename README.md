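# colonycapture

Simulation and analysis toolkit for a question of experiment design in
long-term time-lapse microscopy: **how many imaging positions still contain
a trackable cell colony at the end of a multi-day recording?**

Motile colonies (for example mouse embryonic stem cells, which migrate at
roughly 1 um/min) drift out of a fixed camera field of view (FOV) long
before a 4-day movie ends, so most recorded positions never yield a complete
division tree ("entire lineage"). Confining colonies to adhesive micropatterned
zones removes that loss. Quantifying the gain requires knowing how often an
*unconfined* colony would have stayed in view — a quantity that is almost
unobservable experimentally and is instead estimated by simulation. This
package provides that simulation machinery, the closed-form random-walk
analytics around it, and a nucleus segmentation/tracking pipeline validated
on synthetic movies with known ground truth.

## What is in the box

* **FOV geometry** — exact closed-form area of a disk-shaped colony
  footprint intersected with the rectangular FOV
  (`disk_rect_overlap_fraction()`, vectorized as `capture_fraction_xyr()`).
  The per-frame *capture fraction* is `area(colony ∩ FOV) / area(colony)`.
* **Colony simulator** (`simulate_movie()`) — a colony of `n` cells of
  radius `r1` occupies a disk of radius `r1 * sqrt(n)`; its center performs
  an isotropic fixed-step random walk while `n` grows under either a
  *synchronized* cell-cycle model (`n(t) = 2^floor(t/T)`, area doubling
  every `T` = 12 hr) or a *continuous stochastic* (Gillespie pure-birth)
  model with waiting time `-(T/n) * log(u)`, `u ~ U(0,1)`.
* **Batch experiments** (`run_experiment()`) — thousands of movies in
  batches of 100 (one batch = one microscope session's stage positions),
  classified against >50% and >90% capture thresholds; means and SDs are
  reported across batches. `run_paper_reproduction()` bundles everything.
* **Analytics** — `D_rw = <r>^2 / (pi * dt)` from a mean per-frame
  displacement; adhesive-zone escape time `T = R_zone^2 / (4 D_rw)`;
  continuous colony radius `r1 * 2^(t/2T)`.
* **Synthetic movies** (`make_movie()`) — fluorescence-like image stacks of
  nuclear-label spots: compact circular colonies, heritable log-normal
  brightness that halves at division, a multiplicative paraboloid
  illumination bias, Poisson noise, multi-frame TIFF IO, and full
  ground-truth lineages.
* **Lineage tracker** (`track_movie()`) — paraboloid flat-field correction,
  threshold segmentation with connected components, exact optimal-assignment
  frame linking on a position + intensity cost, and discontinuity heuristics
  that repair transient merges and call divisions; scored against ground
  truth by `evaluate_tracking()` and `lineage_capture_fraction()`.

## Worked example

```r
library(colonycapture)

# one 4-day movie: a single cell at the FOV center, synchronized divisions
m <- simulate_movie(duration = 96, seed = 7)
m
#> Simulated movie: 385 frames over 96.0 hr, synchronized growth
#>   final n = 256 cells, radius 120.0 um
#>   capture fraction: min 0.860, final 0.860
```

After 8 area doublings the colony radius is 120 um — about as wide as the
221.9-um FOV — and this particular colony drifted enough that only 86% of
its area remains in view, so the position fails the "entire lineage"
(>90%) criterion.

```r
# closed-form migration analytics at the reference constants
str(migration_analytics())
#> $ D_rw             : num 4.77      # um^2/min from <r> = 15 um per 15 min
#> $ escape_time_hr   : num 13.6      # mean escape from a 125-um zone
#> $ radius_end_um    : num 120       # day-4 colony radius
#> $ radius_geomean_um: num 30        # literal time-geometric-mean radius

# 2,000 unconfined movies in 20 batches of 100 stage positions
d <- experiment_design(n_batches = 20, batch_size = 100, seed = 1)
run_experiment(d)
#> Capture statistics: 2000 movies (20 batches of 100), synchronized growth, final_frame
#>   > 50% capture: 10.7% +/- 3.2% of positions
#>   > 90% capture: 1.1% +/- 1.0% of positions
```

Roughly one unconfined position in a hundred captures an entire lineage
over 4 days; dividing a patterned-surface full-lineage rate of 72.3% by
that simulated rate (`throughput_improvement(0.723, 0.011)`) gives an
effective-throughput gain well above 30-fold.

The tracker side:

```r
fov <- fov_from_camera(256, 256, 0.8672)      # 222-um FOV, coarse sampling
mv <- make_movie(duration = 30, fov = fov, seed = 11)
tr <- track_movie(mv$frames)
evaluate_tracking(tr, mv)$link_recovery       # 1 on this movie
```

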