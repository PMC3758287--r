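# phagotrack

Segmentation, tracking and kinematic analysis of fluorescent phagocytes
in 3D time-lapse microscopy, written for the inflammation-biology setting
where GFP-labelled neutrophils or macrophages migrate towards a wound
(e.g. a transected zebrafish tail fin) under a confocal or multiphoton
microscope. It is aimed at labs that want a scriptable, fully
deterministic alternative to manual or GUI-based cell tracking, with a
synthetic benchmark to quantify how much noise the analysis tolerates.

## What it computes

* **Segmentation** — double **hysteresis thresholding**: voxels below a
  low threshold are background, voxels above a high threshold are cell,
  and in-between voxels join the cell class only when connected to a
  high-threshold seed. Both thresholds come from a three-class Otsu
  partition of the intensity histogram (exhaustive two-threshold
  between-class-variance maximisation, computed above a robust
  background floor). Objects whose volume exceeds
  *mean + 3 SD* of the pooled volume distribution are split in two by
  sequential erosion, conserving total volume.
* **Tracking** — the **keyhole model**: from positions at *t−1* and *t*
  the landing position at *t+1* is predicted assuming constant velocity;
  candidates are accepted inside a 60° wedge towards the prediction
  (reach 3× the previous displacement) or a complementary 300° truncated
  sphere (radius 1×) around the current position, and links are assigned
  greedily by distance to the prediction. Post-processing validates
  every link backwards in time, bridges single-frame gaps with
  interpolated nodes, and resolves collisions by watershed re-splitting
  of merged objects (volume-conserving), with delete/break/merge editing
  and an audit log.
* **Kinematics** — a wound rectangle defines axes **c** (towards the
  wound) and **r** (lateral); every displacement yields oriented,
  lateral and absolute velocities and an effective velocity in [−1, 1]
  (cosine of the angle to **c**). Per track: mean velocities, meandering
  index, wound arrival. Per population: forward/backward ratios,
  in-wound and idle ratios, transiting counts — and a volume-vs-position
  band profile (25 bands × 20 columns) with an OLS slope test.
* **Benchmarking** — a synthetic generator (moving anisotropic Gaussian
  cells with gold-standard tracks; white Gaussian or Poisson+Gaussian
  noise) whose noise level is calibrated by bisection to a target
  **Bhattacharyya distance** between cell and background intensities,

  `BD = ¼ ln(¼(v₁/v₂ + v₂/v₁ + 2)) + ¼ (m₁−m₂)²/(v₁+v₂)`,

  plus tracking accuracy metrics `d_ag`/`d_ga` (mean node-wise distance
  from automatic to gold-standard tracks and vice versa) and a
  40–140% threshold-robustness sweep.

## Worked example

Generate the default benchmark (98 time points, 11 slices of 275×275
pixels, six cells), add noise calibrated to the most separable benchmark
level (BD = 1.61), run the full pipeline and score it:

```r
library(phagotrack)

spec <- synthetic_spec()                  # 98 t, 11 slices, 275x275, 6 cells
bench <- generate_dataset(spec, seed = 1)
profiles <- clean_class_profiles(bench$sequence, spec)
sigma1 <- calibrate_noise(profiles, 1.61) # most separable level
round(as.numeric(sigma1), 2)
#> [1] 35.82

noisy <- add_noise(bench$sequence, "white_gaussian", as.numeric(sigma1), seed = 7)
cfg <- pipeline_config(wound = c(100, 137, 1, 137), wound_side = "right")
bundle <- run_pipeline(noisy, cfg)
#> read: 98 time points of 275x275x11
#> reduce: grid now 137x137x11
#> segment: thresholds low=86.95 high=134.87
#> segment: 588 objects in total
#> track: 6 tracks from 588 nodes
#> post-processing: 6 tracks of length >= 3

print(bundle$metrics$population)
#> <population_metrics>
#>   mean_velocity                1.131
#>   mean_oriented_velocity       0.9237
#>   mean_lateral_velocity        0.006102
#>   mean_meandering_index        0.8473
#>   in_wound_neutrophils         5
#>   forward_ratio                0.8127
#>   ...

gold <- bench$gold
gold$x <- to_reduced_coords(gold$x); gold$y <- to_reduced_coords(gold$y)
track_set_distance(bundle$track_set, gold)
#> <track_distance_report> d_ag = 0.154 (median 0.146), d_ga = 0.154 (median 0.146)
#>   588 auto nodes (0 unmatched), 588 gold nodes (0 unmatched)
```

All six cells are recovered as single full-length tracks with sub-pixel
centroid accuracy (distances are in pixels of the processed grid). The
population panel says the cells moved at ~1.1 px/frame, almost all of it
oriented towards the wound (mean effective behaviour: 81% of
displacements score above 0.6), five of six reached the wound region and
none left it again.

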