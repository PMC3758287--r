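---
title: "Segmenting, tracking and measuring fluorescent phagocytes in 3D"
author: "phagotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting, tracking and measuring fluorescent phagocytes in 3D}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagotrack)
```

phagotrack quantifies the migration of fluorescently labelled phagocytes
(neutrophils, macrophages) imaged as 3D time-lapse stacks, the typical
setting being GFP-labelled neutrophils converging on a tail-fin wound in a
zebrafish larva. This vignette explains the model behind each stage, the
parameters that matter and their defaults, what the synthetic benchmark
does and does not emulate, and the numerical choices a maintainer would
want spelled out.

## The data model

A recording is a `volume_sequence`: one `volume_stack` (a 3D array, rows =
y, columns = x, slices = z) per time point. All coordinates in the package
are 1-based voxel centres; centroids are continuous in the same units.
Time is a 1-based frame index. Physical units enter only through the
optional voxel size (µm) and frame interval (min); all internal
computations are in pixels and frames.

Fluorescent and transmitted-light (DIC) channels are told apart by their
histograms (`classify_channels`): fluorescence concentrates the vast
majority of voxels at the bottom of its dynamic range, DIC peaks
mid-range. A channel is tagged fluorescent when at least 85% of its voxels
lie in the lowest quarter of the observed range; both numbers are
configurable and the statistic is computed on the per-channel range, so
global rescaling does not change the outcome.

## Pre-processing

**Reduction.** Each z-slice is reduced by averaging disjoint 2x2 pixel
blocks (`reduce_stack`). This halves rows and columns, leaves z alone,
and improves the signal-to-noise ratio by a factor of two at the cost of
in-plane resolution — the standard first move for large recordings. A
trailing odd row or column is cropped rather than padded, which keeps
every output voxel the mean of four genuine neighbours. The in-plane
voxel size doubles accordingly, and `to_reduced_coords()` /
`to_original_coords()` convert coordinates between the grids.

**Thresholds.** Segmentation uses double hysteresis thresholding: voxels
below the low threshold are background, voxels at or above the high
threshold are definite cell, and voxels in between count as cell only if
their connected component (26-connectivity by default) touches a
high-threshold seed. This avoids both failure modes of single-threshold
segmentation — background bleeding in at a permissive threshold, and a
single stretched cell shattering into fragments at a strict one.

Both thresholds come from a three-class Otsu partition: an exhaustive scan
of all threshold pairs on a 256-bin histogram, maximising the
between-class variance. One subtlety matters for fluorescence volumes: the
cells typically occupy well under 1% of the voxels. On the raw histogram
the two-threshold optimum then always splits the dominant background mode
(the gain `w_bg * 0.64 * sigma_bg^2` of splitting a near-Gaussian mode of
weight ~1 dwarfs anything a vanishing foreground class can contribute),
which would drop the low threshold into the background noise. phagotrack
therefore restricts the histogram to voxels above a robust background
floor — median + 3 x 1.4826 x MAD — before scanning; the scan itself is
unchanged. `background_trim = FALSE` restores the literal full-histogram
scan for data where the classes are balanced. Thresholds are computed once
per dataset from the pooled histogram (per-time-point selection is
available via `per_timepoint`), and `threshold_fraction` scales both
thresholds for robustness experiments.

Components smaller than `min_volume` voxels (default 5) are discarded
after labelling. At realistic noise levels, isolated noise excursions
produce a steady rain of 1-4 voxel components; no credible cell
cross-section is that small on the processed grid, and downstream linking
would otherwise occasionally chain such specks into short spurious tracks.

**Volume outliers.** The volumes of all objects at all time points are
pooled; an object exceeding mean + 3 SD (`outlier_k`) is taken to be two
touching cells. It is eroded with a 3x3x3 element until it separates,
then every original voxel is reassigned to the nearest surviving fragment
geodesically within the object, so the split conserves total volume and
the two new volumes remain meaningful. A convex object that shrinks to
nothing without separating is left intact and flagged `unsplittable`;
erosion stops after `max_erosions` (default 30) passes. For strongly
anisotropic stacks (z step >> pixel pitch) `erode_in_plane` restricts the
element to 3x3x1.

## Tracking: the keyhole model

Linking an object at time t to its successor at t+1 uses a motion model
rather than plain nearest-neighbour matching. From the positions at t-1
(grandparent) and t (parent), the most probable landing position at t+1
is the constant-velocity prediction. Two probability regions together
resemble a keyhole:

* a narrow **wedge**, 60° wide, aimed at the predicted landing position,
  reaching 3x the previous displacement — for cells that keep going;
* a complementary **truncated sphere** (the remaining 300°) of radius 1x
  the previous displacement around the current position — for cells that
  turn or jiggle.

All (parent, child) pairs whose child falls inside the parent's keyhole
are candidate links; they are granted greedily in increasing distance to
the predicted landing position, each node used at most once, ties broken
by node id, so tracking is fully deterministic. Unmatched objects open
new tracks.

Two practical amendments, both configurable:

* **First link / idle rule.** With no grandparent, or a previous
  displacement below `idle_tol` (0.5 px), there is no direction to
  predict, and a plain sphere of `first_link_radius` (default 3x the
  median object diameter) is searched instead. Backward validation then
  prunes bad first links.
* **Minimum keyhole.** The keyhole scales with the previous displacement,
  so for a slow cell (~1 px/frame) it would shrink below the centroid
  jitter of the segmentation itself and even perfect straight paths
  fragment. Candidates within `min_keyhole` (default: the median object
  diameter) of the parent are therefore always considered reachable — a
  cell can always be re-found within its own footprint.

**Backward validation** rebuilds each link's keyhole from the two later
nodes pointing backwards in time and cuts links whose earlier node falls
outside it. This matters most for the first link of each track, which was
formed without history; by default every link is re-checked
(`backward_mode = "first"` restricts it).

**Gap bridging.** A cell present at t-1, absent at t and present at t+1
within `gap_roi_radius` (default 2x the median object diameter) is taken
to be a faint cell that dipped below threshold for one frame. An
interpolated node (midpoint position, mean volume) is inserted and the
two track pieces merged; applied repeatedly, this reassembles a blinking
cell. Only single-frame gaps are bridged: the absent-one-frame pattern is
what the interpolation is evidence for.

**Collisions and divisions.** Cells that collide look like one object
with too much volume. A merge is declared when a node's volume is at
least `collision_volume_ratio` (1.5) times its track's previous volume
*and* a neighbouring track terminated at the previous frame within
`gap_roi_radius`. The merged object's mask is then re-split frame by
frame with a seeded watershed — priority flooding of the chamfer distance
transform from seeds at the colliding tracks' last distinct positions —
which partitions the mask exactly, so foreground volume is conserved.
The terminated track continues through its half; when the merged interval
ends with a volume drop and a newly starting neighbour track (the inverse
rules: a division event), the two split chains are joined to the two
diverging heads by total distance. Re-attachment after a split is by
nearest distance within the event, not a fresh global keyhole pass: the
affected nodes are at most a few voxels apart and the local rule keeps
the rest of the network untouched. Division events without a detected
preceding merge are logged but not acted on — from the division frame
onward the objects are already separate. If the watershed yields fewer
regions than seeds the event is logged unresolved and the object left
merged. Spurious volume jumps are common in very noisy segmentations, so
at most `max_events` (20) merge events are processed per run.

**Filtering and editing.** Tracks shorter than `min_track_length`
(default 3 nodes) are released: single-frame objects are noise by
definition, and at benchmark noise levels chance *pairs* of noise blobs
in consecutive frames are also common enough (a first-link radius of ~3
object diameters sweeps up roughly one per frame transition) that
two-node tracks carry no evidence. The three manual editing operations —
`delete`, `break`, `merge` (bridging at most a one-frame gap) — are
exposed programmatically through `edit_tracks`, with every edit appended
to an audit log.

## Wound-oriented kinematics

A manually drawn rectangle defines the wound region. It induces a rotated
frame: unit vector **c** towards the wound, unit vector **r** lateral.
Each displacement decomposes into an oriented distance (along **c**), a
lateral distance (along **r**) and the absolute distance (full 3D
magnitude; the in-plane identity oriented² + lateral² + z² = absolute²
holds exactly). The effective velocity is the cosine of the angle between
the displacement and **c** — +1 straight at the wound, 0 perpendicular,
-1 straight away — the unique smooth score matching those anchors. The
oriented/lateral decomposition is in-plane because the wound frame is a
planar construct; z enters the absolute velocity only.

Per track: mean absolute/oriented/lateral velocity (µm/min when voxel
size and frame interval are provided, px/frame otherwise), the meandering
index (net displacement over path length; 1 = perfectly direct), duration
and wound arrival. Per population, from individual displacements: counts
of wound-reaching and transiting cells, the forward ratio (fraction of
displacements with effective velocity > 0.6), in-wound ratios, the idle
ratio (absolute velocity < `idle_cut`, default 0.5 px/frame, of in-wound
displacements), and the backward and leave-wound ratios. Two sign
conventions circulate for the backward-type ratios: a literal
"larger than -0.6" criterion, which duplicates the forward-type
behaviour, and the mirrored reading (effective velocity < -0.6), which
is what a backward ratio plainly means. The package defaults to the
mirrored reading and `literal_ratios = TRUE` applies the literal
criterion. Ratios with empty
denominators are `NA`, never 0. The in-wound ratio counts displacements
of all tracks; `in_wound_ratio_2` restricts the denominator to
displacements after the track first reached the wound.

**Volume against position.** To ask whether cells swell as they approach
the wound, migratory tracks (duration above 30 frames, mean absolute
velocity at least 2 px/frame on the processed grid — both configurable)
contribute every node to one of 25 adjacent bands of 20 columns each,
higher band numbers closer to the wound. Node volumes are normalised to
the dataset mean (so the grand mean of normalised volumes is exactly 1),
averaged per band, and an ordinary least squares line of band mean
against band index is fitted with a two-sided t-test on the slope.

## The synthetic benchmark

`generate_dataset()` renders moving cells as 3D Gaussian blobs on a
constant background, with exact centroids recorded as the gold standard.
The default geometry is 98 time points of 11 slices of 275x275 pixels
with six cells. The blob parameters are not dictated by any published
value, so they are declared once here: 8-bit intensity scale, background
15, peak amplitude 200 above background, anisotropic in-plane widths
(3.5, 2.3) px rotated per cell, z width 1.3 slices, rendering truncated
at 3 widths (the truncation error is below 1.2% of the amplitude and
keeps rendering linear in the number of cells).

The six default paths realise the benchmark's stated conditions —
tortuosity, time to activation, proximity: a straight mover, two
sinusoids of different tortuosity (periods 40 and 24 frames), a cell that
idles for 30 frames before setting off, and a pair that approaches to
about two cell diameters and separates. The tortuous period was chosen so
that the per-frame turning angle stays within what any physically drawn
migration path exhibits; a sinusoid turning >90° per frame defeats every
motion model and corresponds to no real cell. A separate `crossing` style
brings a pair within one cell diameter for collision experiments, and
`transit` sends staggered cells across the full field width for
position-dependent measurements. An `irregular` shape variant overlays an
isotropic base blob with six randomly offset satellites (maximum over
components, so the peak amplitude is preserved) for a lumpier, more
realistic silhouette.

**Noise and calibration.** White Gaussian noise of variance sigma², or
Poisson shot noise (each voxel replaced by a Poisson draw with its clean
intensity as mean) plus Gaussian read noise, the better model of confocal
and multiphoton acquisition; intensities are clipped to the valid range
and only quantised on export, with separability computed pre-quantisation.
The separability between the cell and background intensity classes is
summarised by the Bhattacharyya distance

BD = ¼ log(¼ (v₁/v₂ + v₂/v₁ + 2)) + ¼ (m₁ - m₂)² / (v₁ + v₂),

with the cell class defined as the voxels inside the noiseless
half-maximum isosurface and the background as everything else. SNR is
reported as 20 log₁₀ of the ratio of the classes' RMS deviations about
their means. `calibrate_noise()` finds, by bisection, the sigma that hits
a target BD. The model behind the bisection is exact rather than
simulated: the mean and variance of clip(v + N(0, sigma²), 0, max) have
closed censored-normal forms, which are integrated over the noiseless
per-class intensity histograms. Clipping matters — at the strongest
benchmark noise a third of the background distribution would fall below
zero — and handling it exactly is what makes the calibrated levels
reproduce their targets when the BD is re-estimated empirically from
generated voxels (to within sampling error, about ±0.015 at the default
volume of 8x10⁷ voxels). The five benchmark levels target BD = 1.61,
1.25, 1, 0.66, 0.45; they are recomputed by `calibrate_noise_levels()`
in a few milliseconds, so no magic sigma values are stored anywhere.

**What the benchmark does not emulate.** Real recordings have uneven
illumination and background structure, cells that change shape and
brightness as they crawl, depth-dependent attenuation, and anisotropic
optical blur; the benchmark has none of these. Passing the benchmark
therefore demonstrates that the algorithms are correct and robust to
photon-budget noise at known separability, not that any particular real
dataset will segment cleanly; on real data the thresholds and the wound
rectangle remain the user's responsibility (and wound-region size
sensitivity should be checked, since several measurements depend on it).

## Evaluation

Tracking accuracy against a gold standard is summarised by two node-wise
distances: `d_ag`, the mean distance from each automatic node to the
nearest gold node at the same time point, and `d_ga`, the reverse. The
pair separates the two failure modes — spurious automatic tracks inflate
`d_ag`, missed faint cells inflate `d_ga`. The aggregation is node-wise
(medians and per-track means are also reported); nodes with no
counterpart at their time point are excluded from the mean and counted as
unmatched rather than assigned an arbitrary penalty.
`threshold_sweep()` re-runs the full pipeline with the automatic
thresholds scaled by each fraction (the classical 40%-140% robustness
experiment) and scores every run; a failure at one fraction is recorded
and the sweep continues.

## Numerical choices and degenerate inputs

* Otsu ties are broken by the first maximum in scan order; a constant
  stack raises an error (no threshold exists), and a two-valued image
  puts both thresholds in the gap, where hysteresis coincides with
  simple thresholding.
* Connected components, erosion, the chamfer distance transform
  (weights 1, √2, √3) and the priority-flood watershed are implemented
  in C++; all tie-breaks are by voxel index, so every stage is
  deterministic.
* Centroids are plain voxel means by default (intensity weighting is
  available); volumes are voxel counts.
* Interpolated nodes carry the mean volume of their neighbours and are
  flagged, and are never used as collision-volume evidence.
* Problem sizes used by the shipped tests: the full default benchmark
  (98 x 11 x 275 x 275) for track recovery, separability and the
  threshold sweep (on a reduced fraction grid: 0.6/1.0/1.4 at low noise,
  0.4/1.0 at high noise), and a 64-frame, 1000-column field for the
  volume-gradient recovery; oracle equivalences run on 20³ grids and
  10⁴ random keyhole configurations.

## Known limitations

* Collisions of three or more cells are re-split with the same two-seed
  machinery only pairwise; dense clumps at the wound will defeat it.
* A cell that jumps several times its own size between frames, with
  neighbours nearby, can still be mis-linked — the keyhole model bounds
  the search but cannot disambiguate everything; the editing operations
  exist for exactly these cases.
* The wound frame is planar; oriented/lateral kinematics ignore z by
  construction.
* One fluorescent channel is assumed; multi-fluorophore joint analysis
  is out of scope.
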