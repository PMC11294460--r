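---
title: "Quantifying junctional localization in endothelial monolayers"
author: "junctionscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying junctional localization in endothelial monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(junctionscape)
```

## The problem

A confluent endothelial monolayer is a tiling of cells whose boundary
network has two kinds of elements: *bicellular junctions*, where exactly
two cells abut, and *multicellular (tricellular) vertices*, where three
or more cells meet. In lymphatic endothelium the vertices are
functionally special: chemokine-loaded secretory vesicles dock and fuse
there, the docking factor ELKS accumulates there, and migrating
dendritic cells preferentially arrest and transmigrate there. Every
quantitative claim of that kind reduces to the same measurement
pattern: detect objects (vesicles, fusion events, cells, tracks),
measure their distance to the nearest multicellular vertex — either
straight-line or along the junction — and summarize the distances in
bins, fractions or group comparisons.

`junctionscape` implements that pattern as a pipeline of small,
separately testable stages, together with a synthetic-monolayer
generator that plants every parameter the pipeline is supposed to
recover. The generator is not a fixture factory: it is the package's
specification of what the analyses mean, and the test suite closes the
loop from planted parameter to recovered estimate for each stage.

## The junction graph

`build_junction_graph()` traces the boundary network of a label image
at "crack" resolution: boundaries run along the lattice of pixel
corners between pixels of different label, so a straight border yields
an exactly straight polyline and arc lengths carry no rasterization
staircase beyond the pixel geometry itself. A corner whose 2×2 pixel
neighborhood contains ≥ 3 distinct labels is a vertex locus; loci
within 2 px of each other are merged and represented by their centroid
(the reproducible analogue of marking a vertex with a dot by hand).
Boundary chains between exactly two labels become edges, split at
vertices; a chain end on the image border is OPEN, never a vertex,
because the junction continues outside the field of view. Analyses that
need a vertex at both ends (profile folding, along-junction distances)
use only *closed* edges.

Two distance measures are exposed, mirroring the two measurement
procedures in use:

* **Euclidean** (`nearest_vertex_distance()`, `distance_field()`): the
  distance-transform convention, used for vesicle colocalization
  binning. The field is computed exactly (minimum over vertices at each
  pixel center), so it is identical to the point query by construction.
* **Arc** (`arc_distance_to_vertex()`): the point is projected
  perpendicularly onto the nearest edge polyline (within a configurable
  band half-width, 7 µm by default) and the distance is the cumulative
  arc length from the projection to the nearer closed endpoint — the
  "draw a line along the junction to the nearest multicellular
  junction" convention used for exocytosis and explant transmigration.
  Ties between edges go to the smaller arc distance; points outside
  every band are flagged, not guessed.

Half-open bins `[0, w), [w, 2w), …` (default `w` = 5 µm, 2 µm for
discontinuous capillary-tip junctions) conserve counts exactly.

## The synthetic monolayer and its planted truth

Geometry is a Voronoi tessellation of uniform random seeds, rasterized
onto the pixel grid, with Lloyd relaxation as the regularity knob
(default 2 iterations — enough to give the near-isotropic, convex-ish
cells of a cultured endothelial sheet while keeping realistic
irregularity). Coordinates are continuous in µm, x along columns, y
along rows, origin at the top-left pixel center. The ground-truth graph
is derived from the labels by the same `build_junction_graph()` the
analyses use, which is deliberate: the generator defines truth in the
exact vocabulary the pipeline measures.

Samplers plant known structure on that geometry, and each stores its
generating labels per point:

* `sample_junction_spots(n, tau, beta, band_halfwidth, perp_halfwidth)`
  draws `(1−β)·n` junctional points whose along-junction density is
  `∝ exp(−d/τ)` (d = arc distance to the nearest vertex) and `β·n`
  uniform background points. Two widths are deliberately distinct: the
  *capture band* (7 µm, the counting region inherited from the 14 µm
  analysis line) and the *physical spread* of points around the
  junction midline (default 1 µm) — vesicles and fusion events sit at
  the membrane junction itself; the band only collects them. Conflating
  the two would smear the planted decay by the band width and make τ
  unrecoverable by any correct estimator.
* `plant_colocalization(f, jitter_sd, n_extra)` places `round(f·n)`
  second-channel points on a random subset of the reference spots plus
  isotropic Gaussian localization jitter, and `n_extra` unrelated
  points; the true pair identity is stored.
* `sample_exocytosis_events(rho0, tau, duration)` draws per-cell counts
  from Poisson(ρ₀·duration) and positions along the owning cell's
  junctions with the same exponential decay.
* `sample_tracks(persistence, step, arrest_fraction, noise_sd)`
  generates correlated random walks (heading turn sd
  `(1−p)·π` per 90 s frame, so `p = 1` is perfectly straight) and a
  planted fraction of arrested tracks that hold a vertex position up to
  localization noise. Tracks reflect at field edges; the truth table
  records whether a reflection occurred, because a reflected
  fully-persistent track is legitimately no longer straight.

The rendered junction channel (`render_junction_image()`) is a
boundary mask blurred with a Gaussian (σ = 0.3 µm by default, a
realistic immunostained junction line) with Poisson shot noise at a
stated peak SNR plus optional Gaussian read noise — the standard
two-parameter fluorescence camera model.

What the generator does **not** emulate: elongated or oak-leaf-shaped
in vivo cell outlines (Voronoi cells are convex-ish), discontinuous
button junctions (beyond OPEN ends), 3-D structure, photobleaching and
drift. Passing tests therefore demonstrate correctness of the
measurement logic on realistic topology and noise, not robustness to
every morphology real tissue can present.

## Rebuilding topology from images, and comparing graphs honestly

`segment_junction_image()` inverts the renderer: smooth, threshold
(Otsu), take connected components of the non-boundary region as cell
seeds (discarding specks below 4 µm²), and grow the seeds across the
boundary band by intensity-guided propagation so the fronts meet on the
intensity ridge — the junction midline. The rebuilt labels then go
through `build_junction_graph()` like any labels.

Comparing a rebuilt graph with the planted one raises a resolution
question that any imaging-based junction analysis faces: a rasterized
Voronoi tessellation contains bicellular edges much shorter than the
junction line width (two tricellular vertices 0.5–2 µm apart), and in
a rendered image such a pair is indistinguishable from a single
higher-order vertex. `match_graphs()` therefore compares *quotient*
graphs at a stated resolution scale: both graphs are contracted with
`contract_short_edges()` (vertices joined by closed edges shorter than
the scale are fused), residual straddle cases — where one graph merged
a pair and the other kept it — are fused by mutual-nearest association
within the same scale, and a border margin is excluded because border
junctions end OPEN and their vertex topology is not fully observed.
The package uses 2 µm for this scale: roughly twice the rendered line's
full width at half maximum, below which two converging junction lines
overlap into one blob. Isomorphism (equal vertex counts, degrees and
closed-edge adjacency under the positional match) is then a meaningful,
attainable statement; on twenty 16-cell monolayers at 0.2 µm/px the
noiseless rebuild is isomorphic in all cases and, at peak SNR 10,
pooled vertex precision and recall at 2 px tolerance are above 0.99.

## Spot pairing

Object-based colocalization pairs spots across channels when their
centers are strictly closer than 0.4 µm (center-to-center; an
edge-to-edge convention is not offered). The matching rule is greedy
shortest-first under injectivity — deterministic, and at realistic
vesicle densities (well below one spot per pairing disk) identical to
the exhaustive optimal matching, which the test suite verifies by
enumeration on 500 instances of up to 8 spots per channel. The
colocalization fraction divides by the reference channel, which is
explicit in the API because swapping channels changes the denominator
but not the pair set. Manually rescued dim spots enter only through
`merge_supplementary_spots()`, which tags them and reports their count.

## Intensity profiles along junctions

`extract_junction_profile()` resamples each closed edge at pixel
resolution, averages intensity across a perpendicular band (default
6 µm, the 60-px line width at 0.1 µm/px), folds each arc position to
its distance from the nearer vertex `d = min(s, L−s)`, averages the two
fold arms within each line, then averages across lines; normalization
divides by the mean at distance 0, so the normalized curve starts at
exactly 1 and renormalizing is the identity. Reversing a polyline's
orientation changes nothing, because folding is symmetric and the
perpendicular band is sampled symmetrically. Aggregation across images
(`aggregate_profiles()`) supports both the unweighted image mean (the
default two-level convention) and line-count weighting.

One identifiability caveat drove a generator design decision: in any
image where junction *lines* converge at a vertex, the measured
intensity at distance 0 is geometrically inflated (three blurred
half-lines overlap), and for a decay length comparable to the line
width that excess is not separable from the decay itself.
`render_vertex_decay_image()` therefore paints the planted curve
`(1−r)·exp(−d/ℓ) + r` into a uniform 1.5 µm half-width junctional band
keyed to each pixel's along-junction vertex distance, so the
width-averaged profile equals the planted curve and recovery of
(ℓ, plateau ratio r) by `fit_profile_decay()` is a well-posed check
(recovered within 10% at ℓ = 3 µm, r = 0.4). For measured data the
same caveat means the first ~1 line-width of the empirical profile
mixes vertex accumulation with bicellular decay; `fit_profile_decay()`
accepts `d_min` to fit the bicellular part alone.

Region intensities follow the masking arithmetic of the imaging
workflow: 5 µm disks around vertices, clipped to a cell mask into
"pieces of a pie" where given, background subtracted (the background
source — untransduced cells or a no-primary region — is the caller's
stated choice); negative background-subtracted values are preserved,
not clipped. `colocalization_area_by_region()` intersects two
thresholded channel masks and reports the colocalized area percentage
within 5 µm of vertices versus the rest of the cell, with the
denominator convention (region area, or reference-mask area within the
region) explicit.

## Tracks: straightness, arrest, site classes

Straightness is net displacement over summed step lengths — 1 for a
straight path, 0 for a closed loop, invariant to rigid motions and time
rescaling, undefined (NA) for zero path length. Arrest uses the
temporal rule: some window of at least 450 s in which every position
stays within a radius R of the window's first point, or transmigration
before 450 s have elapsed. The 450 s dwell is an observed mean arrest
time; the spatial radius is not part of that definition, so R is an
explicit package parameter defaulting to 5 µm — the same
vertex-proximity scale the site classification uses — and the planted
arrest labels are recovered with ≥ 95% accuracy at localization noise
R/4 and 90 s frames. Site classes are `multicellular` within 5 µm of a
vertex, else `bicellular` within 2 µm of an edge midline (a junction
staining line is about that wide), else `non-junctional`; the explant
variant measures the along-junction distance and reports at / < 5 µm /
5–18 µm, flagging larger distances rather than classifying them.
Flow-carried objects are removed by a minimum-displacement filter
(default 10 µm per recording). Transmigration efficiency is the
per-replicate transmigrated fraction divided by the control-group mean,
so control efficiency is exactly 1.

## The testing scheme

`auto_compare_two_groups()` reproduces the normality-gated scheme:
Shapiro–Wilk per group (a Kolmogorov–Smirnov override exists because
one analysis historically used it); both groups passing at α = 0.05
selects the unpaired two-sided Welch t test, anything else the
two-sided Mann–Whitney U. The gate is applied per group and both must
pass — the conservative, deterministic reading. Constant groups, where
normality is undefined, fall to Mann–Whitney with a warning. Under a
Gaussian null at n = 50 the combined procedure's type-I error over
5000 replicates stays within [0.04, 0.06]. Categorical comparisons use
chi-squared without continuity correction, switching to Fisher's exact
test when any expected count is below 5 (the classical reading of "if
the sample size was small"); straightness distributions are first
binned at 0.1 into `[0, 0.1), …, [0.9, 1]`. ΔΔCt expression uses the
standard Livak formula, `100 · 2^−ΔΔCt`, after averaging technical
replicates; it is exactly invariant to per-sample additive Cq offsets
shared by target and reference gene. No multiple-testing correction is
applied anywhere, matching the reporting scheme the pipeline
accompanies.

## Numerical choices and problem sizes

Determinism is a contract: every sampler is a pure function of its
arguments and seed (RNG state is saved and restored), vertex ids are
ordered by position, nearest-vertex ties break to the lowest id, pair
ties break by spot ids, and an event equidistant from two edges goes to
the smaller arc distance. The test suite runs at desk scale by choice:
monolayers of 9–30 cells (16 cells in a 200 µm field for
decay-recovery checks, so edges are long relative to τ = 5 µm and the
exponential-mean estimator's truncation bias stays below the stated
tolerance), 20 seeds for reconstruction fidelity, 2000 spots / 1000
spots for the τ and colocalization recoveries, 5000 and 2000 replicates
for the statistical calibrations. The full suite, acceptance checks
included, completes in about a minute on one CPU.

## Known limitations

Graph extraction assumes 4-connected, gap-free labels; it does not
segment raw stained images beyond the bundled Otsu-plus-propagation
rebuild, and discontinuous (button-type) junctions are handled only as
externally supplied marker points. Spot detection is single-scale and
2-D. The arc distance is measured to the projection on the *nearest*
edge; for points perpendicular-equidistant between junctions at under
a band width this assignment, while deterministic, can differ from a
human's choice. Intensity-correlation colocalization (Pearson/Manders)
is intentionally out of scope, as are mixed-effects models of the
replicate hierarchy.
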