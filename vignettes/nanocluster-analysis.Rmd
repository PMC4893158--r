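---
title: "Quantifying receptor nanoclusters: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receptor nanoclusters: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoclustr)
```

Immune-cell receptors such as the paired killer Ig-like receptors of natural
killer cells are not spread uniformly over the plasma membrane: they sit in
nanometre-scale clusters whose size and packing differ between receptors and
change with signaling state. nanoclustr implements the quantitative pipeline
used to characterise such organisation from two complementary data types:

* **localization tables** from single-molecule localization microscopy
  (SMLM/GSDIM) — one row per detected fluorophore blink, with nanometre
  coordinates — analysed with second-order point-pattern statistics; and
* **two-channel super-resolution images** (STED-style, deconvolved) —
  analysed with intensity co-localization, cluster geometry, and a
  cluster-association statistic against a spatial-randomization null.

This vignette explains the statistical machinery, the tunable parameters,
and the design decisions taken where the underlying methods literature
leaves choices open. It also describes exactly what the built-in synthetic
data emulate, because every claim the test suite makes about the pipeline is
a claim about those synthetic conditions.

## Point-pattern statistics

### Ripley's K and L(r) − r

For `n` events in a window of area `A`, `ripley_k()` estimates

$$\hat K(r) = \frac{A}{n(n-1)} \sum_i \sum_{j \ne i} e_{ij}\,
  \mathbf 1(d_{ij} \le r),$$

with the isotropic (Ripley) edge correction: `e_ij` is the reciprocal of the
fraction of the circle of radius `d_ij` centred on event `i` that lies
inside the window. For a rectangle this fraction has an exact closed form —
the exterior arc is the union of up to four arcs, one per edge, each centred
on the outward normal with half-width `acos(distance/r)`; arcs of adjacent
edges may overlap at corners, arcs of opposite edges cannot overlap for an
interior point (`circle_in_window_fraction()`). The variance-stabilised
transform `L(r) = sqrt(K(r)/π)` gives `L(r) − r ≈ 0` under complete spatial
randomness (CSR); positive values measure clustering at scale `r`.
Isotropic correction is the standard choice for small rectangular membrane
ROIs; the implementation agrees with an independent reference implementation
to machine precision and with brute-force pair counting on interior
configurations.

Significance is judged against a Monte-Carlo envelope (`csr_envelope()`):
`n_sim` patterns of exactly `n` uniform points, with the pointwise central
`1 − α` quantile band of their `L(r) − r` curves. The envelope is pointwise,
not simultaneous — the usual convention when such bands are drawn as "99%
confidence intervals" around zero. The default `n_sim = 199` makes the
`α = 0.01` pointwise quantiles estimable.

### Getis–Franklin local L

`local_l()` scores each event by its own neighbourhood:

$$L_i(r_0) = \sqrt{\frac{A \sum_{j\ne i} e_{ij}\,\mathbf 1(d_{ij} \le r_0)}
  {\pi\,(n-1)}}.$$

The divisor is `n − 1`, so a self-pair never counts and the CSR expectation
of `L_i^2` is exactly `r_0^2`. Published variants divide by `n`; the
difference is negligible at study sizes but `n − 1` keeps the null
calibration exact. The default radius `r_0 = 30` nm is the conventional
scale for receptor nanocluster maps. Note that at membrane densities of
50–500 events/µm² the per-event neighbour count within 30 nm is a small
Poisson count, so the distribution of `L_i` under CSR is strongly discrete —
most events have zero neighbours and `L_i = 0`. Quantities that depend on
upper quantiles of this distribution are therefore meaningful; its median is
not, except at high density.

## From local L to nanoclusters

### Cluster maps

`build_cluster_map()` interpolates the per-event `L(r_0)` values onto a
regular grid (default `grid_step = 10` nm, well below `r_0`, so the grid
never limits resolution) by linear interpolation on the Delaunay
triangulation of event positions; pixels outside the convex hull are 0.
Linear triangulation interpolation is smooth, parameter-free, and the
standard choice in published local-L cluster-map workflows.

### Threshold calibration against density-matched randomness

Clusters are the 8-connected components of the map above a threshold, and
the threshold comes from randomized data with the same density of events
(`calibrate_threshold()`): `n_sim` null patterns are simulated, their local-L
values pooled, and the `quantile` (default 0.99) of the pooled values
returned. Two design choices deserve explanation.

**What is pooled.** We pool the *per-event* L values of the null patterns
rather than the interpolated map pixels. The two conventions differ
materially: events concentrate exactly where chance clumping drives L up, so
a threshold that marks 1% of CSR *pixels* admits roughly 8–10% of CSR
*events* into clusters, whereas the per-event quantile keeps the false
event-assignment rate at about `1 − quantile` (measured ≈ 0.2–0.6% at the
0.99 default, because the discreteness of the neighbour count makes the
threshold land just above an integer count). Controlling the event-level
error is what "percentage of events in clusters" statistics need; the pixel
convention remains available (`pool = "pixels"`) and is tested against its
own calibration property (≈ 1% of pixels marked).

**What the null is.** Plain CSR of the events themselves
(`mean_redetections = 1`, the default) is the classical null. It is,
however, too permissive for SMLM data in which each fluorophore is detected
several times: every multiply-detected background molecule is then a genuine
clump of 2–5 events within ~2 localization precisions, and these
pseudoclusters pass any CSR-events threshold in large numbers — a
well-known blinking artifact. When the re-detection statistics of the data
are known (or estimated), `calibrate_threshold(mean_redetections =,
sigma_loc =)` randomizes *molecule* positions and preserves blinking:
molecules are placed uniformly, re-detected a geometric number of times, and
each detection jittered by the localization noise. Clusters called against
this null exceed what blinking plus randomness produces. The pipeline
(`analysis_config(null_redetections =, null_sigma_loc =)`) exposes the same
choice.

### Binarization, labeling and summaries

`binarize_and_label()` uses strict `> threshold`, 8-connected components
(diagonal connectivity prevents round clusters from fragmenting), and a
minimum area of 300 nm² (3 pixels at the default grid) to suppress
single-pixel speckle. Events are assigned to the cluster whose pixel
footprint contains them — footprint containment, not nearest centroid, so an
event between two clusters is never force-assigned. Connected-component
labeling is authored here (two-pass union–find) because the available image
library labels 4-connected components only; the tests check it against an
independent breadth-first flood fill.

`summarize_clusters()` reports the per-ROI statistics conventional in this
field: median/mean cluster area, clusters per µm², percent of events in
clusters, relative in-cluster density (event density inside cluster
footprints over the overall ROI density), overall event density, and the
cluster-size fractions in the bins `[0, 5000]`, `(5000, 15000]`,
`(15000, ∞)` nm² — whose equivalent-circle diameters are 80 and 138 nm
(`area_to_diameter()`); the lower bin is closed above.

## Two-channel image analysis

### Costes–Pearson co-localization

`pearson_costes()` quantifies co-localization as a Pearson coefficient with
automatic thresholds: channel B is regressed on channel A by orthogonal
regression of the standardized channels (reduced major axis), and the
threshold pair slides down the regression line — bisection on the A
threshold — until the below-threshold pixels are uncorrelated (r ≤ 0). The
final coefficient uses mask pixels above threshold in either channel, the
convention of the widely used Coloc 2 implementation; `pixels = "all"` is
available. The reduced-major-axis slope (rather than the unstandardized
major axis) is deliberate: it makes the threshold pair — and hence the
coefficient — exactly equivariant under affine rescaling of either channel,
a property the unstandardized major axis does not have.

### Image clusters and centroid distances

`binarize_image_clusters()` thresholds deconvolved images inside the cell
mask — Otsu's method computed on the mask-pixel histogram (the full-frame
Otsu of standard image libraries would let background outside the cell move
the threshold), or an absolute threshold for calibrated synthetic tests —
then labels 8-connected components with intensity-weighted centroids.
`centroid_distances()` reports each cluster's nearest-neighbour centroid
distance to the partner channel and the per-cell median. When Otsu's
between-class variance has a flat maximum (an empty intensity valley), the
middle of the flat run is taken.

## The cluster-association statistic

The paper-level question is whether signaling-protein clusters sit near
receptor clusters more often than geometry alone predicts, and whether that
depends on receptor cluster size.

1. `assign_tertiles()` splits all receptor clusters of a cell into size
   tertiles (small/medium/large). Remainders go to the smallest bins first
   (7 clusters → 3/2/2); area ties break by input order.
2. `screen_association()` marks a receptor cluster *associated* when any
   pixel of any signaling cluster lies within `search_radius` of its
   centroid, and sums the signaling image over that circle ("nearby
   intensity"; summation over whole nearby clusters is available, since
   "intensity of clusters found nearby" is ambiguous between the two).
3. `randomize_null()` translates each signaling cluster's rigid pixel
   footprint (with its intensity patch) to a uniform random position fully
   inside the cell mask — rejection sampling on the anchor pixel — and
   re-screens. Footprint count, shapes and areas are preserved exactly;
   randomized clusters may overlap each other, the simplest null consistent
   with "positions randomized within the cell area" (an exclusion rule
   would smuggle in an interaction model).
4. `size_effect_summary()` tabulates observed versus null-mean association
   per tertile.

The `search_radius` has no canonical value in the methods literature; it
defaults to 500 nm, is mandatory in the sense that every output records it,
and results should always be reported together with it. With centroid-based
screening, chance association is essentially independent of receptor
cluster size — for point-like signaling clusters in an unclipped window it
follows the closed form `1 − (1 − πR²/A)^m`, which the tests verify by
Monte Carlo. The empirical size dependence of chance association seen in
real data arises when the screen is measured from the cluster *edge*;
`mode = "edge"` implements that variant (the search circle then effectively
grows with the cluster), and is the mechanism by which large clusters are
inherently more likely to contact independently placed signaling clusters.

## Nonparametric group comparisons

`mann_whitney()` uses the exact rank-sum distribution when both groups have
at most 8 observations and no ties, otherwise the tie-corrected normal
approximation with continuity correction; identical constant groups return
p = 1. `kruskal_dunn()` and `friedman_dunn()` follow the global rank tests
with Dunn's pairwise z statistics (tie-corrected for Kruskal–Wallis;
`z = (R_i − R_j)/\sqrt{nk(k+1)/6}` for Friedman) under Bonferroni
adjustment over the compared pairs — the conventional reading of "Dunn's
post-test" when no adjustment is named. A fully tied Friedman matrix
returns statistic 0 and p = 1 rather than the 0/0 of the tie-corrected
formula. Simulated type-I error for all three tests at the study's sample
sizes (20 + 20; 3 × 25; 25 × 3) is within [0.035, 0.065] at α = 0.05.

## What the synthetic data emulate

`simulate_smlm()` generates the latent structure the localization pipeline
assumes: molecules in tight clusters over a uniform background, geometric
re-detection of every molecule (memoryless blinking, mean 2 detections),
and independent Gaussian localization noise (σ = 20 nm) on every detection.
Defaults place ~200 events/µm² in a 3 × 3 µm window with ~30% of events in
clusters — the regime of receptor nanocluster fields.

Two deliberate design choices:

* **Cluster shape.** Default clusters are uniform discs, so each cluster
  has the unambiguous true area `πr²`; a Gaussian option exists (with the
  conventional 2σ-footprint area `π(2σ)²`), but a Gaussian has no true
  edge, and the measured contour area of a Gaussian cluster depends
  strongly on its peak density — a poor target for parameter-recovery
  tests.
* **In-cluster density.** The default in-cluster event density
  (`7.8 × 10⁻³` events/nm², ~22 events within an `r_0` disc) is far above
  the calibrated threshold. This is the regime real antibody-labeled,
  blinking-inflated nanoclusters occupy, and it is what makes cluster
  detection a property of geometry rather than shot noise: the footprint
  edge is then set by the true disc edge blurred by localization noise,
  and the threshold contour sits near the half-maximum of that blurred
  edge, i.e. near the true radius. At substantially lower contrast the
  per-event neighbour counts fluctuate across the threshold and footprints
  fragment — an estimator property worth knowing about, not a bug.

Under the default conditions, recovered median areas for true 6,000 and
15,000 nm² regimes carry a mild positive bias (~+15%, within the 25%
recovery band the tests assert) and order correctly in every tested seed
pair. The generator does **not** model camera noise, realistic
photoswitching kinetics, drift, or 3-D effects; conclusions from the test
suite are about the estimator under the stated latent model, not about any
specific instrument.

`simulate_two_channel()` renders per-channel uniform discs inside an
elliptical cell mask (`make_cell_mask()`), convolves with a Gaussian PSF
(FWHM 80 nm, pixel 20 nm), and applies Poisson noise over a constant
background. Channel-B discs are displaced from their channel-A partners by
a configurable offset in a random direction — 0 nm emulates a same-protein
positive control, 150–300 nm the juxtaposed/segregated regimes. Recovered
Pearson coefficients are ~0.95 at offset 0 and ~0 at offset 300; the real
positive control/segregated contrast (medians 0.77 vs ≈ −0.2) is smaller
because real images carry uncorrelated background structure the generator
does not emulate — only the ordering is a transferable claim.

## Numerical conventions and determinism

* Continuous coordinates are in nm with the origin at the window's lower
  left; grids are `[ix, iy]` matrices whose pixel (1, 1) covers
  `[0, pixel_size)²`. TIFF I/O converts to and from the top-left raster
  convention, with intensity scale and pixel size in a JSON sidecar.
* ROI cropping is half-open (`[x0, x0 + w)`), consistent with grid binning.
* Binarization is strict (`> threshold`); the association screen is
  inclusive (`≤ search_radius`).
* All stochastic functions take an explicit integer seed, record it in
  their output, and are bit-reproducible given it; `analyze_*` derive
  per-stage seeds from `analysis_config(seed =)` and serialized results
  embed the full configuration (`write_results()`), so identical runs give
  byte-identical JSON.
* Test-suite problem sizes are scaled to what the properties need:
  calibrations pool 20–50 null simulations, recovery uses 10 seeds per
  regime, the association null uses 250 replicates, and the type-I study
  2,000 replicates per test.

## Known limitations

Absolute cluster statistics from local-L maps are sensitive to the search
radius, threshold convention and interpolation — they are comparable within
a pipeline, indicative across pipelines. The ~+15% area bias at default
conditions is part of that. Centroid-based association screening cannot by
itself produce size-dependent chance association; use `mode = "edge"` when
that mechanism is the question. The Mann–Whitney exact path is limited to
small untied samples; elsewhere the normal approximation is used. The
randomization null treats signaling clusters as independent rigid bodies;
correlated placements (e.g. mutual exclusion) are out of scope.
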