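# nanoclustr

Quantitative analysis of receptor nanoclusters from super-resolution
microscopy, for cell biologists and microscopists working with
single-molecule localization data (SMLM/GSDIM localization tables) and
two-channel super-resolution images (STED-style).

Immune receptors such as the paired killer Ig-like receptors sit in
nanometre-scale membrane clusters whose size and packing carry biological
meaning. nanoclustr implements the standard quantification pipeline for
this kind of data:

* **Point-pattern statistics** — Ripley's
  `K̂(r) = A/(n(n−1)) ΣΣ e_ij 1(d_ij ≤ r)` with exact isotropic edge
  correction, the clustering curve `L(r) − r`, Monte-Carlo envelopes under
  complete spatial randomness, and per-event Getis–Franklin local
  `L_i(r_0) = sqrt(A Σ e_ij 1(d_ij ≤ r_0) / (π(n−1)))` (default
  `r_0 = 30` nm).
* **Cluster maps** — local-L values interpolated on a 10 nm grid,
  binarized at a threshold calibrated on density-matched randomized data
  (with an optional blinking-matched null for multiply-detected
  fluorophores), 8-connected components as nanoclusters, and the standard
  per-ROI summaries: median area, clusters/µm², percent of events in
  clusters, relative in-cluster density, size-bin fractions at 5,000 and
  15,000 nm² (equivalent-circle diameters 80 and 138 nm).
* **Co-localization** — Pearson coefficients with Costes auto-thresholds
  (reduced-major-axis regression + bisection), masked Otsu binarization of
  deconvolved images, intensity-weighted centroids and nearest-centroid
  distances.
* **Cluster association** — screening a circular area around each receptor
  cluster centroid for signaling clusters, conditioned on receptor-size
  tertiles, against a null that rigidly re-places signaling-cluster
  footprints uniformly within the cell mask.
* **Group statistics** — Mann–Whitney, Kruskal–Wallis and matched-values
  Friedman tests with Bonferroni–Dunn post-tests.
* **Synthetic data with known truth** — clustered localization tables
  (disc or Gaussian clusters, geometric re-detections, localization noise)
  and paired two-channel images with controllable inter-channel offsets,
  so the whole pipeline is testable without any external data.

Everything is tibble-first: analysis functions take data frames, return
tibbles, and chain with the pipe; fitted objects have `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

Simulate an SMLM field at the default study conditions (3 × 3 µm window,
~200 events/µm², ~30% of events in dense disc-shaped clusters of true area
6,000 nm², geometric re-detections with mean 2, 20 nm localization noise)
and run the localization pipeline with a blinking-matched threshold null:

```r
library(nanoclustr)

sim <- simulate_smlm(seed = 42)
cfg <- analysis_config(threshold_n_sim = 20, null_redetections = 2,
                       null_sigma_loc = 20, seed = 1)
cell <- analyze_gsd_cell(sim$points, roi(), cfg)
glance(cell)
#> # A tibble: 1 × 11
#>   n_clusters median_area mean_area clusters_per_um2 percent_in_clusters
#> 1         13        7600     6685.             1.44                26.9
#>   relative_density event_density frac_small frac_mid frac_large n_rois
#> 1             27.9           205      0.231    0.769          0      1
```

The recovered median cluster area (7,600 nm²) sits close to the generator's
truth (6,000 nm²); about 27% of events fall in clusters, matching the
generated fraction. For the image side, simulate a segregated two-channel
pair (channel-B discs displaced 250 nm from their channel-A partners) and
run the STED pipeline:

```r
tc <- simulate_two_channel(n_spots = 10, offset = 250, seed = 42)
sted <- analyze_sted_cell(tc$img_a, tc$img_b, tc$mask,
                          analysis_config(n_null_reps = 100, seed = 1,
                                          sted_min_area = 2000))
glance(sted)
#> # A tibble: 1 × 5
#>   pearson_r median_centroid_distance n_receptor n_signaling frac_associated
#> 1    -0.913                     249.         10          10               1
```

The Costes–Pearson coefficient is strongly negative (segregated channels)
and the median nearest-centroid distance recovers the configured 250 nm
offset. `sted$size_effect` compares observed per-tertile association
against the randomization null — here the channels were placed with a fixed
offset, so observed fractions sit inside the null band:

```r
sted$size_effect
#> # A tibble: 3 × 7
#>   tertile observed_frac null_frac frac_difference observed_p null_p ...
#> 1 small             0.4     0.410        -0.0101           1  0.74
#> 2 medium            0.3     0.288         0.0115           1  0.69
#> 3 large             0.3     0.301        -0.00143          1  0.727
```

A thin command-line wrapper (`inst/scripts/nanoclust.R`) exposes the same
pipelines as `gsd`, `sted`, `simulate` and `stats` subcommands for shell
use.

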