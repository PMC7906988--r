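# placefields

Analysis of hippocampal CA1 place coding from two-photon calcium imaging of
head-fixed mice navigating air-floating real-world environments — a circular
track (outer diameter 32.5 cm, lane width 5 cm) or a circular open arena.
The package is written for systems neuroscientists who have already run
their imaging through motion correction, ROI segmentation and spike
deconvolution: its inputs are a position-tracking series (~100 Hz) and a
deconvolved calcium-transient event train (frames x cells, non-negative
dF/F amplitudes at ~30 Hz), and its outputs are place-cell classifications,
field metrics, cross-session stability and remapping statistics, lap-to-lap
reliability exponents, and a neural-manifold embedding with position
decoding. A first-class synthetic-data generator reproduces the behavior
and cell statistics the analysis assumes, so the entire pipeline is testable
without recordings.

## What it computes

* **Behavior**: tracking aligned to imaging frames, strict speed gating at
  20 mm/s, circular-track linearization via the known circumference, lap
  segmentation on net forward progress, open-field coverage.
* **Rate maps**: occupancy-normalized activity-rate maps (2-cm bins;
  circular 3-bin boxcar smoothing in 1D, Gaussian sigma = 1.5 bins in 2D,
  both mass-preserving over valid bins), normalized by the smoothed maximum;
  per-lap rate matrices.
* **Place cells**: Skaggs spatial information in bits/event,

  `I = sum_i p_i (lambda_i / lambda_bar) log2(lambda_i / lambda_bar)`,

  a 1,000-shuffle time-stamp permutation null with a 99th-percentile chance
  criterion, and the track criteria — field events on at least half the
  laps, events in at least 5% of moving in-field frames (2% in the open
  field), information above chance. Field location is the argmax bin; field
  size counts bins at or above half maximum; 2D fields are thresholded at
  0.5 of the normalized map with rate-weighted centroids.
* **Stability and remapping**: recurrence, field correlation and circular
  field shift across session pairs; cross-environment map correlations,
  location retention, and the Hodges–Ajne test of circular uniformity of
  field shifts (exact tail `(n - 2m) C(n, m) 2^(1-n)` for small `m`).
* **Reliability**: per-cell lap-to-lap variance vs mean per spatial bin,
  fitted with `var = a * mean^beta` by total least squares in log-log space;
  `beta = 1` is Poisson-like reliability. Activity-rate summaries use a 90%
  log-normal (Cox) confidence interval.
* **Manifold and decoding**: classical MDS on cosine dissimilarities of
  population vectors, dimensionality at 90% variance, and an optimal linear
  estimator decoding angular position via (cos, sin) targets under blocked
  five-fold cross-validation.

## Worked example

Simulate a 10-minute track session with 20 tuned and 20 untuned cells, run
the full pipeline, and inspect one cell:

```r
library(placefields)

cfg <- sim_config(duration_s = 600, n_place_cells = 20, n_untuned_cells = 20,
                  rng_seed = 1)
res <- run_pipeline(cfg, n_shuffles = 200, manifold_max_frames = 800)
res
#> <pipeline_results> 1 session(s)
#>   classification summary:
#>  session environment day n_cells n_place_cells sensitivity false_positive_rate
#>        1           A   1      40            20           1                   0
#>  running_fraction
#>         0.8965613
#>   decoding r: 0.558

res$classification[[1]]$stats[[1]]
#> <place_cell_stats> cell 1 (1d): PLACE CELL
#>   I = 1.140 bits/event, percentile 100.0
#>   c1 laps: TRUE  c2 field occupancy: TRUE  c3 information: TRUE

res$classification[[1]]$stats[[1]]$field
#> <place_field 1d> location 37.0 cm, size 18.0 cm (9 bins)
```

All 20 simulated place cells are recovered and none of the untuned cells is
classified as a place cell. Cell 1 carries 1.14 bits/event of spatial
information, beats all 200 shuffles, and has an 18-cm field centered 37 cm
along the track. The decoding correlation (r = 0.56 from 3 manifold
components of a noisy 40-cell population) rises toward 1 with larger, less
noisy populations; `vignette("place-coding-pipeline")` explains each stage,
its parameters and the design choices.

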