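---
title: "Place-coding analysis for floating-track calcium imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Place-coding analysis for floating-track calcium imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placefields)
```

# Scope

`placefields` implements the downstream analysis of hippocampal CA1 place
coding for head-fixed mice navigating air-floating environments: a circular
track (outer diameter 32.5 cm, lane width 5 cm) and a circular open arena of
the same outer diameter. The package consumes two inputs — a position
tracking series at ~100 Hz and a deconvolved calcium-transient event train
(frames x cells, non-negative dF/F amplitudes) at the ~30 Hz imaging rate —
and produces place-cell classifications, field metrics, cross-session
stability and remapping statistics, lap-to-lap reliability exponents, and a
low-dimensional population embedding with position decoding. A synthetic-data
generator produces behavior and cell populations with the statistical
structure the analysis assumes, so every stage is verifiable without
recordings.

Upstream image processing (motion correction, ROI segmentation, neuropil
decontamination, deconvolution, cross-session ROI registration) is out of
scope; the event train is the package's contract with that stage.

# From behavior to rate maps

**Alignment.** Tracking is linearly interpolated onto the imaging frame
times; speed is recomputed from the interpolated positions by central
differences and smoothed with a 5-frame running median. The median width is
a robustness choice against single-sample tracker glitches; the analysis
gates on this smoothed series (whether the gate should apply to raw or
smoothed speed is genuinely open; smoothed is the stabler choice and the two
differ only at bout edges). Tracking gaps longer than 0.5 s mark the
overlapped frames invalid, and invalid frames are excluded from every map.

**Speed gating.** Only frames with speed strictly above 20 mm/s enter any
spatial analysis, removing reward pauses and grooming. The inequality is
strict: a frame at exactly 20 mm/s is excluded.

**Linearization and laps.** Track position is linearized as
`distance = angle / 360 x circumference`. The circumference defaults to the
annulus midline, `pi x (325 - 50) mm ~ 86.39 cm`, because the animal's body
occupies the lane center on average; it is configurable wherever it enters.
The unwrapped cumulative distance accumulates the minimal signed angular
step, so brief backward motion subtracts. A lap boundary falls each time
cumulative distance first advances one full circumference past the previous
boundary; backward excursions never remove a boundary, so laps accrue only
on net forward progress. The final partial lap is kept but flagged, and all
per-lap statistics use complete laps only.

**Rate maps.** 1D maps use 2-cm bins (`round(C / 2) = 43` bins; the last bin
absorbs the rounding remainder). The activity rate of a bin is the summed
event amplitude during occupancy divided by occupancy time (dF/F per s); the
event rate (events/s) is kept alongside. Maps are smoothed with a circular
three-bin boxcar — the track is a loop, so smoothing wraps — and normalized
by the smoothed maximum (smoothing before normalization). 2D maps use
2 x 2 cm bins masked to the arena disc and a Gaussian kernel with
sigma = 1.5 bins (3 cm; the smoothing scale is interpreted in bins, matching
the binned-map convention). Two numerical choices matter here:

* Smoothing is implemented in *scatter* (transpose) form: every valid source
  bin distributes its rate over its valid neighbors with kernel weights
  renormalized per source. This is identical to ordinary convolution when
  all bins are valid, conserves total rate mass over valid bins to machine
  precision, and avoids attenuation at mask edges.
* Unvisited bins propagate as missing (`NA`), never as zeros, through
  smoothing, correlations and information.

Per-lap maps accumulate the same quantities within each lap; bins unvisited
within a lap are missing for that lap. The occupancy-weighted mean of the
lap rows reconstructs the session map exactly (this is asserted at 1e-9 in
the tests).

# Place-cell classification

**Spatial information** is the Skaggs rate `I = sum_i p_i (l_i / L) log2(l_i / L)`
bits/event, with `p_i` occupancy probability, `l_i` the bin rate, and
`L = sum_i p_i l_i`. It is computed from the *raw* (unsmoothed) rates over
valid bins — smoothing would leak information across bins before the
statistic is taken — and from the amplitude-weighted map by default (the
event train is amplitude-marked; an events-only mode is available).

**Chance level** comes from 1,000 shuffles of the cell's activity time
stamps: each shuffle permutes the per-frame activity values across the
moving frames, conserving event count and amplitudes, and the information is
recomputed. The percentile is the fraction of null values strictly below the
observed information. The implementation places the nonzero amplitudes on a
uniform random subset of moving frames, which is distributionally identical
to a full permutation (a permutation restricted to its nonzero support) but
costs O(events) per shuffle rather than O(frames); the equivalence is tested
against an explicit full-permutation oracle. A circular-rotation null is
available by option for users who prefer a null that preserves the
autocorrelation of the event train.

**Criteria.** On the track a place cell must satisfy all three of:

1. events present on at least half of the complete laps — read as at least
   one event *inside the detected field* during the lap (fields are reliable
   but not expressed on every traversal; a whole-lap mode is available);
2. events present in at least 5% of the moving time bins spent inside the
   field, where "time bins" are imaging frames;
3. spatial information exceeding the 99th percentile of the shuffle null.

In the open field criterion 2 uses a 2% threshold and criterion 1 does not
apply (classification is information + field-occupancy only). All criteria
are evaluated against the field detected from the full-session smoothed map;
no provisional field is defined. Field location is the bin of maximum
smoothed rate (ties break to the lowest index and are flagged); field size
is the number of bins at or above 50% of the maximum times the bin width,
without a contiguity requirement. In 2D the field is the set of bins with
normalized rate above 0.5, the centroid is their rate-weighted mean, and
disconnected member sets are flagged multimodal.

# Stability and remapping

For a pair of sessions over a shared (registered) cell index the package
reports: recurrence (the fraction of cells holding a classification in the
first session that hold it in the second — deliberately directional),
field correlation (mean Pearson correlation of normalized smoothed maps over
cells classified in both sessions, restricted to bins valid in both), and
the circular field shift. Cross-environment remapping additionally reports
the mean map correlation over all common active cells, the fraction of
common place cells retaining their location, and the Hodges–Ajne test of
circular uniformity of the shifts. "Retained location" has no canonical
threshold; the default is a circular shift within one 2-cm bin,
configurable.

The Hodges–Ajne statistic `m` is the minimum number of observations in any
closed half-circle. The count of a closed half-circle is piecewise constant
as it rotates, with breakpoints at the data angles and their antipodes, so
the sweep evaluates the breakpoints and the midpoints between consecutive
breakpoints; this is exact, and is tested against brute-force enumeration.
For `m < n/3` the exact tail probability `(n - 2m) C(n, m) 2^(1-n)` is used;
otherwise the large-sample approximation
`p = sqrt(2 pi) / A exp(-pi^2 / (8 A^2))`, `A = pi sqrt(n) / (2(n - 2m))`,
clipped to [0, 1].

# Lap-to-lap reliability

For each cell, the per-lap per-bin activity rates give, per bin, a mean and
an unbiased variance across the laps that visited the bin (at least two
visits required; zero-mean bins are excluded before the log transform since
the log is undefined there). A power law `var = a x mean^beta` is fitted by
total least squares in log-log space: the slope of the first principal
direction of the centered scatter, with the intercept through the centroid.
TLS rather than ordinary regression because both axes are estimates from the
same laps; ordinary least squares on `log var | log mean` is attenuated by
the noise in the abscissa (shown side by side in the tests). `beta = 1`
corresponds to Poisson-like reliability; larger exponents indicate extra
trial-to-trial variability. The variance-mean points pool all valid bins of
the track — the relation is meant to span the rate range the animal's
progress through the field produces — rather than in-field bins only.

Activity-rate summaries report per-group means with standard errors for
event rates, and for activity rates — which are approximately log-normal
across cells, so a symmetric interval would be wrong — the log-normal mean
with its 90% confidence interval by Cox's method
(`exp(m + s^2/2)` with limits `m + s^2/2 -/+ z sqrt(s^2/n + s^4/(2(n-1)))`
on the log scale). Coverage of this interval is verified by simulation.

# Population manifold and decoding

The population matrix holds the moving-frame activity vectors. Frames on
which no cell fired are dropped before the cosine distance (the angle to a
zero vector is undefined); their count is logged on the object. Classical
MDS double-centers the squared cosine dissimilarities and eigendecomposes;
component time courses are eigenvectors scaled by the square roots of their
eigenvalues. Cosine distance makes the embedding invariant to global
amplitude scaling, which is the right invariance for dF/F units calibrated
only up to a per-session factor. Variance explained is computed over the
positive eigenvalues only; negative eigenvalues (the cosine matrix is not
Euclidean-embeddable in general) are retained on the object for inspection
but carry no variance. Manifold dimensionality is the smallest number of
components reaching 90% cumulative variance. A PCA backend sits behind the
same interface for comparison.

Decoding uses an optimal linear estimator — least squares with intercept —
from the first `n_dims` components to `(cos, sin)` of the angular position,
under five-fold cross-validation. Folds are contiguous temporal blocks by
default: neighboring frames are strongly autocorrelated, and random-frame
folds would leak training information into the test sets (a random-frame
mode exists). Performance is the mean Pearson correlation of predicted and
true cosine and sine over held-out frames, decoded angle by `atan2`; the
circular correlation of decoded and true angle is also reported. The
cos/sin parameterization avoids the wrap discontinuity a direct regression
on angle would suffer.

# The synthetic generator: what it emulates

The generator's defaults describe the study conditions the analysis expects.

**Behavior.** Circular-track running is forward angular motion on the lane
midline with an AR(1) speed process (mean 100 mm/s, SD 30 mm/s, 1-s
relaxation, clipped at 250 mm/s — mice run up to ~200 mm/s on this
apparatus), exponentially timed pauses (rate 0.05 /s, mean 2 s), and a small
frozen-while-paused radial wobble inside the lane. These defaults complete
well over 100 laps in a 45-minute session. Open-field behavior is a
persistent random walk: Ornstein–Uhlenbeck-style heading diffusion
(1.6 rad/sqrt(s)), reflection at the wall, and a mild tangential bias in the
outer 6-cm band. The walk covers more than 90% of the 2 x 2 cm in-arena
bins in 45 minutes, and spends roughly 55–60% of its time in the outer 6 cm
— close to the ~60% that uniform coverage of the disc implies by area, and
to what the mice do.

**Cells.** Tuned cells follow a circular Gaussian (von Mises-like) tuning
curve on the track, parameterized by center and full width at half maximum
(default 80 degrees ~ 19 cm, matching the scale of measured field sizes), or
an isotropic 2D Gaussian in the arena (FWHM 148 mm, chosen so the area above
half maximum is ~172 cm^2). Tuning curves are truncated below 1% of peak so
fields have finite support. The peak rate default of 5 events/s is derived
from session-scale numbers: place cells emit ~1 event/s averaged over a
session in which the field occupies roughly a quarter of the running time,
implying in-field rates of several events per second. Background rate is
0.05 events/s; untuned cells fire uniformly at 0.45 events/s (the scale of
non-place-cell rates); homogeneous Poisson controls default to 1 event/s.
Event amplitudes are log-normal (meanlog 0, sdlog 0.5) in dF/F units.
Events are drawn per frame as Bernoulli with `p = rate / frame_rate`, which
is an adequate Poisson thinning because rates are far below the 30 Hz frame
rate. Lap-to-lap unreliability is a per-lap Bernoulli gate on the tuned
component with default probability 0.72 (place cells are active on ~72% of
laps); there is no quantitative model of this in the literature the package
follows, so the gate is the simplest mechanism producing the observed
marginal.

**Studies.** Field centers are drawn uniformly (angle, or area-uniform in
the disc). Centers are shared within an environment; with `remap = TRUE`
each distinct environment label receives independent centers, which makes
cross-environment field shifts uniform by construction. Within an
environment, centers may drift day to day by a Gaussian step (default 0).
Cell participation after the first session is Bernoulli with the recurrence
probability (default 0.9).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: calcium indicator dynamics (rise/decay kernels,
shot noise; the generator emits deconvolved events directly), theta-phase
or speed modulation of firing, multi-peaked or directional fields, border
cells, slow within-session representational drift, and deconvolution
artifacts such as merged or split events. Results on real recordings depend
on the upstream processing meeting the event-train contract.

# Calibration of the Poisson reliability anchor

The package's headline calibration simulates 50 homogeneous Poisson cells
(1 event/s, unit amplitudes) over 100 complete constant-speed laps and
checks that the mean TLS exponent is 1. The constant speed is set to
200 mm/s, the apparatus's top running speed. This choice is substantive,
not cosmetic: for a homogeneous cell the per-bin mean is flat, so the
log-log scatter is pure estimation noise, and the TLS slope of that scatter
depends on the expected event count per bin-lap. With `a = rate x bin time`
events per bin-lap, the log-mean axis has variance `~1/(Ka)` over `K` laps
while the log-variance axis has an additional floor `~2/K` from the
sampling variance of a variance; as `a` grows the scatter becomes
vertically elongated and the principal axis steepens above 1 (empirically
~1.4 at 50 mm/s, ~1.14 at 100 mm/s, ~1.01 at 200 mm/s). At 200 mm/s a bin
holds ~0.1 expected events per lap — the sparse-count regime that CA1
calcium event trains actually occupy — and there the Poisson exponent is
recovered. The calibration is therefore run in the regime the method is
meant for, and the sensitivity of the estimator outside it is a documented
property, not a defect of the fit.

# Problem sizes and determinism

The test suite and the acceptance script run end-to-end at desk scale:
30-minute simulated sessions (54,000 frames) for classifier recovery with
200 cells, 200-shuffle nulls in the routine suite (the chance criterion
itself is defined at 1,000 shuffles and the shuffle count is a parameter),
embeddings capped at 800–2,000 frames by even subsampling, and 100-lap
reliability calibrations. These sizes were chosen so the full pipeline
exercises every code path in about a minute per stage while keeping
Monte-Carlo margins comfortable.

All randomness flows from explicit integer seeds through a deterministic
sub-seed derivation, so identical configuration and seed reproduce
bit-identical output; the pipeline records a seed manifest alongside its
results.

# Known limitations

* The backward within-session field shift seen in some cells is exposed
  only as the per-lap map matrix; no statistic is defined for it.
* 1D fields are not split into sub-fields, and clockwise/counter-clockwise
  running is not separated.
* The open-field classification has no lap-analogue criterion; single
  transient bursts are guarded against only by the 2% occupancy rule.
* Recurrence is estimated per session pair; no decay model is fitted over
  day intervals.
* Session I/O uses CSV with a JSON metadata sidecar; matrices are written
  at full precision so round trips are exact, but files are larger than a
  binary container would be.
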