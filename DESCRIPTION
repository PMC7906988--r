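Package: placefields
Title: Place-Cell Analysis for Calcium Imaging in Floating-Track Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of hippocampal CA1 place coding from
    deconvolved calcium-transient event trains and position tracking on
    air-floating circular tracks and open arenas. Aligns 100 Hz tracking to
    ~30 Hz imaging frames, linearizes circular-track position, builds
    occupancy-normalized activity-rate maps (2-cm bins, circular boxcar or 2D
    Gaussian smoothing), computes Skaggs spatial information in bits/event,
    classifies place cells against a 1,000-shuffle chance criterion, measures
    cross-session recurrence, field correlation and circular field shift
    (including the Hodges-Ajne test of circular uniformity), fits lap-to-lap
    variance-mean power laws by total least squares, and embeds population
    activity with cosine-dissimilarity classical multidimensional scaling
    followed by optimal-linear-estimator position decoding under five-fold
    cross-validation. A synthetic-data generator emulates floating-track
    behavior and tuned, untuned and Poisson cell populations so that every
    stage is testable without experimental recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
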