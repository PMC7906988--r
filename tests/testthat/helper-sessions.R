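# Fixtures are built in code: small hand-constructed sessions give exact
# control over occupancy and event placement for oracle tests, while the
# package's own generator supplies realistic populations.

# Circular-track session constructed directly from a cumulative-distance
# series (cm) and an activity matrix, bypassing tracking interpolation so
# occupancy and bin membership are exact.
make_track_session <- function(cumulative_cm, activity,
                               circumference_cm = pi * 27.5,
                               frame_rate_hz = 30,
                               speed_mm_s = NULL) {
  n <- length(cumulative_cm)
  activity <- as.matrix(activity)
  stopifnot(nrow(activity) == n)
  if (is.null(speed_mm_s)) speed_mm_s <- rep(100, n)
  pos <- cumulative_cm %% circumference_cm
  theta <- pos / circumference_cm * 360
  r <- circumference_cm * 10 / (2 * pi)
  s <- list(
    frame_times = (seq_len(n) - 1) / frame_rate_hz,
    x_mm = r * cos(theta * pi / 180),
    y_mm = r * sin(theta * pi / 180),
    theta_deg = theta,
    speed_mm_s = speed_mm_s,
    moving = speed_mm_s > 20,
    valid = rep(TRUE, n),
    running_fraction = mean(speed_mm_s > 20),
    activity = activity,
    n_cells = ncol(activity),
    frame_rate_hz = frame_rate_hz,
    arena = "circular_track",
    environment = "A", day = 1L,
    speed_threshold_mm_s = 20,
    circumference_cm = circumference_cm,
    position_cm = pos,
    cumulative_cm = cumulative_cm,
    laps = segment_laps(cumulative_cm, circumference_cm)
  )
  class(s) <- "aligned_session"
  s
}

# n_laps uniform laps with frames_per_bin frames in each 2-cm bin
uniform_lap_session <- function(n_laps, frames_per_bin, activity,
                                circumference_cm = 86, bin_size_cm = 2) {
  nb <- round(circumference_cm / bin_size_cm)
  per_lap <- nb * frames_per_bin
  # frame f sits strictly inside bin floor(offset / bin) via mid-step offsets
  offs <- (seq_len(per_lap) - 0.5) / per_lap * circumference_cm
  cum <- rep(seq_len(n_laps) - 1, each = per_lap) * circumference_cm +
    rep(offs, n_laps)
  make_track_session(cum, activity, circumference_cm = circumference_cm)
}

# bare ratemap_1d object for field-detection oracles
manual_map_1d <- function(smoothed, valid = rep(TRUE, length(smoothed)),
                          bin_size_cm = 2) {
  nb <- length(smoothed)
  structure(list(
    n_bins = nb, bin_size_cm = bin_size_cm,
    bin_edges_cm = seq(0, nb) * bin_size_cm,
    bin_centers_cm = (seq_len(nb) - 0.5) * bin_size_cm,
    circumference_cm = nb * bin_size_cm,
    occupancy_s = rep(1, nb), raw_rate = smoothed,
    event_rate = smoothed, smoothed_rate = smoothed,
    normalized_rate = smoothed / max(smoothed[valid]),
    valid = valid, all_zero = all(smoothed[valid] == 0), cell = 1L
  ), class = "ratemap_1d")
}

# bare ratemap_2d object on an n x n grid (all bins in-arena and valid)
manual_map_2d <- function(smoothed_matrix, bin_size_cm = 2) {
  n <- nrow(smoothed_matrix)
  centers <- (seq_len(n) - (n + 1) / 2) * bin_size_cm
  structure(list(
    n = n, bin_size_cm = bin_size_cm, sigma_bins = 1.5,
    arena_radius_cm = n * bin_size_cm / 2,
    bin_centers_cm = centers,
    center_x = matrix(rep(centers, times = n), n, n),
    center_y = matrix(rep(centers, each = n), n, n),
    occupancy_s = matrix(1, n, n),
    raw_rate = smoothed_matrix, event_rate = smoothed_matrix,
    smoothed_rate = smoothed_matrix,
    normalized_rate = smoothed_matrix / max(smoothed_matrix),
    valid = matrix(TRUE, n, n), in_arena = matrix(TRUE, n, n),
    all_zero = all(smoothed_matrix == 0), cell = 1L
  ), class = "ratemap_2d")
}

# brute-force minimum half-circle count over a dense sweep of directions
brute_force_ajne_m <- function(th, step = 0.01) {
  th <- th %% 360
  anchors <- seq(0, 360 - step, by = step)
  min(vapply(anchors, function(a) sum(((th - a) %% 360) <= 180), 0))
}

# noiseless tuned-population session (expected rates as activity)
noiseless_session <- function(cfg) {
  traj <- simulate_trajectory(cfg)
  erm <- expected_rate_matrix(cfg, traj)
  aligned_session(
    traj, erm$rates, arena = cfg$arena,
    circumference_cm = if (cfg$arena == "circular_track")
      arena_geometry(cfg)$circumference_cm else NULL,
    frame_times = erm$frame_times)
}

# cells tiling a ring, evaluated along a constant-speed angular sweep
ring_population <- function(n_cells = 64, n_frames = 1500, n_laps = 6,
                            fwhm_deg = 80) {
  th <- (seq_len(n_frames) - 1) / n_frames * n_laps * 360
  th <- th %% 360
  centers <- seq(0, 360, length.out = n_cells + 1)[-(n_cells + 1)]
  kappa <- log(2) / (1 - cos(fwhm_deg / 2 * pi / 180))
  X <- vapply(seq_len(n_frames), function(t)
    exp(kappa * (cos((th[t] - centers) * pi / 180) - 1)), numeric(n_cells))
  list(X = X, theta = th)
}


# rank correlation between an embedding angle and the true track angle,
# aligned at the origin and checked under reflection
embedding_rank_correlation <- function(phi_deg, theta_deg) {
  phi_a <- (phi_deg - phi_deg[1]) %% 360
  th_a <- (theta_deg - theta_deg[1]) %% 360
  max(abs(stats::cor(phi_a, th_a, method = "spearman")),
      abs(stats::cor((360 - phi_a) %% 360, th_a, method = "spearman")))
}
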