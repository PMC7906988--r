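#' Simulate a behavioral trajectory
#'
#' Circular-track sessions produce forward angular running on the annulus
#' midline with an autocorrelated speed process and exponentially distributed
#' pauses; open-field sessions produce a smooth persistent random walk with a
#' reflecting wall and a mild wall-following bias, reproducing meandering
#' coverage with peripheral preference. Positions are sampled at the tracking
#' rate and always lie inside the arena.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to the configuration's `rng_seed`.
#' @return A [trajectory()].
#' @export
simulate_trajectory <- function(config, seed = config$rng_seed) {
  validate_sim_config(config)
  set.seed(derive_seed(seed, 1L))
  dt <- 1 / config$tracking_rate_hz
  n <- max(2L, floor(config$duration_s / dt) + 1L)
  t_s <- (seq_len(n) - 1L) * dt
  geom <- arena_geometry(config)

  if (config$speed_mean_mm_s == 0 && config$speed_sd_mm_s == 0) {
    # degenerate stationary animal
    r0 <- if (config$arena == "circular_track") geom$midline_radius_mm else 0
    return(trajectory(t_s, rep(r0, n), rep(0, n), arena = config$arena))
  }

  v <- speed_process(n, dt, config)

  if (config$arena == "circular_track") {
    omega <- v / geom$midline_radius_mm       # rad/s, counter-clockwise
    theta <- cumsum(omega * dt)
    # small radial wobble inside the lane, frozen while paused
    tau_r <- 0.5
    phi <- exp(-dt / tau_r)
    wob <- stats::filter(stats::rnorm(n, 0, 3 * sqrt(1 - phi^2)), phi,
                         method = "recursive")
    wob <- as.numeric(wob) * (v > 0)
    half <- config$track_width_mm / 2 - 4
    r <- geom$midline_radius_mm + pmin(pmax(wob, -half), half)
    trajectory(t_s, r * cos(theta), r * sin(theta), arena = "circular_track")
  } else {
    open_field_walk(t_s, v, dt, geom$outer_radius_mm)
  }
}

# AR(1) running-speed process (tau = 1 s) gated by exponential run/pause bouts
speed_process <- function(n, dt, config) {
  phi <- exp(-dt)
  v <- config$speed_mean_mm_s +
    as.numeric(stats::filter(
      stats::rnorm(n, 0, config$speed_sd_mm_s * sqrt(1 - phi^2)),
      phi, method = "recursive"))
  v <- pmin(pmax(v, 0), 250)
  if (config$pause_rate_hz > 0 && config$pause_duration_s > 0) {
    state <- logical(n)   # TRUE = paused
    i <- 1L
    while (i <= n) {
      run_len <- ceiling(stats::rexp(1, config$pause_rate_hz) / dt)
      i <- i + run_len
      if (i > n) break
      pause_len <- max(1L, ceiling(stats::rexp(1, 1 / config$pause_duration_s) / dt))
      state[i:min(n, i + pause_len - 1L)] <- TRUE
      i <- i + pause_len
    }
    v[state] <- 0
  }
  v
}

# Persistent random walk in a disc: Ornstein-Uhlenbeck-like heading diffusion,
# reflection at the wall, and a gentle tangential bias in the peripheral band.
open_field_walk <- function(t_s, v, dt, R_mm, margin_mm = 12,
                            heading_sd = 1.6, wall_bias = 0.6,
                            wall_band_mm = 60) {
  n <- length(t_s)
  x <- numeric(n); y <- numeric(n)
  x[1] <- 0; y[1] <- -R_mm / 2
  phi <- stats::runif(1, 0, 2 * pi)
  eps <- stats::rnorm(n, 0, heading_sd * sqrt(dt))
  Rin <- R_mm - margin_mm
  for (i in 2:n) {
    r <- sqrt(x[i - 1]^2 + y[i - 1]^2)
    if (r > R_mm - wall_band_mm && r > 0) {
      tang <- atan2(x[i - 1], -y[i - 1])  # clockwise tangent direction
      # steer toward whichever tangent is closer
      d1 <- sin(tang - phi); d2 <- sin(tang + pi - phi)
      pull <- if (abs(d1) < abs(d2)) d1 else d2
      phi <- phi + wall_bias * pull * dt
    }
    phi <- phi + eps[i]
    nx <- x[i - 1] + v[i] * cos(phi) * dt
    ny <- y[i - 1] + v[i] * sin(phi) * dt
    if (nx * nx + ny * ny > Rin * Rin) {
      # reflect the heading across the wall tangent and retake the step
      a <- atan2(ny, nx)
      phi <- 2 * a + pi - phi
      nx <- x[i - 1] + v[i] * cos(phi) * dt
      ny <- y[i - 1] + v[i] * sin(phi) * dt
      if (nx * nx + ny * ny > Rin * Rin) { nx <- x[i - 1]; ny <- y[i - 1] }
    }
    x[i] <- nx; y[i] <- ny
  }
  trajectory(t_s, x, y, arena = "open_field")
}

#' Simulate a cell population on a trajectory
#'
#' Generates an amplitude-marked event train for each cell at the imaging
#' frame rate. Tuned cells follow a unimodal tuning curve evaluated at the
#' animal's position (1D: circular Gaussian parameterized by center and
#' full-width-at-half-maximum in degrees; 2D: isotropic Gaussian), truncated
#' below 1% of peak so fields have finite support, plus a position-independent
#' background rate, with a per-lap Bernoulli reliability gate on the tuned
#' component. Untuned cells fire at a position-independent rate and Poisson
#' control cells are homogeneous in time. Events are drawn per frame as
#' Bernoulli with p = rate / frame_rate and marked with log-normal amplitudes.
#'
#' @param config A [sim_config()].
#' @param traj A [trajectory()] covering the session.
#' @param seed Integer seed.
#' @param truth Optional pre-drawn ground truth (from [draw_ground_truth()]);
#'   drawn fresh when `NULL`.
#' @param participating Logical per cell; non-participating cells are silent.
#' @return List with `activity` (frames x cells matrix), `truth`
#'   (a `ground_truth` data.frame) and `frame_times`.
#' @export
simulate_cells <- function(config, traj, seed = config$rng_seed,
                           truth = NULL, participating = NULL) {
  validate_sim_config(config)
  if (length(traj$t_s) < 2L) stop("empty trajectory", call. = FALSE)
  set.seed(derive_seed(seed, 2L))
  fr <- config$frame_rate_hz
  n_frames <- max(1L, floor((max(traj$t_s) - traj$t_s[1]) * fr) + 1L)
  frame_times <- traj$t_s[1] + (seq_len(n_frames) - 1L) / fr
  al <- align_tracking(traj, frame_times)
  if (is.null(truth)) truth <- draw_ground_truth(config, seed = seed)
  n_cells <- nrow(truth)
  if (is.null(participating)) participating <- rep(TRUE, n_cells)

  lap_of_frame <- rep(1L, n_frames)
  n_laps <- 1L
  if (config$arena == "circular_track") {
    geom <- arena_geometry(config)
    lin <- linearize_position(al$theta_deg, geom$circumference_cm)
    segs <- segment_laps(lin$cumulative_cm, geom$circumference_cm)
    lap_of_frame <- segs$lap_index
    n_laps <- max(lap_of_frame)
  }

  activity <- matrix(0, n_frames, n_cells)
  for (j in seq_len(n_cells)) {
    if (!participating[j]) next
    rate <- cell_rate(truth[j, ], config, al)
    if (truth$type[j] == "place" && config$lap_reliability < 1 &&
        config$arena == "circular_track") {
      gate <- stats::runif(n_laps) < config$lap_reliability
      tuned <- rate - config$background_event_rate
      rate <- config$background_event_rate + tuned * gate[lap_of_frame]
    }
    p <- pmin(rate / fr, 1)
    ev <- stats::runif(n_frames) < p
    k <- sum(ev)
    if (k > 0)
      activity[ev, j] <- stats::rlnorm(k, config$amplitude_meanlog,
                                       config$amplitude_sdlog)
  }
  list(activity = activity, truth = truth, frame_times = frame_times)
}

#' Expected-rate population matrix (noiseless tuning)
#'
#' Evaluates every cell's tuning curve along a trajectory at the imaging
#' frame times, without event sampling, lap gating or amplitude noise. This
#' is the noiseless population used to probe manifold geometry: a ring of 1D
#' tuned cells yields a closed loop, a 2D-tuned population a sheet.
#'
#' @param config A [sim_config()].
#' @param traj A [trajectory()].
#' @param truth Ground truth from [draw_ground_truth()] (drawn if `NULL`).
#' @return List with `rates` (frames x cells expected event rates),
#'   `frame_times` and `truth`.
#' @export
expected_rate_matrix <- function(config, traj, truth = NULL) {
  if (is.null(truth)) truth <- draw_ground_truth(config)
  fr <- config$frame_rate_hz
  n_frames <- max(1L, floor((max(traj$t_s) - traj$t_s[1]) * fr) + 1L)
  frame_times <- traj$t_s[1] + (seq_len(n_frames) - 1L) / fr
  al <- align_tracking(traj, frame_times)
  rates <- vapply(seq_len(nrow(truth)),
                  function(j) cell_rate(truth[j, ], config, al),
                  numeric(n_frames))
  list(rates = rates, frame_times = frame_times, truth = truth)
}

# per-frame expected event rate for one cell
cell_rate <- function(tr, config, al) {
  n <- length(al$theta_deg)
  switch(tr$type,
    place = {
      if (config$arena == "circular_track") {
        kappa <- log(2) / (1 - cos(tr$field_width / 2 * pi / 180))
        tun <- exp(kappa * (cos((al$theta_deg - tr$center_deg) * pi / 180) - 1))
      } else {
        sigma <- tr$field_width / 2.3548
        d2 <- (al$x_mm - tr$center_x_mm)^2 + (al$y_mm - tr$center_y_mm)^2
        tun <- exp(-d2 / (2 * sigma^2))
      }
      tun[tun < 0.01] <- 0   # finite field support
      config$background_event_rate + tr$peak_rate * tun
    },
    untuned = rep(config$untuned_event_rate, n),
    poisson = rep(config$poisson_event_rate, n),
    stop("unknown cell type: ", tr$type, call. = FALSE))
}

#' Draw ground-truth cell parameters
#'
#' Field centers are uniform over the track angle (1D) or uniform over the
#' arena disc (2D); untuned and Poisson cells carry no center.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Data frame of class `ground_truth` with one row per cell: `cell`,
#'   `type` (`"place"`, `"untuned"`, `"poisson"`), `center_deg`,
#'   `center_x_mm`, `center_y_mm`, `field_width` (deg in 1D, mm in 2D) and
#'   `peak_rate` (events/s).
#' @export
draw_ground_truth <- function(config, seed = config$rng_seed) {
  set.seed(derive_seed(seed, 3L))
  types <- rep(c("place", "untuned", "poisson"),
               c(config$n_place_cells, config$n_untuned_cells,
                 config$n_poisson_cells))
  n <- length(types)
  if (n == 0L) stop("configuration defines no cells", call. = FALSE)
  tr <- data.frame(cell = seq_len(n), type = types,
                   center_deg = NA_real_, center_x_mm = NA_real_,
                   center_y_mm = NA_real_, field_width = NA_real_,
                   peak_rate = NA_real_, stringsAsFactors = FALSE)
  pc <- which(types == "place")
  if (length(pc)) {
    tr$peak_rate[pc] <- config$peak_event_rate
    if (config$arena == "circular_track") {
      tr$center_deg[pc] <- stats::runif(length(pc), 0, 360)
      tr$field_width[pc] <- config$field_width_deg
    } else {
      R <- config$outer_diameter_mm / 2
      rr <- R * sqrt(stats::runif(length(pc)))
      aa <- stats::runif(length(pc), 0, 2 * pi)
      tr$center_x_mm[pc] <- rr * cos(aa)
      tr$center_y_mm[pc] <- rr * sin(aa)
      tr$field_width[pc] <- config$field_width_mm
    }
  }
  class(tr) <- c("ground_truth", "data.frame")
  tr
}

#' Simulate a multi-session study
#'
#' Each session gets its own trajectory and event trains from one top-level
#' seed. Field centers are shared within an environment; with `remap = TRUE`
#' each distinct environment label receives independently drawn centers.
#' Within an environment, centers drift day to day by a Gaussian step of
#' standard deviation `drift_deg` (0 = stable). Cell participation after the
#' first session follows `recurrence_prob`.
#'
#' @param config A [sim_config()].
#' @param n_sessions Number of sessions (>= 1).
#' @param environments Character vector of environment labels, recycled to
#'   `n_sessions`.
#' @param days Integer day index per session (defaults to 1..n_sessions).
#' @param seed Integer seed.
#' @return List of length `n_sessions`; each element has `session`
#'   (an [aligned_session()]) and `truth` (per-session ground truth).
#' @export
simulate_study <- function(config, n_sessions, environments = "A",
                           days = seq_len(n_sessions),
                           seed = config$rng_seed) {
  validate_sim_config(config)
  if (n_sessions < 1L) stop("n_sessions must be >= 1", call. = FALSE)
  environments <- rep_len(as.character(environments), n_sessions)
  if (anyNA(environments) || any(!nzchar(environments)))
    stop("unknown environment label", call. = FALSE)
  base_truth <- draw_ground_truth(config, seed = seed)
  pc <- which(base_truth$type == "place")
  geom <- arena_geometry(config)

  # per-environment field centers
  envs <- unique(environments)
  env_truth <- list()
  for (k in seq_along(envs)) {
    tt <- base_truth
    if (config$remap && k > 1L && length(pc)) {
      set.seed(derive_seed(seed, 100L + k))
      if (config$arena == "circular_track") {
        tt$center_deg[pc] <- stats::runif(length(pc), 0, 360)
      } else {
        R <- config$outer_diameter_mm / 2
        rr <- R * sqrt(stats::runif(length(pc)))
        aa <- stats::runif(length(pc), 0, 2 * pi)
        tt$center_x_mm[pc] <- rr * cos(aa)
        tt$center_y_mm[pc] <- rr * sin(aa)
      }
    }
    env_truth[[envs[k]]] <- tt
  }

  out <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    tt <- env_truth[[environments[s]]]
    if (config$drift_deg > 0 && length(pc) &&
        config$arena == "circular_track") {
      set.seed(derive_seed(seed, 200L + s))
      drift <- stats::rnorm(length(pc), 0, config$drift_deg)
      tt$center_deg[pc] <- wrap_deg(tt$center_deg[pc] + drift)
      env_truth[[environments[s]]] <- tt
    }
    set.seed(derive_seed(seed, 300L + s))
    participating <- if (s == 1L) rep(TRUE, nrow(tt)) else
      stats::runif(nrow(tt)) < config$recurrence_prob
    traj <- simulate_trajectory(config, seed = derive_seed(seed, 400L + s))
    sim <- simulate_cells(config, traj, seed = derive_seed(seed, 500L + s),
                          truth = tt, participating = participating)
    tt$participating <- participating
    sess <- aligned_session(
      traj, sim$activity, frame_rate_hz = config$frame_rate_hz,
      arena = config$arena,
      circumference_cm = if (config$arena == "circular_track")
        geom$circumference_cm else NULL,
      environment = environments[s], day = days[s],
      speed_threshold_mm_s = config$speed_threshold_mm_s,
      frame_times = sim$frame_times)
    out[[s]] <- list(session = sess, truth = tt)
  }
  out
}
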