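#' Simulation configuration
#'
#' Builds a validated configuration object for the synthetic-data generator.
#' Defaults describe the floating-track apparatus (outer diameter 32.5 cm,
#' track width 5 cm, 100 Hz tracking, 30 Hz imaging) and a cell population
#' with unimodal spatial tuning, background activity, log-normal event
#' amplitudes and partial lap-to-lap field expression.
#'
#' @param arena `"circular_track"` or `"open_field"`.
#' @param outer_diameter_mm Outer diameter of the arena (mm).
#' @param track_width_mm Width of the annular track (mm); ignored for the
#'   open field.
#' @param duration_s Session duration in seconds.
#' @param frame_rate_hz Imaging frame rate (Hz).
#' @param tracking_rate_hz Position-tracking sampling rate (Hz).
#' @param speed_mean_mm_s Mean running speed while moving (mm/s).
#' @param speed_sd_mm_s Standard deviation of the running-speed process (mm/s).
#' @param pause_rate_hz Rate (per second) at which running bouts are
#'   interrupted by pauses.
#' @param pause_duration_s Mean pause duration (s, exponential).
#' @param n_place_cells,n_untuned_cells,n_poisson_cells Population
#'   composition: spatially tuned cells, untuned cells (position-independent
#'   rate), and homogeneous Poisson control cells.
#' @param field_width_deg Full width at half maximum of 1D tuning curves
#'   (degrees of track angle).
#' @param field_width_mm Full width at half maximum of 2D tuning curves (mm).
#' @param peak_event_rate Peak in-field event rate of tuned cells (events/s).
#' @param background_event_rate Position-independent background event rate of
#'   tuned cells (events/s).
#' @param untuned_event_rate Event rate of untuned cells (events/s).
#' @param poisson_event_rate Event rate of homogeneous Poisson cells
#'   (events/s).
#' @param amplitude_meanlog,amplitude_sdlog Log-normal parameters of the
#'   calcium-transient event amplitudes (dimensionless dF/F). Setting
#'   `amplitude_sdlog = 0` and `amplitude_meanlog = 0` yields unit amplitudes.
#' @param lap_reliability Probability that a tuned cell expresses its field on
#'   a given lap (per-lap Bernoulli gate on the tuned rate component).
#' @param remap If `TRUE`, field centers are redrawn independently and
#'   uniformly for each distinct environment in a multi-session study.
#' @param recurrence_prob Probability that a cell participates (is active) in
#'   each session after the first, in multi-day studies.
#' @param drift_deg Standard deviation of day-to-day field-center drift within
#'   the same environment (degrees; 0 = perfectly stable fields).
#' @param speed_threshold_mm_s Speed gate used downstream (mm/s); stored here
#'   so the generator and the analysis share one value.
#' @param rng_seed Integer seed; the same configuration and seed reproduce
#'   bit-identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(arena = c("circular_track", "open_field"),
                       outer_diameter_mm = 325,
                       track_width_mm = 50,
                       duration_s = 1800,
                       frame_rate_hz = 30,
                       tracking_rate_hz = 100,
                       speed_mean_mm_s = 100,
                       speed_sd_mm_s = 30,
                       pause_rate_hz = 0.05,
                       pause_duration_s = 2,
                       n_place_cells = 100,
                       n_untuned_cells = 100,
                       n_poisson_cells = 0,
                       field_width_deg = 80,
                       field_width_mm = 148,
                       peak_event_rate = 5,
                       background_event_rate = 0.05,
                       untuned_event_rate = 0.45,
                       poisson_event_rate = 1,
                       amplitude_meanlog = 0,
                       amplitude_sdlog = 0.5,
                       lap_reliability = 0.72,
                       remap = FALSE,
                       recurrence_prob = 0.9,
                       drift_deg = 0,
                       speed_threshold_mm_s = 20,
                       rng_seed = 1L) {
  arena <- match.arg(arena)
  cfg <- list(
    arena = arena,
    outer_diameter_mm = outer_diameter_mm,
    track_width_mm = track_width_mm,
    duration_s = duration_s,
    frame_rate_hz = frame_rate_hz,
    tracking_rate_hz = tracking_rate_hz,
    speed_mean_mm_s = speed_mean_mm_s,
    speed_sd_mm_s = speed_sd_mm_s,
    pause_rate_hz = pause_rate_hz,
    pause_duration_s = pause_duration_s,
    n_place_cells = n_place_cells,
    n_untuned_cells = n_untuned_cells,
    n_poisson_cells = n_poisson_cells,
    field_width_deg = field_width_deg,
    field_width_mm = field_width_mm,
    peak_event_rate = peak_event_rate,
    background_event_rate = background_event_rate,
    untuned_event_rate = untuned_event_rate,
    poisson_event_rate = poisson_event_rate,
    amplitude_meanlog = amplitude_meanlog,
    amplitude_sdlog = amplitude_sdlog,
    lap_reliability = lap_reliability,
    remap = isTRUE(remap),
    recurrence_prob = recurrence_prob,
    drift_deg = drift_deg,
    speed_threshold_mm_s = speed_threshold_mm_s,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid config: ", msg, call. = FALSE)
  if (!is.numeric(cfg$duration_s) || cfg$duration_s <= 0)
    stop_cfg("duration_s must be > 0")
  if (cfg$frame_rate_hz <= 0 || cfg$tracking_rate_hz <= 0)
    stop_cfg("sampling rates must be > 0")
  rates <- c(cfg$speed_mean_mm_s, cfg$speed_sd_mm_s, cfg$pause_rate_hz,
             cfg$pause_duration_s, cfg$peak_event_rate,
             cfg$background_event_rate, cfg$untuned_event_rate,
             cfg$poisson_event_rate)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop_cfg("all rates and durations must be finite and >= 0")
  probs <- c(cfg$lap_reliability, cfg$recurrence_prob)
  if (any(probs < 0) || any(probs > 1))
    stop_cfg("lap_reliability and recurrence_prob must lie in [0, 1]")
  if (cfg$outer_diameter_mm <= 0)
    stop_cfg("outer_diameter_mm must be > 0")
  if (cfg$arena == "circular_track" &&
      (cfg$track_width_mm <= 0 || cfg$track_width_mm >= cfg$outer_diameter_mm))
    stop_cfg("track_width_mm must be in (0, outer_diameter_mm)")
  counts <- c(cfg$n_place_cells, cfg$n_untuned_cells, cfg$n_poisson_cells)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_cfg("cell counts must be non-negative integers")
  invisible(cfg)
}

#' Arena geometry derived from a configuration
#'
#' For the circular track the reference path is the annulus midline, so the
#' default circumference is `pi * (outer_diameter - track_width)`.
#'
#' @param config A [sim_config()].
#' @return A list with `outer_radius_mm`, and for the track `inner_radius_mm`,
#'   `midline_radius_mm` and `circumference_cm`.
#' @export
arena_geometry <- function(config) {
  R <- config$outer_diameter_mm / 2
  if (config$arena == "circular_track") {
    mid <- R - config$track_width_mm / 2
    list(outer_radius_mm = R,
         inner_radius_mm = R - config$track_width_mm,
         midline_radius_mm = mid,
         circumference_cm = 2 * pi * mid / 10)
  } else {
    list(outer_radius_mm = R)
  }
}

# Deterministic sub-seed derivation so that one top-level seed drives every
# stage independently. Kept below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 10007) %% 2147483629)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$arena, "\n")
  cat(sprintf("  duration %.0f s, imaging %g Hz, tracking %g Hz\n",
              x$duration_s, x$frame_rate_hz, x$tracking_rate_hz))
  cat(sprintf("  cells: %d tuned, %d untuned, %d Poisson\n",
              x$n_place_cells, x$n_untuned_cells, x$n_poisson_cells))
  cat(sprintf("  speed %g +/- %g mm/s, lap reliability %.2f, seed %d\n",
              x$speed_mean_mm_s, x$speed_sd_mm_s, x$lap_reliability,
              x$rng_seed))
  invisible(x)
}
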