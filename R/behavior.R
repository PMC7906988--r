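#' Trajectory object
#'
#' A position-tracking time series sampled at the tracking rate (~100 Hz).
#' Angles are measured counter-clockwise in degrees, wrapped to [0, 360).
#'
#' @param t_s Strictly increasing timestamps (s).
#' @param x_mm,y_mm Cartesian position (mm), origin at the arena center.
#' @param arena Arena label carried for downstream checks.
#' @return An object of class `trajectory` with fields `t_s`, `x_mm`, `y_mm`,
#'   `theta_deg`, `radius_mm` and `speed_mm_s` (central-difference speed).
#' @export
trajectory <- function(t_s, x_mm, y_mm, arena = "circular_track") {
  n <- length(t_s)
  if (n < 2L) stop("trajectory needs at least two samples", call. = FALSE)
  if (any(diff(t_s) <= 0))
    stop("trajectory timestamps must be strictly increasing", call. = FALSE)
  if (length(x_mm) != n || length(y_mm) != n)
    stop("x_mm and y_mm must match the length of t_s", call. = FALSE)
  structure(list(
    t_s = as.double(t_s),
    x_mm = as.double(x_mm),
    y_mm = as.double(y_mm),
    theta_deg = wrap_deg(atan2(y_mm, x_mm) * 180 / pi),
    radius_mm = sqrt(x_mm^2 + y_mm^2),
    speed_mm_s = path_speed(t_s, x_mm, y_mm),
    arena = arena
  ), class = "trajectory")
}

wrap_deg <- function(theta) theta %% 360

# central-difference speed from a sampled path
path_speed <- function(t, x, y) {
  n <- length(t)
  v <- numeric(n)
  if (n >= 3L) {
    dt <- t[3:n] - t[1:(n - 2L)]
    v[2:(n - 1L)] <- sqrt((x[3:n] - x[1:(n - 2L)])^2 +
                          (y[3:n] - y[1:(n - 2L)])^2) / dt
  }
  if (n >= 2L) {
    v[1] <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2) / (t[2] - t[1])
    v[n] <- sqrt((x[n] - x[n - 1L])^2 + (y[n] - y[n - 1L])^2) /
      (t[n] - t[n - 1L])
  }
  v
}

#' Align position tracking to imaging frames
#'
#' Linearly interpolates tracked position onto the imaging frame times and
#' recomputes speed from the interpolated positions (central differences,
#' then a 5-frame running median to suppress single-sample tracker noise).
#' Frames that fall inside a tracking gap longer than `max_gap_s`, or outside
#' the tracked time span, are flagged invalid.
#'
#' @param traj A [trajectory()].
#' @param frame_times Imaging frame times (s).
#' @param max_gap_s Tracking gaps longer than this mark overlapped frames
#'   invalid (default 0.5 s).
#' @return A list with `x_mm`, `y_mm`, `theta_deg`, `speed_mm_s` and logical
#'   `valid` per frame.
#' @export
align_tracking <- function(traj, frame_times, max_gap_s = 0.5) {
  if (max(frame_times) < min(traj$t_s) || min(frame_times) > max(traj$t_s))
    stop("alignment error: frame times do not overlap the tracking span",
         call. = FALSE)
  x <- stats::approx(traj$t_s, traj$x_mm, xout = frame_times, rule = 2)$y
  y <- stats::approx(traj$t_s, traj$y_mm, xout = frame_times, rule = 2)$y
  valid <- frame_times >= min(traj$t_s) & frame_times <= max(traj$t_s)
  gaps <- which(diff(traj$t_s) > max_gap_s)
  for (g in gaps) {
    valid[frame_times > traj$t_s[g] & frame_times < traj$t_s[g + 1L]] <- FALSE
  }
  v <- path_speed(frame_times, x, y)
  if (length(v) >= 5L) v <- stats::runmed(v, 5L, endrule = "keep")
  list(x_mm = x, y_mm = y, theta_deg = wrap_deg(atan2(y, x) * 180 / pi),
       speed_mm_s = as.double(v), valid = valid)
}

#' Linearize circular-track position
#'
#' Converts angular position to linear distance using the known track
#' circumference. Returns both the within-lap position and the unwrapped
#' cumulative distance, which increases monotonically under forward running
#' and accumulates the minimal signed angular step at wrap crossings.
#'
#' @param theta_deg Angle series in degrees (any range; wrapped internally).
#' @param circumference_cm Track circumference (cm).
#' @return List with `position_cm` (within-lap, in [0, circumference)) and
#'   `cumulative_cm` (unwrapped distance from the first sample).
#' @export
linearize_position <- function(theta_deg, circumference_cm) {
  if (circumference_cm <= 0) stop("circumference must be > 0", call. = FALSE)
  th <- wrap_deg(theta_deg)
  pos <- th / 360 * circumference_cm
  d <- diff(th)
  d <- (d + 180) %% 360 - 180   # minimal signed step, forward positive
  cum <- cumsum(c(0, d)) / 360 * circumference_cm
  list(position_cm = pos, cumulative_cm = cum)
}

#' Speed gating and running fraction
#'
#' The moving mask keeps frames whose speed strictly exceeds the threshold
#' (20 mm/s by default), excluding pauses for rewards or grooming.
#'
#' @param speed_mm_s Per-frame speed (mm/s).
#' @param threshold_mm_s Gate (strict inequality).
#' @return List with logical `moving` and scalar `running_fraction`.
#' @export
compute_kinematics <- function(speed_mm_s, threshold_mm_s = 20) {
  moving <- speed_mm_s > threshold_mm_s
  list(moving = moving, running_fraction = mean(moving))
}

#' Segment a linearized session into laps
#'
#' A new lap boundary is placed each time the cumulative distance advances a
#' full circumference past the previous boundary; backward excursions do not
#' remove boundaries, so laps accrue only on net forward progress. The final
#' partial lap is retained and flagged incomplete.
#'
#' @param cumulative_cm Unwrapped cumulative distance per frame (cm).
#' @param circumference_cm Track circumference (cm).
#' @return Object of class `lap_segmentation`: data.frame `laps` with
#'   `start_frame`, `end_frame`, `complete`, plus per-frame `lap_index` and
#'   `n_complete`.
#' @export
segment_laps <- function(cumulative_cm, circumference_cm) {
  n <- length(cumulative_cm)
  # boundary k at the first frame where net progress reaches k circumferences
  prog <- cummax(cumulative_cm - cumulative_cm[1])
  lap_index <- floor(prog / circumference_cm) + 1L
  starts <- c(1L, which(diff(lap_index) > 0) + 1L)
  ends <- c(starts[-1L] - 1L, n)
  n_laps <- length(starts)
  # lap k is complete iff lap k+1 started; the final lap is the partial one
  # (a zero-length final lap occurs only when the session ends exactly on a
  # boundary, in which case all earlier laps are complete)
  complete <- c(rep(TRUE, n_laps - 1L), FALSE)
  structure(list(
    laps = data.frame(lap = seq_len(n_laps), start_frame = starts,
                      end_frame = ends, complete = complete),
    lap_index = lap_index,
    n_complete = sum(complete)
  ), class = "lap_segmentation")
}

#' @export
print.lap_segmentation <- function(x, ...) {
  cat("<lap_segmentation>", nrow(x$laps), "laps (", x$n_complete,
      "complete )\n")
  invisible(x)
}

#' Open-field coverage fraction
#'
#' Fraction of in-arena spatial bins (2 x 2 cm by default) visited at least
#' once. A bin belongs to the arena if its center lies inside the disc.
#'
#' @param x_mm,y_mm Position samples (mm).
#' @param arena_radius_mm Disc radius (mm).
#' @param bin_size_cm Bin side (cm).
#' @return Fraction in [0, 1].
#' @export
coverage_fraction <- function(x_mm, y_mm, arena_radius_mm = 162.5,
                              bin_size_cm = 2) {
  g <- square_grid(arena_radius_mm / 10, bin_size_cm)
  ix <- bin_index_2d(x_mm / 10, y_mm / 10, g)
  visited <- unique(ix[!is.na(ix)])
  length(intersect(visited, which(g$in_arena))) / sum(g$in_arena)
}

# Square grid of side bins covering [-R, R] with the disc membership mask.
square_grid <- function(radius_cm, bin_size_cm) {
  n <- ceiling(2 * radius_cm / bin_size_cm)
  edges <- seq(-n / 2, n / 2) * bin_size_cm
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  cx <- rep(centers, times = n)
  cy <- rep(centers, each = n)
  list(n = n, edges = edges, centers = centers,
       center_x = cx, center_y = cy,
       in_arena = sqrt(cx^2 + cy^2) <= radius_cm,
       radius_cm = radius_cm, bin_size_cm = bin_size_cm)
}

# linear (column-major: x fast) bin index into a square grid; NA if outside
bin_index_2d <- function(x_cm, y_cm, g) {
  i <- findInterval(x_cm, g$edges, rightmost.closed = TRUE)
  j <- findInterval(y_cm, g$edges, rightmost.closed = TRUE)
  out <- i < 1L | i > g$n | j < 1L | j > g$n
  idx <- (j - 1L) * g$n + i
  idx[out] <- NA_integer_
  idx
}

#' Aligned session: behavior joined to neural activity
#'
#' Resamples a trajectory to the imaging frame times, computes the moving
#' mask, linearizes position for circular-track sessions and attaches the
#' frames x cells activity matrix.
#'
#' @param traj A [trajectory()].
#' @param activity Numeric matrix, frames x cells, non-negative deconvolved
#'   event amplitudes (dF/F units); row count defines the frame count.
#' @param frame_rate_hz Imaging frame rate.
#' @param arena `"circular_track"` or `"open_field"`.
#' @param circumference_cm Track circumference (cm); required for the track.
#' @param environment,day Session metadata.
#' @param speed_threshold_mm_s Speed gate (strict).
#' @param frame_times Frame times (s); defaults to a regular grid at
#'   `frame_rate_hz` starting at the first tracking sample.
#' @param max_gap_s Tracking-gap threshold passed to [align_tracking()].
#' @return Object of class `aligned_session`.
#' @export
aligned_session <- function(traj, activity, frame_rate_hz = 30,
                            arena = c("circular_track", "open_field"),
                            circumference_cm = NULL,
                            environment = "A", day = 1L,
                            speed_threshold_mm_s = 20,
                            frame_times = NULL, max_gap_s = 0.5) {
  arena <- match.arg(arena)
  activity <- as.matrix(activity)
  if (any(activity < 0))
    stop("activity amplitudes must be non-negative", call. = FALSE)
  if (is.null(frame_times))
    frame_times <- traj$t_s[1] + seq_len(nrow(activity)) / frame_rate_hz -
      1 / frame_rate_hz
  if (length(frame_times) != nrow(activity))
    stop("frame_times must match the activity frame count", call. = FALSE)
  al <- align_tracking(traj, frame_times, max_gap_s = max_gap_s)
  kin <- compute_kinematics(al$speed_mm_s, speed_threshold_mm_s)
  s <- list(frame_times = frame_times,
            x_mm = al$x_mm, y_mm = al$y_mm, theta_deg = al$theta_deg,
            speed_mm_s = al$speed_mm_s,
            moving = kin$moving & al$valid,
            valid = al$valid,
            running_fraction = kin$running_fraction,
            activity = activity,
            n_cells = ncol(activity),
            frame_rate_hz = frame_rate_hz,
            arena = arena,
            environment = environment, day = day,
            speed_threshold_mm_s = speed_threshold_mm_s)
  if (arena == "circular_track") {
    if (is.null(circumference_cm))
      stop("circumference_cm is required for circular-track sessions",
           call. = FALSE)
    lin <- linearize_position(al$theta_deg, circumference_cm)
    s$circumference_cm <- circumference_cm
    s$position_cm <- lin$position_cm
    s$cumulative_cm <- lin$cumulative_cm
    s$laps <- segment_laps(lin$cumulative_cm, circumference_cm)
  } else {
    if (!is.null(circumference_cm)) s$circumference_cm <- circumference_cm
  }
  class(s) <- "aligned_session"
  s
}

#' @export
print.aligned_session <- function(x, ...) {
  cat("<aligned_session>", x$arena, "env", x$environment, "day", x$day, "\n")
  cat(sprintf("  %d frames at %g Hz, %d cells, running fraction %.2f\n",
              length(x$frame_times), x$frame_rate_hz, x$n_cells,
              x$running_fraction))
  if (!is.null(x$laps))
    cat("  ", x$laps$n_complete, "complete laps\n")
  invisible(x)
}
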