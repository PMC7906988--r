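#' Write tracking data to CSV
#'
#' Columns `t_s`, `x_mm`, `y_mm`, `theta_deg`, written with 17 significant
#' digits so a read round-trips to bit-identical doubles.
#'
#' @param traj A [trajectory()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tracking_csv <- function(traj, path) {
  d <- data.frame(t_s = traj$t_s, x_mm = traj$x_mm, y_mm = traj$y_mm,
                  theta_deg = traj$theta_deg)
  write_full_precision(d, path)
  invisible(path)
}

write_full_precision <- function(d, path) {
  fmt <- vapply(d, function(col) sprintf("%.17g", col), character(nrow(d)))
  if (nrow(d) == 1L) fmt <- matrix(fmt, nrow = 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(d), collapse = ","), con)
  writeLines(apply(fmt, 1, paste, collapse = ","), con)
}

#' Read tracking data from CSV
#'
#' Requires columns `t_s`, `x_mm`, `y_mm` (header mandatory); `theta_deg` is
#' recomputed from the coordinates. Timestamps must be strictly increasing.
#'
#' @param path CSV file.
#' @param arena Arena label to attach.
#' @return A [trajectory()].
#' @export
read_tracking_csv <- function(path, arena = "circular_track") {
  d <- utils::read.csv(path)
  need <- c("t_s", "x_mm", "y_mm")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("tracking file ", path, " is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(diff(d$t_s) <= 0))
    stop("tracking file ", path, " has non-monotone timestamps",
         call. = FALSE)
  trajectory(d$t_s, d$x_mm, d$y_mm, arena = arena)
}

#' Write an activity matrix to CSV with a JSON metadata sidecar
#'
#' The matrix is written frames x cells with header `cell_1..cell_N` at full
#' precision; metadata (frame rate, arena, environment, day, circumference)
#' goes to `<path>.json`.
#'
#' @param activity Frames x cells matrix.
#' @param path CSV file.
#' @param frame_rate_hz,arena,environment,day,circumference_cm Metadata.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(activity, path, frame_rate_hz = 30,
                               arena = "circular_track", environment = "A",
                               day = 1, circumference_cm = NULL) {
  d <- as.data.frame(activity)
  names(d) <- paste0("cell_", seq_len(ncol(d)))
  write_full_precision(d, path)
  meta <- list(frame_rate_hz = frame_rate_hz, arena = arena,
               environment = environment, day = day,
               n_frames = nrow(activity), n_cells = ncol(activity))
  if (!is.null(circumference_cm)) meta$circumference_cm <- circumference_cm
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an activity matrix and its metadata
#'
#' @param path CSV file written by [write_activity_csv()].
#' @return List with `activity` matrix and `meta` list.
#' @export
read_activity_csv <- function(path) {
  d <- utils::read.csv(path)
  activity <- as.matrix(d)
  dimnames(activity) <- NULL
  neg <- which(activity < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf(
      "negative amplitude at frame %d, cell %d in %s",
      neg[1, 1], neg[1, 2], path), call. = FALSE)
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  list(activity = activity, meta = meta)
}

#' Session bundle
#'
#' Paths plus metadata describing one recorded session on disk.
#'
#' @param tracking Path to the tracking CSV.
#' @param activity Path to the activity CSV.
#' @param arena,circumference_cm,environment,day,frame_rate_hz Metadata
#'   overriding the activity sidecar.
#' @return List of class `session_bundle`.
#' @export
session_bundle <- function(tracking, activity, arena = NULL,
                           circumference_cm = NULL, environment = NULL,
                           day = NULL, frame_rate_hz = NULL) {
  for (p in c(tracking, activity))
    if (!file.exists(p)) stop("file does not exist: ", p, call. = FALSE)
  structure(list(tracking = tracking, activity = activity, arena = arena,
                 circumference_cm = circumference_cm,
                 environment = environment, day = day,
                 frame_rate_hz = frame_rate_hz),
            class = "session_bundle")
}

#' Load and align a session from disk
#'
#' Reads the tracking and activity files, validates them (negative
#' amplitudes, missing columns and non-monotone timestamps raise descriptive
#' errors), aligns behavior to the imaging frames and computes the moving
#' mask. If the tracking ends before the imaging span, the trailing frames
#' are flagged invalid with a warning.
#'
#' @param bundle A [session_bundle()].
#' @return An [aligned_session()].
#' @export
load_session <- function(bundle) {
  act <- read_activity_csv(bundle$activity)
  meta <- act$meta
  pick <- function(field, default) {
    if (!is.null(bundle[[field]])) bundle[[field]]
    else if (!is.null(meta[[field]])) meta[[field]]
    else default
  }
  arena <- pick("arena", "circular_track")
  traj <- read_tracking_csv(bundle$tracking, arena = arena)
  fr <- pick("frame_rate_hz", 30)
  n_frames <- nrow(act$activity)
  frame_times <- traj$t_s[1] + (seq_len(n_frames) - 1L) / fr
  if (max(frame_times) > max(traj$t_s) + 1 / fr)
    warning(sprintf(
      "tracking ends %.2f s before the imaging span; trailing frames flagged invalid",
      max(frame_times) - max(traj$t_s)), call. = FALSE)
  aligned_session(
    traj, act$activity, frame_rate_hz = fr, arena = arena,
    circumference_cm = pick("circumference_cm",
                            if (arena == "circular_track")
                              pi * 27.5 else NULL),
    environment = pick("environment", "A"),
    day = pick("day", 1L),
    frame_times = frame_times)
}

#' Export per-cell classification results to CSV
#'
#' @param results A `session_results` from [classify_cells()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results$table, path, row.names = FALSE)
  invisible(path)
}
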