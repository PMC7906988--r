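#' Circular difference between field locations
#'
#' Signed minimal difference `b - a` on a circle of the given period, wrapped
#' to (-period/2, period/2].
#'
#' @param a,b Positions (same units as `period`).
#' @param period Circumference (cm) or 360 for degrees.
#' @return Signed circular difference.
#' @export
circular_diff <- function(a, b, period) {
  d <- (b - a) %% period
  ifelse(d > period / 2, d - period, d)
}

#' Cross-session stability statistics
#'
#' For a pair of classified sessions sharing a registered cell index:
#' recurrence of the active and place-cell classifications (directional,
#' a to b), mean Pearson correlation of normalized smoothed rate maps over
#' cells classified as place cells in both sessions (restricted to bins valid
#' in both), the circular field shift per recurring place cell, and the mean
#' map correlation over all cells active in both sessions.
#'
#' @param a,b `session_results` from [classify_cells()] over the same cells.
#' @return Object of class `session_pair_stats`.
#' @export
session_pair_stats <- function(a, b) {
  if (!identical(a$cells, b$cells))
    stop("sessions do not share a registered cell index", call. = FALSE)
  ta <- a$table; tb <- b$table
  if (nrow(ta) == 0L) stop("no shared cells", call. = FALSE)
  day_interval <- abs(as.numeric(b$day) - as.numeric(a$day))

  act_a <- ta$active; act_b <- tb$active
  pc_a <- ta$is_place_cell; pc_b <- tb$is_place_cell
  recurrence_active <- if (any(act_a)) mean(act_b[act_a]) else NA_real_
  recurrence_place <- if (any(pc_a)) mean(pc_b[pc_a]) else NA_real_

  both_pc <- which(pc_a & pc_b)
  both_active <- which(act_a & act_b)
  corr_of <- function(k) {
    ma <- a$stats[[k]]$map; mb <- b$stats[[k]]$map
    if (is.null(ma) || is.null(mb)) return(NA_real_)
    keep <- ma$valid & mb$valid
    if (sum(keep, na.rm = TRUE) < 3L) return(NA_real_)
    suppressWarnings(stats::cor(ma$normalized_rate[keep],
                                mb$normalized_rate[keep]))
  }
  field_correlation <- if (length(both_pc))
    mean(vapply(both_pc, corr_of, 0), na.rm = TRUE) else NA_real_
  mean_map_correlation_all <- if (length(both_active))
    mean(vapply(both_active, corr_of, 0), na.rm = TRUE) else NA_real_

  shifts <- if (length(both_pc) && a$mode == "1d") {
    C <- a$circumference_cm
    circular_diff(ta$field_location[both_pc], tb$field_location[both_pc], C)
  } else numeric(0)

  structure(list(
    day_interval = day_interval,
    n_cells = nrow(ta),
    recurrence_active = recurrence_active,
    recurrence_place = recurrence_place,
    n_recurring_place = length(both_pc),
    field_correlation = field_correlation,
    field_correlation_defined = length(both_pc) > 0L,
    mean_map_correlation_all_cells = mean_map_correlation_all,
    field_shifts_cm = shifts
  ), class = "session_pair_stats")
}

#' @export
print.session_pair_stats <- function(x, ...) {
  cat(sprintf("<session_pair_stats> interval %g d: recurrence active %.2f, place %.2f\n",
              x$day_interval, x$recurrence_active, x$recurrence_place))
  cat(sprintf("  field correlation %.3f over %d recurring place cells\n",
              x$field_correlation, x$n_recurring_place))
  invisible(x)
}

#' Hodges-Ajne test of circular uniformity
#'
#' The statistic m is the minimum number of observations in any closed
#' half-circle, found by sweeping half-planes anchored at each data angle and
#' its antipode. For m < n/3 the exact tail probability is
#' p = (n - 2m) C(n, m) 2^(1-n); otherwise the large-sample approximation
#' p = sqrt(2 pi) / A exp(-pi^2 / (8 A^2)) with A = pi sqrt(n) / (2 (n - 2m))
#' is used. p is clipped to [0, 1].
#'
#' @param angles_deg Angles in degrees (any range).
#' @return List with `m`, `p` and `n`.
#' @export
hodges_ajne_test <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 4L) stop("insufficient-sample error: need n >= 4", call. = FALSE)
  th <- wrap_deg(angles_deg)
  m <- hodges_ajne_m(th)
  p <- hodges_ajne_p(n, m)
  list(m = m, p = p, n = n)
}

# Minimum closed-half-circle count. The count of [a, a+180] is piecewise
# constant in a with breakpoints at the data angles and their antipodes, and
# attains its minimum strictly between breakpoints, so it is evaluated at the
# breakpoints and at the midpoints between consecutive breakpoints (the
# breakpoint set is symmetric under rotation by 180 degrees, so both
# half-circles of every split are visited).
hodges_ajne_m <- function(th) {
  n <- length(th)
  bp <- sort(unique(wrap_deg(c(th, th + 180))))
  mids <- wrap_deg((bp + c(bp[-1L], bp[1L] + 360)) / 2)
  anchors <- c(bp, mids)
  m <- n
  for (a in anchors) {
    d <- wrap_deg(th - a)
    m <- min(m, sum(d <= 180))
  }
  m
}

hodges_ajne_p <- function(n, m) {
  if (n - 2 * m <= 0) return(1)
  p <- if (m < n / 3) {
    (n - 2 * m) * choose(n, m) * 2^(1 - n)
  } else {
    A <- pi * sqrt(n) / (2 * (n - 2 * m))
    sqrt(2 * pi) / A * exp(-pi^2 / (8 * A^2))
  }
  min(max(p, 0), 1)
}

#' Cross-environment remapping statistics
#'
#' Compares classified results from two tracks over a shared cell index:
#' the per-cell Pearson correlation of normalized rate maps averaged over
#' cells active in both tracks, the fraction of common place cells retaining
#' their field location (|circular shift| within `retain_bins` bins), the
#' shift distribution, and the Hodges-Ajne test of circular uniformity of the
#' shifts.
#'
#' @param a,b `session_results` for the two tracks.
#' @param retain_bins Retention threshold in bins (default 1 bin = 2 cm).
#' @return Object of class `remap_stats`.
#' @export
cross_track_remapping <- function(a, b, retain_bins = 1) {
  if (!identical(a$cells, b$cells))
    stop("sessions do not share a registered cell index", call. = FALSE)
  ta <- a$table; tb <- b$table
  common_active <- which(ta$active & tb$active)
  if (length(common_active) == 0L)
    stop("no common active cells", call. = FALSE)
  pair <- session_pair_stats(a, b)
  C <- a$circumference_cm
  common_pc <- which(ta$is_place_cell & tb$is_place_cell)
  shifts <- pair$field_shifts_cm
  bin_cm <- 2
  retained <- if (length(shifts))
    mean(abs(shifts) <= retain_bins * bin_cm) else NA_real_
  ha <- if (length(shifts) >= 4L)
    hodges_ajne_test(shifts / C * 360) else list(m = NA, p = NA_real_)
  structure(list(
    n_common_active = length(common_active),
    n_common_place_cells = length(common_pc),
    fraction_retaining_location = retained,
    mean_activity_correlation = pair$mean_map_correlation_all_cells,
    shift_distribution_cm = shifts,
    hodges_ajne_m = ha$m,
    hodges_ajne_p = ha$p
  ), class = "remap_stats")
}

#' @export
print.remap_stats <- function(x, ...) {
  cat(sprintf("<remap_stats> %d common active cells, %d common place cells\n",
              x$n_common_active, x$n_common_place_cells))
  cat(sprintf("  mean activity correlation %.3f; %.0f%% retained location\n",
              x$mean_activity_correlation,
              100 * x$fraction_retaining_location))
  cat(sprintf("  Hodges-Ajne p = %.3f on field shifts\n", x$hodges_ajne_p))
  invisible(x)
}
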