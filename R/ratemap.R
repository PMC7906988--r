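#' One-dimensional activity-rate map
#'
#' Bins the linearized track into 2-cm bins (the last bin absorbs the
#' rounding remainder), accumulates deconvolved event amplitudes over the
#' occupancy of each bin during moving frames, divides by occupancy time,
#' smooths with a circular three-bin boxcar and normalizes by the smoothed
#' maximum. The amplitude-blind event-rate map (events/s) is kept alongside
#' the amplitude-weighted activity-rate map (dF/F per s).
#'
#' @param session An [aligned_session()] on a circular track.
#' @param cell Column index of the cell in the activity matrix.
#' @param bin_size_cm Spatial bin size (cm).
#' @param frames Optional logical/integer subset of frames to use instead of
#'   all moving frames (still intersected with the moving mask).
#' @return Object of class `ratemap_1d` with `occupancy_s`, `raw_rate`,
#'   `event_rate`, `smoothed_rate`, `normalized_rate`, `valid` (occupied
#'   bins), `bin_centers_cm`, `all_zero` flag.
#' @export
rate_map_1d <- function(session, cell, bin_size_cm = 2, frames = NULL) {
  if (session$arena != "circular_track")
    stop("rate_map_1d requires a circular-track session", call. = FALSE)
  use <- session$moving
  if (!is.null(frames)) {
    sel <- rep(FALSE, length(use))
    sel[frames] <- TRUE
    use <- use & sel
  }
  if (!any(use)) stop("empty-map error: no moving frames", call. = FALSE)
  nb <- n_bins_1d(session$circumference_cm, bin_size_cm)
  bin <- bin_index_1d(session$position_cm[use], bin_size_cm, nb)
  amp <- session$activity[use, cell]
  dt <- 1 / session$frame_rate_hz
  occ <- tabulate(bin, nb) * dt
  if (all(occ == 0)) stop("empty-map error: zero occupancy", call. = FALSE)
  amp_sum <- accumulate_by_bin(amp, bin, nb)
  ev_sum <- accumulate_by_bin(as.double(amp > 0), bin, nb)
  valid <- occ > 0
  raw <- ifelse(valid, amp_sum / occ, NA_real_)
  evr <- ifelse(valid, ev_sum / occ, NA_real_)
  sm <- smooth_boxcar_circular(raw, valid)
  m <- max(sm[valid], 0, na.rm = TRUE)
  all_zero <- !is.finite(m) || m <= 0
  norm <- if (all_zero) ifelse(valid, 0, NA_real_) else sm / m
  structure(list(
    n_bins = nb, bin_size_cm = bin_size_cm,
    bin_edges_cm = seq(0, nb) * bin_size_cm,
    bin_centers_cm = (seq_len(nb) - 0.5) * bin_size_cm,
    circumference_cm = session$circumference_cm,
    occupancy_s = occ, raw_rate = raw, event_rate = evr,
    smoothed_rate = sm, normalized_rate = norm,
    valid = valid, all_zero = all_zero, cell = cell
  ), class = "ratemap_1d")
}

#' @export
print.ratemap_1d <- function(x, ...) {
  cat("<ratemap_1d>", x$n_bins, "bins of", x$bin_size_cm, "cm; peak",
      format(suppressWarnings(max(x$smoothed_rate[x$valid], na.rm = TRUE)),
             digits = 3), "dF/F per s\n")
  invisible(x)
}

n_bins_1d <- function(circumference_cm, bin_size_cm = 2) {
  max(1L, round(circumference_cm / bin_size_cm))
}

# half-open [left, right) bins; the last bin absorbs the rounding remainder
bin_index_1d <- function(position_cm, bin_size_cm, nb) {
  pmin(floor(position_cm / bin_size_cm) + 1L, nb)
}

accumulate_by_bin <- function(values, bin, nb) {
  out <- numeric(nb)
  if (length(values)) {
    rs <- rowsum(values, bin)
    out[as.integer(rownames(rs))] <- rs[, 1]
  }
  out
}

# Mass-preserving circular boxcar: each valid source bin distributes its rate
# equally over its valid destinations among {i-1, i, i+1}, so the total over
# valid bins is conserved exactly and the all-valid case reduces to the
# ordinary circular three-bin average.
smooth_boxcar_circular <- function(rate, valid) {
  nb <- length(rate)
  wrap <- function(i) ((i - 1L) %% nb) + 1L
  sm <- numeric(nb)
  src <- which(valid & is.finite(rate))
  ndest <- numeric(length(src))
  dests <- vector("list", 3L)
  for (k in -1:1) {
    d <- wrap(src + k)
    ok <- valid[d]
    dests[[k + 2L]] <- list(d = d, ok = ok)
    ndest <- ndest + ok
  }
  for (k in 1:3) {
    d <- dests[[k]]$d; ok <- dests[[k]]$ok
    idx <- which(ok)
    if (length(idx))
      sm[d[idx]] <- sm[d[idx]] + rate[src[idx]] / ndest[idx]
  }
  # scatter adds; but equal-split per source means each destination receives
  # source/ndest, matching the convolution transpose — already accumulated
  sm[!valid] <- NA_real_
  sm
}

#' Two-dimensional activity-rate map
#'
#' Open-field analogue of [rate_map_1d()]: 2 x 2 cm bins masked to the arena
#' disc, Gaussian smoothing with a standard deviation of 1.5 bins (kernel
#' mass renormalized over valid bins to avoid edge attenuation), and
#' normalization by the smoothed maximum.
#'
#' @param session An [aligned_session()] in the open field.
#' @param cell Cell column index.
#' @param bin_size_cm Bin side (cm).
#' @param sigma_bins Gaussian smoothing SD in bins.
#' @param arena_radius_cm Disc radius (cm).
#' @return Object of class `ratemap_2d`; rate fields are `n x n` matrices
#'   (x indexes rows), `valid` marks in-arena occupied bins.
#' @export
rate_map_2d <- function(session, cell, bin_size_cm = 2, sigma_bins = 1.5,
                        arena_radius_cm = 16.25) {
  if (session$arena != "open_field")
    stop("rate_map_2d requires an open-field session", call. = FALSE)
  use <- session$moving
  if (!any(use)) stop("empty-map error: no moving frames", call. = FALSE)
  g <- square_grid(arena_radius_cm, bin_size_cm)
  nbin <- g$n * g$n
  ix <- bin_index_2d(session$x_mm[use] / 10, session$y_mm[use] / 10, g)
  keep <- !is.na(ix)
  ix <- ix[keep]
  amp <- session$activity[use, cell][keep]
  dt <- 1 / session$frame_rate_hz
  occ <- tabulate(ix, nbin) * dt
  if (all(occ == 0)) stop("empty-map error: zero occupancy", call. = FALSE)
  amp_sum <- accumulate_by_bin(amp, ix, nbin)
  ev_sum <- accumulate_by_bin(as.double(amp > 0), ix, nbin)
  valid <- occ > 0 & g$in_arena
  raw <- ifelse(valid, amp_sum / occ, NA_real_)
  evr <- ifelse(valid, ev_sum / occ, NA_real_)
  sm <- smooth_gaussian_masked(raw, valid, g$n, sigma_bins)
  m <- max(sm[valid], 0, na.rm = TRUE)
  all_zero <- !is.finite(m) || m <= 0
  norm <- if (all_zero) ifelse(valid, 0, NA_real_) else sm / m
  shape <- function(v) matrix(v, g$n, g$n)
  structure(list(
    n = g$n, bin_size_cm = bin_size_cm, sigma_bins = sigma_bins,
    arena_radius_cm = arena_radius_cm,
    bin_centers_cm = g$centers,
    center_x = shape(g$center_x), center_y = shape(g$center_y),
    occupancy_s = shape(occ), raw_rate = shape(raw),
    event_rate = shape(evr), smoothed_rate = shape(sm),
    normalized_rate = shape(norm),
    valid = shape(valid), in_arena = shape(g$in_arena),
    all_zero = all_zero, cell = cell
  ), class = "ratemap_2d")
}

#' @export
print.ratemap_2d <- function(x, ...) {
  cat("<ratemap_2d>", x$n, "x", x$n, "bins of", x$bin_size_cm, "cm;",
      sum(x$valid), "valid bins\n")
  invisible(x)
}

# Mass-preserving masked Gaussian smoothing on a square grid (vector layout,
# x fast): every valid source bin spreads its rate with a truncated Gaussian
# kernel renormalized over valid destinations.
smooth_gaussian_masked <- function(rate, valid, n, sigma_bins) {
  rad <- ceiling(3 * sigma_bins)
  off <- expand.grid(di = -rad:rad, dj = -rad:rad)
  w <- exp(-(off$di^2 + off$dj^2) / (2 * sigma_bins^2))
  sm <- numeric(n * n)
  src <- which(valid & is.finite(rate))
  si <- ((src - 1L) %% n) + 1L
  sj <- ((src - 1L) %/% n) + 1L
  for (s in seq_along(src)) {
    di <- si[s] + off$di; dj <- sj[s] + off$dj
    ok <- di >= 1L & di <= n & dj >= 1L & dj <= n
    d <- (dj[ok] - 1L) * n + di[ok]
    ww <- w[ok]
    keep <- valid[d]
    ww <- ww[keep]; d <- d[keep]
    sm[d] <- sm[d] + rate[src[s]] * ww / sum(ww)
  }
  sm[!valid] <- NA_real_
  sm
}

#' Per-lap rate maps
#'
#' Builds a laps x bins matrix of per-lap activity rate (amplitude sums
#' divided by per-lap occupancy). Bins not visited within a lap are missing
#' (`NA`), not zero. The occupancy-weighted mean over all lap rows (complete
#' and partial) reconstructs the session map exactly.
#'
#' @param session Circular-track [aligned_session()].
#' @param cell Cell column index.
#' @param laps A [segment_laps()] result; defaults to the session's.
#' @param bin_size_cm Bin size (cm).
#' @return Object of class `lap_rate_matrix` with `rate` (laps x bins),
#'   `occupancy_s`, `complete` flag per lap.
#' @export
per_lap_maps <- function(session, cell, laps = session$laps,
                         bin_size_cm = 2) {
  if (session$arena != "circular_track")
    stop("per_lap_maps requires a circular-track session", call. = FALSE)
  if (is.null(laps) || laps$n_complete < 1L)
    stop("per_lap_maps requires at least one complete lap", call. = FALSE)
  nb <- n_bins_1d(session$circumference_cm, bin_size_cm)
  n_laps <- nrow(laps$laps)
  dt <- 1 / session$frame_rate_hz
  use <- which(session$moving)
  bin <- bin_index_1d(session$position_cm[use], bin_size_cm, nb)
  lap <- laps$lap_index[use]
  amp <- session$activity[use, cell]
  cell_id <- (lap - 1L) * nb + bin
  occ <- accumulate_by_bin(rep(dt, length(use)), cell_id, n_laps * nb)
  amp_sum <- accumulate_by_bin(amp, cell_id, n_laps * nb)
  occ <- matrix(occ, n_laps, nb, byrow = TRUE)
  amp_sum <- matrix(amp_sum, n_laps, nb, byrow = TRUE)
  rate <- ifelse(occ > 0, amp_sum / occ, NA_real_)
  structure(list(
    rate = rate, occupancy_s = occ,
    complete = laps$laps$complete,
    n_bins = nb, bin_size_cm = bin_size_cm, cell = cell
  ), class = "lap_rate_matrix")
}

#' @export
print.lap_rate_matrix <- function(x, ...) {
  cat("<lap_rate_matrix>", nrow(x$rate), "laps x", x$n_bins, "bins (",
      sum(x$complete), "complete )\n")
  invisible(x)
}
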