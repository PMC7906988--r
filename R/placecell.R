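#' Skaggs spatial information (bits/event)
#'
#' I = sum_i p_i (lambda_i / lambda_bar) log2(lambda_i / lambda_bar), with
#' p_i the occupancy probability of bin i, lambda_i its activity rate and
#' lambda_bar the occupancy-weighted mean rate. Bins with zero rate
#' contribute zero (x log x -> 0). Computed from the unsmoothed rates over
#' valid bins.
#'
#' @param map A `ratemap_1d` or `ratemap_2d`, or a list with numeric
#'   `occupancy_s` and `raw_rate` (equal length after removing `NA`).
#' @param use_event_rate If `TRUE`, use the amplitude-blind event-rate map.
#' @return Spatial information in bits/event (>= 0).
#' @export
spatial_information <- function(map, use_event_rate = FALSE) {
  lambda <- if (use_event_rate) map$event_rate else map$raw_rate
  occ <- map$occupancy_s
  keep <- is.finite(lambda) & is.finite(occ) & occ > 0
  skaggs_information(as.double(lambda[keep]), as.double(occ[keep]))
}

# core formula on vectors of rates and occupancies
skaggs_information <- function(lambda, occ) {
  p <- occ / sum(occ)
  lbar <- sum(p * lambda)
  if (!is.finite(lbar) || lbar <= 0)
    stop("undefined-information error: mean rate is zero", call. = FALSE)
  r <- lambda / lbar
  pos <- r > 0
  sum(p[pos] * r[pos] * log2(r[pos]))
}

#' Shuffle null distribution for spatial information
#'
#' Chance-level spatial information is the distribution of the information
#' rate after randomly permuting the cell's per-frame activity values across
#' the moving frames (event count and amplitudes are conserved). The
#' percentile is the fraction of null values strictly below the observed
#' information, times 100. Permutation is realized by placing the nonzero
#' event amplitudes on a uniformly sampled subset of moving frames, which is
#' distributionally identical to a full permutation. A circular-shift null
#' (rotating the activity series by a random offset along the moving frames)
#' is available as an alternative.
#'
#' @param session An [aligned_session()].
#' @param cell Cell column index.
#' @param n_shuffles Number of shuffles (1,000 to match the chance criterion).
#' @param seed Integer seed.
#' @param mode `"1d"` or `"2d"` (controls which map is built).
#' @param method `"permute"` (default) or `"rotate"`.
#' @param bin_size_cm Bin size.
#' @return List with `information`, `percentile`, `null` (vector of shuffled
#'   information values) and `n_events`; cells with no events while moving
#'   return `skipped = TRUE`.
#' @export
shuffle_null <- function(session, cell, n_shuffles = 1000, seed = 1L,
                         mode = c("1d", "2d"), method = c("permute", "rotate"),
                         bin_size_cm = 2) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  use <- which(session$moving)
  amp <- session$activity[use, cell]
  ev <- which(amp > 0)
  if (length(ev) == 0L)
    return(list(skipped = TRUE, n_events = 0L,
                information = NA_real_, percentile = NA_real_,
                null = numeric(0)))
  if (mode == "1d") {
    nb <- n_bins_1d(session$circumference_cm, bin_size_cm)
    bin <- bin_index_1d(session$position_cm[use], bin_size_cm, nb)
  } else {
    g <- square_grid(16.25, bin_size_cm)
    bin <- bin_index_2d(session$x_mm[use] / 10, session$y_mm[use] / 10, g)
    nb <- g$n * g$n
    ok <- !is.na(bin)
    use <- use[ok]; amp <- amp[ok]; bin <- bin[ok]
    ev <- which(amp > 0)
  }
  dt <- 1 / session$frame_rate_hz
  occ <- tabulate(bin, nb) * dt
  occupied <- occ > 0
  info_of <- function(amp_sum) {
    skaggs_information((amp_sum / occ)[occupied], occ[occupied])
  }
  obs <- info_of(accumulate_by_bin(amp, bin, nb))
  amps <- amp[ev]
  nT <- length(amp)
  set.seed(derive_seed(seed, cell))
  null <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    idx <- if (method == "permute") sample.int(nT, length(ev))
           else ((ev - 1L + sample.int(nT, 1L)) %% nT) + 1L
    null[s] <- info_of(accumulate_by_bin(amps, bin[idx], nb))
  }
  list(skipped = FALSE, information = obs,
       percentile = 100 * mean(null < obs),
       null = null, n_events = length(ev))
}

#' Detect a 1D place field
#'
#' Field location is the bin of maximum smoothed activity rate (ties break to
#' the lowest bin index and set `tie`); the field comprises every valid bin
#' whose smoothed rate is at least 50% of the maximum (contiguity is not
#' required) and its size is the member count times the bin width.
#'
#' @param map A `ratemap_1d`.
#' @param threshold Fraction of the maximum defining membership.
#' @return Object of class `place_field` with `location_bin`, `location_cm`,
#'   `size_cm`, `member_bins`, `degenerate` (all valid bins are members) and
#'   `tie` flags.
#' @export
detect_field_1d <- function(map, threshold = 0.5) {
  if (map$all_zero) stop("no-field error: all-zero map", call. = FALSE)
  sm <- map$smoothed_rate
  sm[!map$valid] <- NA_real_
  m <- max(sm, na.rm = TRUE)
  peaks <- which(abs(sm - m) < 1e-12 * max(m, 1))
  loc <- peaks[1L]
  members <- which(!is.na(sm) & sm >= threshold * m)
  structure(list(
    location_bin = loc,
    location_cm = map$bin_centers_cm[loc],
    size_cm = length(members) * map$bin_size_cm,
    member_bins = members,
    degenerate = length(members) == sum(map$valid),
    tie = length(peaks) > 1L,
    mode = "1d"
  ), class = "place_field")
}

#' Detect a 2D place field
#'
#' Member bins are those with normalized rate above 0.5; the centroid is the
#' rate-weighted mean of member-bin centers and the size is the member count
#' times the bin area. Fields whose member bins form more than one connected
#' component (4-connectivity) are flagged multimodal.
#'
#' @param map A `ratemap_2d`.
#' @param threshold Normalized-rate threshold.
#' @return `place_field` with `centroid_cm` (x, y), `size_cm2`,
#'   `member_bins` (linear indices), `degenerate` and `multimodal` flags.
#' @export
detect_field_2d <- function(map, threshold = 0.5) {
  if (map$all_zero) stop("no-field error: all-zero map", call. = FALSE)
  norm <- map$normalized_rate
  members <- which(!is.na(norm) & norm > threshold)
  if (length(members) == 0L)
    stop("no-field error: no bins above threshold", call. = FALSE)
  w <- map$smoothed_rate[members]
  cx <- sum(map$center_x[members] * w) / sum(w)
  cy <- sum(map$center_y[members] * w) / sum(w)
  structure(list(
    centroid_cm = c(x = cx, y = cy),
    size_cm2 = length(members) * map$bin_size_cm^2,
    member_bins = members,
    degenerate = length(members) == sum(map$valid),
    multimodal = n_components_4(members, map$n) > 1L,
    mode = "2d"
  ), class = "place_field")
}

# number of 4-connected components among linear indices on an n x n grid
n_components_4 <- function(members, n) {
  if (length(members) == 0L) return(0L)
  inset <- logical(n * n)
  inset[members] <- TRUE
  seen <- logical(n * n)
  comps <- 0L
  for (m in members) {
    if (seen[m]) next
    comps <- comps + 1L
    queue <- m
    seen[m] <- TRUE
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      i <- ((cur - 1L) %% n) + 1L
      j <- ((cur - 1L) %/% n) + 1L
      nb <- c(if (i > 1L) cur - 1L, if (i < n) cur + 1L,
              if (j > 1L) cur - n, if (j < n) cur + n)
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}

#' @export
print.place_field <- function(x, ...) {
  if (x$mode == "1d")
    cat(sprintf("<place_field 1d> location %.1f cm, size %.1f cm (%d bins)\n",
                x$location_cm, x$size_cm, length(x$member_bins)))
  else
    cat(sprintf("<place_field 2d> centroid (%.1f, %.1f) cm, size %.0f cm^2\n",
                x$centroid_cm[1], x$centroid_cm[2], x$size_cm2))
  invisible(x)
}

#' Classify one cell as place cell or not
#'
#' Circular track (1D): a place cell must (1) emit at least one in-field
#' event on at least half of the complete laps, (2) have events in at least
#' 5% of the moving frames spent inside its field, and (3) carry spatial
#' information exceeding 99% of a 1,000-shuffle null. Open field (2D): the
#' event-presence threshold is 2% of moving in-field frames and the
#' information criterion applies; there is no lap criterion. The field used
#' by the criteria is detected from the full-session smoothed map.
#'
#' @param session An [aligned_session()].
#' @param cell Cell column index.
#' @param mode `"1d"` or `"2d"`; defaults from the session's arena.
#' @param n_shuffles,seed Shuffle-null settings.
#' @param shuffle_method Passed to [shuffle_null()].
#' @param lap_criterion_mode `"in_field"` (an event inside the field during
#'   the lap; default) or `"whole_lap"` (any event during the lap).
#' @param percentile_criterion Chance percentile a place cell must reach.
#' @param bin_size_cm Spatial bin size.
#' @return Object of class `place_cell_stats`: information, percentile,
#'   criteria flags `c1_laps`, `c2_field_occupancy`, `c3_information`,
#'   `is_place_cell`, the detected `field` and the rate `map`.
#' @export
classify_place_cell <- function(session, cell,
                                mode = if (session$arena == "circular_track")
                                  "1d" else "2d",
                                n_shuffles = 1000, seed = 1L,
                                shuffle_method = "permute",
                                lap_criterion_mode = c("in_field", "whole_lap"),
                                percentile_criterion = 99,
                                bin_size_cm = 2) {
  lap_criterion_mode <- match.arg(lap_criterion_mode)
  res <- list(cell = cell, mode = mode, is_place_cell = FALSE,
              reason = NA_character_,
              information = NA_real_, percentile = NA_real_,
              lap_active_fraction = NA_real_,
              within_field_active_fraction = NA_real_,
              c1_laps = NA, c2_field_occupancy = NA, c3_information = NA,
              field = NULL, map = NULL)
  class(res) <- "place_cell_stats"

  use <- which(session$moving)
  amp <- session$activity[use, cell]
  if (!any(amp > 0)) {
    res$reason <- "no events while moving"
    return(res)
  }
  map <- tryCatch(
    if (mode == "1d") rate_map_1d(session, cell, bin_size_cm = bin_size_cm)
    else rate_map_2d(session, cell, bin_size_cm = bin_size_cm),
    error = function(e) NULL)
  if (is.null(map) || map$all_zero) {
    res$reason <- "empty or all-zero rate map"
    return(res)
  }
  res$map <- map
  field <- tryCatch(
    if (mode == "1d") detect_field_1d(map) else detect_field_2d(map),
    error = function(e) NULL)
  if (is.null(field)) {
    res$reason <- "no field detected"
    return(res)
  }
  res$field <- field
  res$information <- spatial_information(map)

  # in-field frame membership among moving frames
  if (mode == "1d") {
    nb <- map$n_bins
    bin <- bin_index_1d(session$position_cm[use], bin_size_cm, nb)
  } else {
    g <- square_grid(map$arena_radius_cm, bin_size_cm)
    bin <- bin_index_2d(session$x_mm[use] / 10, session$y_mm[use] / 10, g)
  }
  in_field <- !is.na(bin) & bin %in% field$member_bins

  # criterion 2: events present in enough moving in-field time bins
  c2_threshold <- if (mode == "1d") 0.05 else 0.02
  n_if <- sum(in_field)
  res$within_field_active_fraction <-
    if (n_if > 0) sum(amp > 0 & in_field) / n_if else 0
  res$c2_field_occupancy <- res$within_field_active_fraction >= c2_threshold

  # criterion 1 (1D only): active on at least half the complete laps
  if (mode == "1d") {
    laps <- session$laps
    if (is.null(laps) || laps$n_complete < 1L) {
      res$reason <- "no complete laps"
      return(res)
    }
    lap_of <- laps$lap_index[use]
    complete_set <- which(laps$laps$complete)
    active_on <- if (lap_criterion_mode == "in_field")
      unique(lap_of[amp > 0 & in_field]) else unique(lap_of[amp > 0])
    res$lap_active_fraction <-
      length(intersect(active_on, complete_set)) / length(complete_set)
    res$c1_laps <- res$lap_active_fraction >= 0.5
  }

  sh <- shuffle_null(session, cell, n_shuffles = n_shuffles, seed = seed,
                     mode = mode, method = shuffle_method,
                     bin_size_cm = bin_size_cm)
  res$percentile <- sh$percentile
  res$c3_information <- !sh$skipped && sh$percentile >= percentile_criterion

  res$is_place_cell <- if (mode == "1d")
    isTRUE(res$c1_laps) && isTRUE(res$c2_field_occupancy) &&
      isTRUE(res$c3_information)
  else isTRUE(res$c2_field_occupancy) && isTRUE(res$c3_information)
  res
}

#' @export
print.place_cell_stats <- function(x, ...) {
  cat(sprintf("<place_cell_stats> cell %d (%s): %s\n", x$cell, x$mode,
              if (isTRUE(x$is_place_cell)) "PLACE CELL" else "not a place cell"))
  cat(sprintf("  I = %.3f bits/event, percentile %.1f\n",
              x$information, x$percentile))
  cat(sprintf("  c1 laps: %s  c2 field occupancy: %s  c3 information: %s\n",
              format(x$c1_laps), format(x$c2_field_occupancy),
              format(x$c3_information)))
  invisible(x)
}

#' Classify every cell in a session
#'
#' Runs [classify_place_cell()] over all cells and assembles a per-cell
#' results table plus the per-cell stats objects (maps and fields retained
#' for downstream stability analysis).
#'
#' @inheritParams classify_place_cell
#' @param cells Cell indices (default: all).
#' @return Object of class `session_results`: `table` (data.frame with
#'   cell, active, information, percentile, criteria, is_place_cell, field
#'   location and size), `stats` (list), and the `session` metadata.
#' @export
classify_cells <- function(session, cells = seq_len(session$n_cells),
                           mode = if (session$arena == "circular_track")
                             "1d" else "2d",
                           n_shuffles = 1000, seed = 1L, ...) {
  stats_list <- vector("list", length(cells))
  rows <- vector("list", length(cells))
  mov <- session$moving
  for (k in seq_along(cells)) {
    j <- cells[k]
    st <- classify_place_cell(session, j, mode = mode,
                              n_shuffles = n_shuffles, seed = seed, ...)
    stats_list[[k]] <- st
    loc <- if (!is.null(st$field)) {
      if (mode == "1d") st$field$location_cm else NA_real_
    } else NA_real_
    size <- if (!is.null(st$field)) {
      if (mode == "1d") st$field$size_cm else st$field$size_cm2
    } else NA_real_
    rows[[k]] <- data.frame(
      cell = j,
      active = any(session$activity[mov, j] > 0),
      information = st$information,
      percentile = st$percentile,
      c1_laps = isTRUE(st$c1_laps),
      c2_field_occupancy = isTRUE(st$c2_field_occupancy),
      c3_information = isTRUE(st$c3_information),
      is_place_cell = isTRUE(st$is_place_cell),
      field_location = loc,
      field_size = size)
  }
  structure(list(table = do.call(rbind, rows), stats = stats_list,
                 cells = cells, mode = mode,
                 environment = session$environment, day = session$day,
                 circumference_cm = session$circumference_cm,
                 arena = session$arena),
            class = "session_results")
}

#' @export
print.session_results <- function(x, ...) {
  n <- nrow(x$table)
  cat(sprintf("<session_results> env %s day %s: %d/%d place cells (%.0f%%)\n",
              x$environment, format(x$day), sum(x$table$is_place_cell), n,
              100 * mean(x$table$is_place_cell)))
  invisible(x)
}
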