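test_that("single event produces the boxcar delta response, with wrap", {
  nb <- 43
  n_frames <- 2 * nb * 15               # two uniform laps
  for (k in c(10L, nb)) {               # interior bin and wrap at last bin
    act <- matrix(0, n_frames, 1)
    sess <- uniform_lap_session(2, 15, act)
    bin <- placefields:::bin_index_1d(sess$position_cm, 2, nb)
    f <- which(bin == k)[1]
    sess$activity[f, 1] <- 1
    map <- rate_map_1d(sess, 1)
    # raw rate concentrated in bin k
    expect_true(all(map$raw_rate[-k] == 0))
    expect_gt(map$raw_rate[k], 0)
    # smoothing spreads exactly one third to each circular neighbor
    wrap <- function(i) ((i - 1) %% nb) + 1
    nbrs <- wrap(c(k - 1, k, k + 1))
    expect_equal(map$smoothed_rate[nbrs],
                 rep(map$raw_rate[k] / 3, 3), tolerance = 1e-12)
    expect_true(all(map$smoothed_rate[-nbrs] == 0))
  }
})

test_that("uniform activity with uniform occupancy normalizes to one", {
  nb <- 43
  n_frames <- nb * 15
  act <- matrix(1, n_frames, 1)
  sess <- uniform_lap_session(1, 15, act)
  map <- rate_map_1d(sess, 1)
  expect_equal(unname(map$normalized_rate[map$valid]),
               rep(1, sum(map$valid)), tolerance = 1e-9)
})

test_that("smoothing preserves total rate mass over valid bins", {
  set.seed(5)
  for (i in 1:10) {
    nb <- 43
    rate <- rexp(nb)
    valid <- runif(nb) > 0.2
    rate[!valid] <- NA
    sm <- placefields:::smooth_boxcar_circular(rate, valid)
    expect_equal(sum(sm[valid]), sum(rate[valid]), tolerance = 1e-9)
  }
  for (i in 1:5) {
    n <- 17
    rate <- matrix(rexp(n * n), n, n)
    valid <- matrix(runif(n * n) > 0.3, n, n)
    rate[!valid] <- NA
    sm <- placefields:::smooth_gaussian_masked(as.vector(rate),
                                               as.vector(valid), n, 1.5)
    expect_equal(sum(sm[as.vector(valid)]), sum(rate[valid]),
                 tolerance = 1e-9)
  }
})

test_that("event-rate and activity-rate maps agree for unit amplitudes", {
  cfg <- sim_config(duration_s = 300, n_place_cells = 3, n_untuned_cells = 1,
                    amplitude_meanlog = 0, amplitude_sdlog = 0, rng_seed = 8)
  st <- simulate_study(cfg, 1)
  sess <- st[[1]]$session
  map <- rate_map_1d(sess, 1)
  expect_equal(map$raw_rate, map$event_rate, tolerance = 1e-12)
})

test_that("maps are invariant to frame permutations preserving pairing", {
  cfg <- sim_config(duration_s = 300, n_place_cells = 2, n_untuned_cells = 0,
                    rng_seed = 9)
  st <- simulate_study(cfg, 1)
  sess <- st[[1]]$session
  map <- rate_map_1d(sess, 1)
  perm <- sample(length(sess$frame_times))
  sess2 <- sess
  sess2$position_cm <- sess$position_cm[perm]
  sess2$speed_mm_s <- sess$speed_mm_s[perm]
  sess2$moving <- sess$moving[perm]
  sess2$activity <- sess$activity[perm, , drop = FALSE]
  map2 <- rate_map_1d(sess2, 1)
  expect_equal(map2$raw_rate, map$raw_rate, tolerance = 1e-12)
  expect_equal(map2$occupancy_s, map$occupancy_s)
})

test_that("occupancy accounts for all moving time", {
  cfg <- sim_config(duration_s = 300, n_place_cells = 1, n_untuned_cells = 0,
                    rng_seed = 10)
  st <- simulate_study(cfg, 1)
  sess <- st[[1]]$session
  map <- rate_map_1d(sess, 1)
  expect_equal(sum(map$occupancy_s),
               sum(sess$moving) / sess$frame_rate_hz,
               tolerance = 1 / sess$frame_rate_hz)
})

test_that("2D maps respond to a single event with a Gaussian bump", {
  cfg <- sim_config(arena = "open_field", duration_s = 600,
                    n_place_cells = 1, n_untuned_cells = 0,
                    background_event_rate = 0, rng_seed = 12)
  sess <- noiseless_session(cfg)
  # replace activity with a single event at a known frame
  sess$activity[] <- 0
  f <- which(sess$moving)[100]
  sess$activity[f, 1] <- 1
  map <- rate_map_2d(sess, 1)
  ix <- placefields:::bin_index_2d(sess$x_mm[f] / 10, sess$y_mm[f] / 10,
                                   placefields:::square_grid(16.25, 2))
  # smoothed peak sits at the event bin
  expect_equal(which.max(replace(map$smoothed_rate, !map$valid, -1)), ix)
})

test_that("proportional activity yields identical normalized 2D maps", {
  cfg <- sim_config(arena = "open_field", duration_s = 600,
                    n_place_cells = 2, n_untuned_cells = 0, rng_seed = 14)
  sess <- noiseless_session(cfg)
  sess$activity[, 2] <- 3.7 * sess$activity[, 1]
  m1 <- rate_map_2d(sess, 1)
  m2 <- rate_map_2d(sess, 2)
  expect_equal(m1$normalized_rate, m2$normalized_rate, tolerance = 1e-9)
})

test_that("zero-activity cells yield an all-zero flagged map", {
  cfg <- sim_config(arena = "open_field", duration_s = 120,
                    n_place_cells = 1, n_untuned_cells = 1,
                    untuned_event_rate = 0, rng_seed = 15)
  st <- simulate_study(cfg, 1)
  map <- rate_map_2d(st[[1]]$session, 2)
  expect_true(map$all_zero)
  expect_true(all(map$normalized_rate[map$valid] == 0))
})

test_that("per-lap maps reconstruct the session map by occupancy weighting", {
  cfg <- sim_config(duration_s = 600, n_place_cells = 3, n_untuned_cells = 0,
                    rng_seed = 16)
  st <- simulate_study(cfg, 1)
  sess <- st[[1]]$session
  for (cell in 1:3) {
    lm <- per_lap_maps(sess, cell)
    map <- rate_map_1d(sess, cell)
    w <- lm$occupancy_s
    num <- colSums(lm$rate * w, na.rm = TRUE)
    den <- colSums(w)
    recon <- ifelse(den > 0, num / den, NA)
    expect_equal(recon[map$valid], unname(map$raw_rate[map$valid]),
                 tolerance = 1e-9)
    expect_equal(den[map$valid], unname(map$occupancy_s[map$valid]),
                 tolerance = 1e-12)
  }
})

test_that("zero-event laps give zero rates in visited bins, NA elsewhere", {
  nb <- 43
  n_frames <- 3 * nb * 10
  act <- matrix(0, n_frames, 1)
  sess <- uniform_lap_session(3, 10, act)
  sess$activity[which(sess$laps$lap_index == 1), 1] <- 0.5  # events on lap 1 only
  lm <- per_lap_maps(sess, 1)
  expect_true(all(lm$rate[2, !is.na(lm$rate[2, ])] == 0))
  expect_gt(sum(lm$rate[1, ], na.rm = TRUE), 0)
})

test_that("empty sessions raise map errors", {
  nb <- 43
  act <- matrix(0, nb * 10, 1)
  sess <- uniform_lap_session(1, 10, act)
  sess$moving[] <- FALSE
  expect_error(rate_map_1d(sess, 1), "moving")
})
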