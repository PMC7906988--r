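test_that("spatial information matches analytic cases", {
  # uniform rate over uniform occupancy carries no information
  m_uniform <- list(occupancy_s = rep(1, 10), raw_rate = rep(2.5, 10))
  expect_equal(spatial_information(m_uniform), 0)
  # activity confined to 1 of 4 equal-occupancy bins: log2(4) = 2 bits/event
  m_four <- list(occupancy_s = rep(1, 4), raw_rate = c(8, 0, 0, 0))
  expect_equal(spatial_information(m_four), 2)
  # p = (1/2, 1/2), rates (2, 0): 0.5 * 2 * log2(2) = 1 bit/event
  m_two <- list(occupancy_s = c(3, 3), raw_rate = c(2, 0))
  expect_equal(spatial_information(m_two), 1)
  expect_error(spatial_information(list(occupancy_s = c(1, 1),
                                        raw_rate = c(0, 0))),
               "undefined-information")
})

test_that("spatial information is invariant to rate scaling and relabeling", {
  set.seed(3)
  occ <- rexp(40) + 0.1
  lam <- rexp(40)
  i0 <- spatial_information(list(occupancy_s = occ, raw_rate = lam))
  expect_gte(i0, 0)
  expect_equal(spatial_information(list(occupancy_s = occ,
                                        raw_rate = 7.3 * lam)), i0)
  perm <- sample(40)
  expect_equal(spatial_information(list(occupancy_s = occ[perm],
                                        raw_rate = lam[perm])), i0)
})

test_that("shuffle null conserves events and matches a full permutation null", {
  cfg <- sim_config(duration_s = 300, n_place_cells = 1, n_untuned_cells = 0,
                    rng_seed = 23)
  st <- simulate_study(cfg, 1)
  sess <- st[[1]]$session
  sh <- shuffle_null(sess, 1, n_shuffles = 300, seed = 4)
  expect_false(sh$skipped)
  expect_length(sh$null, 300)
  expect_true(all(is.finite(sh$null)))

  # oracle: explicit full permutation of per-frame activity among moving
  # frames, information recomputed from scratch
  use <- which(sess$moving)
  amp <- sess$activity[use, 1]
  nb <- placefields:::n_bins_1d(sess$circumference_cm, 2)
  bin <- placefields:::bin_index_1d(sess$position_cm[use], 2, nb)
  occ <- tabulate(bin, nb) / sess$frame_rate_hz
  set.seed(99)
  null_perm <- replicate(300, {
    a <- amp[sample(length(amp))]
    num <- placefields:::accumulate_by_bin(a, bin, nb)
    placefields:::skaggs_information((num / occ)[occ > 0], occ[occ > 0])
  })
  expect_gt(suppressWarnings(stats::ks.test(sh$null, null_perm))$p.value,
            0.01)
})

test_that("shuffle percentiles of untuned cells are uniform", {
  cfg <- sim_config(duration_s = 600, n_place_cells = 0,
                    n_untuned_cells = 60, rng_seed = 29)
  st <- simulate_study(cfg, 1)
  sess <- st[[1]]$session
  pct <- vapply(seq_len(60), function(j)
    shuffle_null(sess, j, n_shuffles = 100, seed = 5)$percentile, 0)
  expect_gt(suppressWarnings(
    stats::ks.test(pct / 100, "punif"))$p.value, 0.01)
})

test_that("a strongly tuned noiseless cell reaches the top percentile", {
  cfg <- sim_config(duration_s = 1800, n_place_cells = 1,
                    n_untuned_cells = 0, background_event_rate = 0,
                    lap_reliability = 1, rng_seed = 37)
  st <- simulate_study(cfg, 1)
  sh <- shuffle_null(st[[1]]$session, 1, n_shuffles = 200, seed = 6)
  expect_equal(sh$percentile, 100)
})

test_that("cells without events are skipped with a flag", {
  nb <- 43
  sess <- uniform_lap_session(2, 10, matrix(0, 2 * nb * 10, 1))
  sh <- shuffle_null(sess, 1)
  expect_true(sh$skipped)
  expect_equal(sh$n_events, 0L)
})

test_that("1D field detection follows the 50%-of-maximum rule", {
  map <- manual_map_1d(c(0, 0.2, 0.6, 1, 0.6, 0.2, 0))
  f <- detect_field_1d(map)
  expect_equal(f$location_bin, 4L)         # 0-based bin 3
  expect_equal(sort(f$member_bins), 3:5)
  expect_equal(f$size_cm, 6)
  expect_false(f$degenerate)
  expect_false(f$tie)

  # constant positive map: the whole track, flagged degenerate
  fc <- detect_field_1d(manual_map_1d(rep(2, 10)))
  expect_equal(fc$size_cm, 20)
  expect_true(fc$degenerate)

  # two equal maxima: lowest index wins with a tie flag
  ft <- detect_field_1d(manual_map_1d(c(0, 1, 0, 1, 0)))
  expect_equal(ft$location_bin, 2L)
  expect_true(ft$tie)

  expect_error(detect_field_1d(manual_map_1d(rep(0, 5))), "no-field")
})

test_that("2D field detection finds centroids of bumps", {
  n <- 17
  centers <- (seq_len(n) - (n + 1) / 2) * 2
  bump <- function(cx, cy, sd = 3)
    outer(centers, centers, function(x, y)
      exp(-((x - cx)^2 + (y - cy)^2) / (2 * sd^2)))
  f <- detect_field_2d(manual_map_2d(bump(4, -6)))
  expect_lt(abs(f$centroid_cm["x"] - 4), 1)
  expect_lt(abs(f$centroid_cm["y"] + 6), 1)
  expect_false(f$multimodal)

  # uniform map: centroid at the grid center of mass, degenerate
  fu <- detect_field_2d(manual_map_2d(matrix(1, n, n)))
  expect_lt(abs(fu$centroid_cm["x"]), 1e-9)
  expect_lt(abs(fu$centroid_cm["y"]), 1e-9)
  expect_true(fu$degenerate)

  # two symmetric equal bumps: centroid at the midpoint, multimodal flag
  fb <- detect_field_2d(manual_map_2d(bump(-8, 0) + bump(8, 0)))
  expect_lt(abs(fb$centroid_cm["x"]), 0.5)
  expect_true(fb$multimodal)
})

test_that("noiseless reliable place cells pass all 1D criteria", {
  cfg <- sim_config(duration_s = 900, n_place_cells = 3, n_untuned_cells = 0,
                    lap_reliability = 1, rng_seed = 41)
  st <- simulate_study(cfg, 1)
  res <- classify_place_cell(st[[1]]$session, 1, n_shuffles = 100, seed = 7)
  expect_true(res$c1_laps)
  expect_true(res$c2_field_occupancy)
  expect_true(res$c3_information)
  expect_true(res$is_place_cell)
})

test_that("a cell expressed on too few laps fails the lap criterion", {
  cfg <- sim_config(duration_s = 1200, n_place_cells = 2,
                    n_untuned_cells = 0, lap_reliability = 0.35,
                    background_event_rate = 0, rng_seed = 43)
  st <- simulate_study(cfg, 1)
  res <- classify_place_cell(st[[1]]$session, 1, n_shuffles = 50, seed = 7)
  expect_false(res$c1_laps)
  expect_false(res$is_place_cell)
  expect_lt(res$lap_active_fraction, 0.5)
})

test_that("homogeneous Poisson cells fail the information criterion", {
  cfg <- sim_config(duration_s = 900, n_place_cells = 0, n_untuned_cells = 0,
                    n_poisson_cells = 5, rng_seed = 47)
  st <- simulate_study(cfg, 1)
  res <- lapply(1:5, function(j)
    classify_place_cell(st[[1]]$session, j, n_shuffles = 200, seed = 7))
  c3 <- vapply(res, function(r) isTRUE(r$c3_information), TRUE)
  expect_lte(sum(c3), 1)   # chance level is ~1% per cell
  expect_false(any(vapply(res, `[[`, TRUE, "is_place_cell") & !c3))
})

test_that("classification is deterministic given a seed", {
  cfg <- sim_config(duration_s = 300, n_place_cells = 2, n_untuned_cells = 2,
                    rng_seed = 53)
  st <- simulate_study(cfg, 1)
  r1 <- classify_cells(st[[1]]$session, n_shuffles = 50, seed = 9)
  r2 <- classify_cells(st[[1]]$session, n_shuffles = 50, seed = 9)
  expect_identical(r1$table, r2$table)
})
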