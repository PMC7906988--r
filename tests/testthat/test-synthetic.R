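test_that("invalid configurations are rejected", {
  expect_error(sim_config(duration_s = 0), "duration")
  expect_error(sim_config(duration_s = -5), "duration")
  expect_error(sim_config(peak_event_rate = -1), "rates")
  expect_error(sim_config(lap_reliability = 1.5), "lap_reliability")
  expect_error(sim_config(track_width_mm = 400), "track_width")
  expect_error(sim_config(n_place_cells = -2), "cell counts")
})

test_that("identical config and seed reproduce bit-identical output", {
  cfg <- sim_config(duration_s = 60, n_place_cells = 5, n_untuned_cells = 3,
                    rng_seed = 7)
  t1 <- simulate_trajectory(cfg)
  t2 <- simulate_trajectory(cfg)
  expect_identical(t1, t2)
  c1 <- simulate_cells(cfg, t1)
  c2 <- simulate_cells(cfg, t1)
  expect_identical(c1$activity, c2$activity)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cells(cfg, t1, seed = 8)
  expect_false(identical(c1$activity, c3$activity))
})

test_that("zero-speed configuration produces a stationary animal", {
  cfg <- sim_config(duration_s = 10, speed_mean_mm_s = 0, speed_sd_mm_s = 0)
  tr <- simulate_trajectory(cfg)
  expect_true(all(tr$x_mm == tr$x_mm[1]))
  expect_true(all(tr$y_mm == tr$y_mm[1]))
  expect_true(all(tr$speed_mm_s == 0))
})

test_that("trajectories stay inside the arena", {
  cfg <- sim_config(duration_s = 120, rng_seed = 3)
  tr <- simulate_trajectory(cfg)
  geom <- arena_geometry(cfg)
  expect_true(all(tr$radius_mm <= geom$outer_radius_mm + 1e-9))
  expect_true(all(tr$radius_mm >= geom$inner_radius_mm - 1e-9))
  expect_true(all(diff(tr$t_s) > 0))

  cfg2 <- sim_config(arena = "open_field", duration_s = 120, rng_seed = 3)
  tr2 <- simulate_trajectory(cfg2)
  expect_true(all(tr2$radius_mm <= cfg2$outer_diameter_mm / 2 + 1e-9))
})

test_that("circular-track behavior reaches the expected lap count", {
  cfg <- sim_config(duration_s = 2700, speed_mean_mm_s = 100, rng_seed = 3)
  tr <- simulate_trajectory(cfg)
  lin <- linearize_position(tr$theta_deg, arena_geometry(cfg)$circumference_cm)
  segs <- segment_laps(lin$cumulative_cm, arena_geometry(cfg)$circumference_cm)
  expect_gte(segs$n_complete, 100)
})

test_that("open-field walk covers the arena and prefers the periphery", {
  cfg <- sim_config(arena = "open_field", duration_s = 2700, rng_seed = 3)
  tr <- simulate_trajectory(cfg)
  expect_gt(coverage_fraction(tr$x_mm, tr$y_mm), 0.9)
  outer <- mean(tr$radius_mm > cfg$outer_diameter_mm / 2 - 60)
  expect_gt(outer, 0.4)
  expect_lt(outer, 0.8)
})

test_that("zero rates produce an all-zero activity matrix", {
  cfg <- sim_config(duration_s = 30, n_place_cells = 3, n_untuned_cells = 2,
                    n_poisson_cells = 1, peak_event_rate = 0,
                    background_event_rate = 0, untuned_event_rate = 0,
                    poisson_event_rate = 0)
  tr <- simulate_trajectory(cfg)
  sim <- simulate_cells(cfg, tr)
  expect_true(all(sim$activity == 0))
})

test_that("amplitudes are non-negative and events respect field support", {
  cfg <- sim_config(duration_s = 600, n_place_cells = 1, n_untuned_cells = 0,
                    background_event_rate = 0, lap_reliability = 1,
                    rng_seed = 21)
  tr <- simulate_trajectory(cfg)
  sim <- simulate_cells(cfg, tr)
  expect_true(all(sim$activity >= 0))
  ev <- which(sim$activity[, 1] > 0)
  expect_gt(length(ev), 10)
  al <- align_tracking(tr, sim$frame_times)
  # truncating the circular Gaussian at 1% of peak bounds the half-support
  kappa <- log(2) / (1 - cos(cfg$field_width_deg / 2 * pi / 180))
  half_support <- acos(1 + log(0.01) / kappa) * 180 / pi
  d <- abs(circular_diff(sim$truth$center_deg[1], al$theta_deg[ev], 360))
  expect_true(all(d <= half_support + 1e-6))
})

test_that("homogeneous Poisson cells match their nominal rate", {
  cfg <- sim_config(duration_s = 600, n_place_cells = 0, n_untuned_cells = 0,
                    n_poisson_cells = 1, poisson_event_rate = 1,
                    rng_seed = 13)
  tr <- simulate_trajectory(cfg)
  sim <- simulate_cells(cfg, tr)
  count <- sum(sim$activity[, 1] > 0)
  expect_lt(abs(count - 600), 3 * sqrt(600))

  cfg2 <- sim_config(duration_s = 1800, n_place_cells = 0,
                     n_untuned_cells = 0, n_poisson_cells = 3,
                     poisson_event_rate = 1, rng_seed = 17)
  tr2 <- simulate_trajectory(cfg2)
  sim2 <- simulate_cells(cfg2, tr2)
  rates <- colSums(sim2$activity > 0) / 1800
  expect_true(all(abs(rates - 1) / 1 < 0.05))
})

test_that("multi-session studies preserve, drift or remap centers as configured", {
  cfg <- sim_config(duration_s = 60, n_place_cells = 30, n_untuned_cells = 0,
                    drift_deg = 0, recurrence_prob = 1, rng_seed = 5)
  st <- simulate_study(cfg, 2, environments = "A")
  expect_identical(st[[1]]$truth$center_deg, st[[2]]$truth$center_deg)

  cfg_r <- sim_config(duration_s = 60, n_place_cells = 103,
                      n_untuned_cells = 0, remap = TRUE, recurrence_prob = 1,
                      rng_seed = 5)
  st_r <- simulate_study(cfg_r, 2, environments = c("A", "B"))
  shifts <- circular_diff(st_r[[1]]$truth$center_deg,
                          st_r[[2]]$truth$center_deg, 360)
  expect_false(all(shifts == 0))
  # independent uniform redraw implies uniform circular shifts
  expect_gt(hodges_ajne_test(shifts)$p, 0.05)

  expect_error(simulate_study(cfg, 2, environments = c("A", NA)),
               "environment")
})

test_that("cell participation across days follows the recurrence probability", {
  cfg <- sim_config(duration_s = 30, n_place_cells = 50, n_untuned_cells = 50,
                    recurrence_prob = 0.9, rng_seed = 19)
  st <- simulate_study(cfg, 2)
  frac <- mean(st[[2]]$truth$participating)
  half_width <- stats::qnorm(0.995) * sqrt(0.9 * 0.1 / 100)
  expect_lt(abs(frac - 0.9), half_width + 1e-12)
})
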