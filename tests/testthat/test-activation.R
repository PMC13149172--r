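planar_movie <- function(speed, angle = 0, noise = TRUE, seed = 1,
                         pitch = 0.01, hw = 64) {
  cfg <- sim_config(height = hw, width = hw, pixel_pitch = pitch,
                    duration = 6, noise_sd = if (noise) NULL else 0,
                    seed = seed, rhythm = rhythm_script(0.67),
                    propagation = propagation_model("planar", speed,
                                                    angle = angle))
  simulate_recording(cfg)$movie
}

test_that("a noiseless planar wave maps to a linear activation ramp", {
  v <- 10
  mv <- planar_movie(v, noise = FALSE)
  tr <- preprocess_trace(extract_trace(mv, "global"))
  b <- detect_beats(tr)
  map <- compute_activation_map(mv, c(b$onset[1] - 0.05, b$onset[2] - 0.05))
  # slope along the propagation axis = pitch / v seconds per pixel
  row <- map$act_time[32, ]
  fit <- stats::coef(stats::lm(row ~ seq_along(row)))
  expect_equal(unname(fit[2]), 0.01 / v, tolerance = 0.01)

  est <- estimate_cv(map)
  expect_equal(est$median_cv, v, tolerance = 0.01)
  expect_false(est$global_activation)
})

test_that("a target wave activates radially at the scripted speed", {
  cfg <- sim_config(height = 64, width = 64, duration = 6, noise_sd = 0,
                    seed = 1, rhythm = rhythm_script(0.67),
                    propagation = propagation_model("target", 10))
  mv <- simulate_recording(cfg)$movie
  est <- recording_cv(mv)
  expect_equal(est$median_cv, 10, tolerance = 0.02)
})

test_that("the conduction velocity estimate is rotation invariant", {
  e0 <- recording_cv(planar_movie(14, angle = 0, noise = FALSE))
  e45 <- recording_cv(planar_movie(14, angle = pi / 4, noise = FALSE))
  expect_equal(e0$median_cv, 14, tolerance = 0.02)
  expect_equal(e45$median_cv, 14, tolerance = 0.02)
  expect_lt(abs(e45$median_cv - e0$median_cv) / 14, 0.02)
})

test_that("doubling the pixel pitch doubles the velocity estimate", {
  mv <- planar_movie(10, noise = FALSE)
  tr <- preprocess_trace(extract_trace(mv, "global"))
  b <- detect_beats(tr)
  map <- compute_activation_map(mv, c(b$onset[1] - 0.05, b$onset[2] - 0.05))
  est1 <- estimate_cv(map)
  map$pixel_pitch <- map$pixel_pitch * 2
  est2 <- estimate_cv(map)
  expect_equal(est2$median_cv, 2 * est1$median_cv, tolerance = 1e-6)
})

test_that("noisy planar waves keep quality and timing accuracy", {
  v <- 10
  cfg <- sim_config(height = 64, width = 64, duration = 6, seed = 4,
                    rhythm = rhythm_script(0.67),
                    propagation = propagation_model("planar", v))
  rec <- simulate_recording(cfg)
  mv <- rec$movie
  tr <- preprocess_trace(extract_trace(mv, "global"))
  b <- detect_beats(tr)
  map <- compute_activation_map(mv, c(b$onset[1] - 0.05, b$onset[2] - 0.05))
  expect_gte(mean(map$quality), 0.95)
  # truth: beat time + column delay
  dly <- delay_field(rec$truth$config$propagation, 64, 64, 0.01)
  truth <- rec$truth$beats$time[1] + dly
  err <- (map$act_time - truth)[map$quality]
  expect_lt(sqrt(mean(err^2)), 0.011)  # RMSE within one frame
})

test_that("noise leaves at most 5% velocity bias across the observed range", {
  for (v in c(5, 20)) {
    est <- recording_cv(planar_movie(v, seed = 2))
    expect_lt(abs(est$median_cv - v) / v, 0.05)
  }
})

test_that("simultaneous activation is flagged, not given a velocity", {
  cfg <- sim_config(height = 32, width = 32, duration = 4, noise_sd = 0,
                    seed = 1, rhythm = rhythm_script(1),
                    propagation = propagation_model("planar", Inf))
  mv <- simulate_recording(cfg)$movie
  tr <- preprocess_trace(extract_trace(mv, "global"))
  b <- detect_beats(tr)
  map <- compute_activation_map(mv, c(b$onset[1] - 0.05, b$onset[1] + 0.4))
  est <- estimate_cv(map, min_quality = 50)
  expect_true(est$global_activation)
  expect_true(is.na(est$median_cv))
})

test_that("degenerate maps raise errors", {
  mv <- planar_movie(10, noise = FALSE, hw = 8)
  tr <- preprocess_trace(extract_trace(mv, "global"))
  b <- detect_beats(tr)
  map <- compute_activation_map(mv, c(b$onset[1] - 0.05, b$onset[2] - 0.05))
  expect_error(estimate_cv(map), "too few quality pixels")
  flat <- fluor_movie(array(1, c(50, 16, 16)), 100, 0.01, "voltage")
  expect_error(compute_activation_map(flat, c(0, 0.4)),
               "no detectable activation")
})
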