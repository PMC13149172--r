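test_that("HDF5 round trip is bit-exact and carries metadata", {
  rec <- sim_trace_rec(rhythm_script(1), seed = 5)
  cfg <- sim_config(height = 8, width = 8, duration = 2, seed = 5,
                    modality = "calcium", pixel_pitch = 0.02,
                    recording_id = "rt")
  mv <- simulate_recording(cfg)$movie
  p <- file.path(withr::local_tempdir(), "m.h5")
  write_movie(mv, p)
  back <- read_movie(p)
  expect_identical(back$frames, mv$frames)
  expect_equal(back$frame_rate, mv$frame_rate)
  expect_equal(back$pixel_pitch, mv$pixel_pitch)
  expect_equal(back$modality, "calcium")
  expect_equal(back$recording_id, "rt")
})

test_that("TIFF round trip preserves values", {
  # data already in [0,1]: stored as exact float32
  arr <- array(rep(c(0.09, 0.46), each = 32), dim = c(2, 4, 8))
  arr <- arr[rep(1:2, 5), , , drop = FALSE]
  mv <- fluor_movie(arr, 100, 0.01, "calcium", "small")
  td <- withr::local_tempdir()
  p1 <- file.path(td, "a.tif")
  write_movie(mv, p1)
  back <- read_movie(p1)
  expect_lt(max(abs(back$frames - mv$frames)), 1e-6)
  expect_equal(back$modality, "calcium")

  # out-of-range data: affine packing recorded in the sidecar
  cfg <- sim_config(height = 8, width = 8, duration = 2, seed = 3)
  mv2 <- simulate_recording(cfg)$movie
  expect_gt(max(mv2$frames), 1)  # voltage amplitude 1 + noise
  p2 <- file.path(td, "b.tif")
  write_movie(mv2, p2)
  back2 <- read_movie(p2)
  rel <- max(abs(back2$frames - mv2$frames)) / diff(range(mv2$frames))
  expect_lt(rel, 1e-6)
})

test_that("degenerate and invalid movies are rejected", {
  td <- withr::local_tempdir()
  p <- file.path(td, "single.tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), p)
  expect_error(read_movie(p, frame_rate = 100, pixel_pitch = 0.01,
                          modality = "voltage"), "single image")
  expect_error(read_movie(file.path(td, "nope.tif")), "not found")
  expect_error(fluor_movie(array(0, c(1, 4, 4)), 100, 0.01), "fewer than 2")
  expect_error(fluor_movie(matrix(0, 4, 4), 100, 0.01), "3-D")
  expect_error(fluor_movie(array(0, c(5, 4, 4)), -1, 0.01), "frame_rate")
  expect_error(fluor_movie(array(0, c(5, 4, 4)), 100, 0), "pixel_pitch")
  expect_error(fluor_movie(array(NA_real_, c(5, 4, 4)), 100, 0.01),
               "finite")
})

test_that("extract_trace averages the requested ROI", {
  # every pixel at frame t equals t-1 (0-based time index)
  arr <- array(rep(0:9, 16), dim = c(10, 4, 4))
  mv <- fluor_movie(arr, 10, 0.01, "voltage")
  expect_equal(extract_trace(mv, "global")$values, as.numeric(0:9))

  # single pixel: that pixel's series exactly
  arr2 <- array(stats::rnorm(10 * 4 * 4), dim = c(10, 4, 4))
  mv2 <- fluor_movie(arr2, 10, 0.01, "voltage")
  expect_equal(extract_trace(mv2, cbind(2, 3))$values, arr2[, 2, 3])
  expect_equal(extract_trace(mv2, cbind(2, 3))$source, "pixel")

  # two-pixel ROI: the mean
  roi <- rbind(c(1, 1), c(4, 4))
  expect_equal(extract_trace(mv2, roi)$values,
               (arr2[, 1, 1] + arr2[, 4, 4]) / 2)

  # rectangle
  expect_equal(extract_trace(mv2, c(1, 2, 1, 2))$values,
               apply(arr2[, 1:2, 1:2], 1, mean))

  expect_error(extract_trace(mv2, cbind(5, 1)), "out of bounds")
  expect_error(extract_trace(mv2, matrix(numeric(0), 0, 2)), "non-empty")
})

test_that("extract_trace is linear in the movie", {
  a1 <- array(stats::rnorm(10 * 3 * 3), dim = c(10, 3, 3))
  a2 <- array(stats::rnorm(10 * 3 * 3), dim = c(10, 3, 3))
  m1 <- fluor_movie(a1, 10, 0.01, "voltage")
  m2 <- fluor_movie(a2, 10, 0.01, "voltage")
  ms <- fluor_movie(a1 + a2, 10, 0.01, "voltage")
  roi <- rbind(c(1, 2), c(3, 1), c(2, 2))
  expect_equal(extract_trace(ms, roi)$values,
               extract_trace(m1, roi)$values + extract_trace(m2, roi)$values)
})

test_that("trace CSV round trip recovers values and sampling rate", {
  rec <- sim_trace_rec(rhythm_script(1), seed = 2)
  tr <- global_trace(rec)
  p <- file.path(withr::local_tempdir(), "t.csv")
  write_trace_csv(tr, p)
  back <- read_trace_csv(p, "voltage")
  expect_equal(back$frame_rate, tr$frame_rate)
  expect_equal(back$values, tr$values, tolerance = 1e-12)
})
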