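test_that("preprocessing is the identity when both steps are off", {
  tr <- global_trace(sim_trace_rec(rhythm_script(1), seed = 2))
  out <- preprocess_trace(tr, smooth = FALSE, detrend = FALSE)
  expect_equal(out$values, tr$values)

  # constant trace stays constant under detrending
  cst <- fluor_trace(rep(2.5, 500), 100, "voltage")
  out2 <- preprocess_trace(cst, smooth = FALSE, detrend = TRUE)
  expect_equal(out2$values, cst$values, tolerance = 1e-10)
})

test_that("detrending removes linear drift without moving the a.u. level", {
  rec <- sim_trace_rec(rhythm_script(1), duration = 20, noise_sd = 0)
  clean <- global_trace(rec)
  drift <- 0.01 * trace_times(clean)  # 0.01 a.u./s
  drifted <- fluor_trace(clean$values + drift, clean$frame_rate, "voltage")
  fixed <- preprocess_trace(drifted, smooth = FALSE, detrend = TRUE,
                            detrend_degree = 1)
  # within 1% of the transient amplitude of the driftless twin,
  # up to a common offset that preserves the mean level
  err <- fixed$values - clean$values
  expect_lt(max(abs(err - mean(err))), 0.01)
  expect_equal(mean(fixed$values), mean(drifted$values), tolerance = 1e-6)
})

test_that("smoothing window bounds are enforced", {
  tr <- fluor_trace(stats::rnorm(50), 100, "voltage")
  expect_error(preprocess_trace(tr, smooth_window = 2), "longer than")
})

test_that("beats are detected at their scripted times", {
  # noiseless beats near 0.5/1.5/2.5 s detected within one frame
  rec <- sim_trace_rec(rhythm_script(1), duration = 3, noise_sd = 0)
  tr <- preprocess_trace(global_trace(rec))
  b <- detect_beats(tr)
  expect_equal(nrow(b), nrow(rec$truth$beats))
  expect_lt(max(abs(b$onset - rec$truth$beats$time)), 0.011)

  # flat trace: no events
  flat <- fluor_trace(rep(1, 300), 100, "voltage")
  expect_equal(nrow(detect_beats(flat)), 0L)

  # pure-noise trace: no events either (robust floor)
  set.seed(9)
  noisy <- preprocess_trace(fluor_trace(stats::rnorm(1000, sd = 0.05),
                                        100, "voltage"))
  expect_equal(nrow(detect_beats(noisy)), 0L)
})

test_that("detection matches ground truth at SNR 20 with no spurious events", {
  n_match <- 0; n_true <- 0; n_spur <- 0
  for (seed in 1:10) {
    rec <- sim_trace_rec(rhythm_script(1, jitter_cv = 0.05),
                         duration = 30, seed = seed)
    tr <- preprocess_trace(global_trace(rec))
    det <- detect_beats(tr)$time
    truth <- rec$truth$beats$time
    n_true <- n_true + length(truth)
    used <- rep(FALSE, length(det))
    for (t0 in truth) {
      j <- which(!used & abs(det - t0) <= 0.021)  # within 2 frames
      if (length(j)) { used[j[1]] <- TRUE; n_match <- n_match + 1 }
    }
    n_spur <- n_spur + sum(!used)
  }
  expect_gte(n_match / n_true, 0.99)
  expect_lte(n_spur / 10, 0.0)  # zero spurious per recording on average
})

test_that("a square pulse yields step geometry", {
  fps <- 100
  v <- rep(0, 200)
  v[51:80] <- 1  # 0.30 s wide, baseline 0, amplitude 1
  tr <- fluor_trace(v, fps, "voltage")
  m <- measure_beats(tr, detect_beats(tr))
  expect_equal(nrow(m), 1L)
  expect_lt(abs(m$amplitude - 1), 0.05)
  expect_lt(abs(m$d80 - 0.30), 0.011)
  expect_lt(m$tri, 0.011)
})

test_that("interrupted repolarization censors the unreached fractions", {
  # next beat arrives 0.4 s later while D90 is 0.6 s: D90 censored,
  # D30 (0.23 s) still reported. The first beat rises from the true
  # diastolic baseline, so its D30 matches the template; later beats are
  # measured against their own (elevated) pre-upstroke baseline by design.
  tpl <- solve_template(0.02, 0.23, 0.6)
  rec <- sim_trace_rec(rhythm_script(2.5), duration = 8, noise_sd = 0,
                       waveform = tpl)
  m <- quick_metrics(rec)
  expect_true(is.na(m$d90[1]))
  expect_true(m$censored[1])
  expect_true(all(!is.na(m$d30)))
  expect_lt(abs(m$d30[1] - 0.23), 0.012)
})

test_that("beats with no discernible transient are rejected with a message", {
  tr <- fluor_trace(c(rep(0, 50), seq(0, 1, length.out = 5),
                      rep(1, 145)), 100, "voltage")
  # fabricate an activation in the flat tail: no amplitude there
  expect_message(out <- measure_beat(tr, 1.9), "rejected")
  expect_null(out)
})

test_that("Fridericia correction has its closed-form properties", {
  expect_equal(fridericia_correct(0.2, 1), 0.2)
  expect_equal(fridericia_correct(0.2, 0.512), 0.25)  # 0.512^(1/3) = 0.8
  expect_equal(fridericia_correct(0.14, 1 / 1.28),
               0.14 * 1.28^(1 / 3), tolerance = 1e-12)
  # homogeneity: scaling D80 scales the output
  expect_equal(fridericia_correct(3 * 0.11, 0.7),
               3 * fridericia_correct(0.11, 0.7))
  expect_true(is.na(fridericia_correct(0.2, NA)))
  expect_error(fridericia_correct(0.2, -1), "positive")
})

test_that("spontaneous frequency counts intervals, not beats", {
  f <- spontaneous_frequency(0:9, 10)
  expect_equal(as.numeric(f), 1)
  expect_false(attr(f, "quiescent"))
  f1 <- spontaneous_frequency(12.3, 30)
  expect_equal(as.numeric(f1), 0)
  expect_true(attr(f1, "quiescent"))
  f0 <- spontaneous_frequency(numeric(0), 30)
  expect_true(attr(f0, "quiescent"))
})

test_that("isoproterenol response is the mean of per-syncytium ratios", {
  pre <- data.frame(recording_id = c("a", "b", "c"),
                    frequency = c(0.5, 0.5, 0.5))
  post <- data.frame(recording_id = c("a", "b", "c"),
                     frequency = c(1.5, 2.0, 2.5))
  r <- iso_response(pre, post, "frequency")
  expect_equal(r$ratio, c(3, 4, 5))
  expect_equal(attr(r, "mean_ratio"), 4)

  # identical summaries give ratio 1 everywhere
  r1 <- iso_response(pre, pre, "frequency")
  expect_equal(r1$ratio, rep(1, 3))

  # zero pre-values are excluded with a message
  pre0 <- data.frame(recording_id = c("a", "b"), frequency = c(0, 0.5))
  post0 <- data.frame(recording_id = c("a", "b"), frequency = c(1, 1))
  expect_message(r0 <- iso_response(pre0, post0, "frequency"), "zero")
  expect_equal(r0$recording_id, "b")
})

test_that("recovery fractions are ordered on every synthetic beat", {
  # property: D30 <= D80 <= D90 and tri = D90 - D30 >= 0
  for (seed in 1:6) {
    md <- if (seed %% 2) "voltage" else "calcium"
    rec <- sim_trace_rec(rhythm_script(0.8, jitter_cv = 0.1),
                         duration = 20, modality = md, seed = seed)
    m <- quick_metrics(rec)
    ok <- !m$censored
    expect_true(all(m$d30[ok] <= m$d80[ok] + 1e-12))
    expect_true(all(m$d80[ok] <= m$d90[ok] + 1e-12))
    expect_true(all(m$tri[ok] >= -1e-12))
  }
})

test_that("group-level parameter recovery meets tolerance", {
  # noiseless: D80 within one frame; SNR 20: within 5% for D80,
  # baseline, amplitude, frequency
  tpl <- default_waveform("voltage")
  d80_true <- template_duration(tpl, 0.8)
  for (noise in c(0, NA)) {  # NA = default SNR 20
    vals <- sapply(1:8, function(seed) {
      rec <- sim_trace_rec(rhythm_script(1, jitter_cv = 0.03),
                           duration = 10, seed = seed,
                           noise_sd = if (is.na(noise)) NULL else noise)
      m <- quick_metrics(rec)
      ok <- !m$censored
      c(d80 = mean(m$d80[ok]), base = mean(m$baseline),
        amp = mean(m$amplitude),
        f = as.numeric(spontaneous_frequency(m$activation_time, 10)))
    })
    mm <- rowMeans(vals)
    if (is.na(noise)) {
      expect_lt(abs(mm["d80"] - d80_true) / d80_true, 0.05)
      expect_lt(abs(mm["base"] - tpl$baseline), 0.05 * tpl$amplitude)
      expect_lt(abs(mm["amp"] - tpl$amplitude) / tpl$amplitude, 0.05)
      expect_lt(abs(mm["f"] - 1), 0.05)
    } else {
      expect_lt(abs(mm["d80"] - d80_true), 0.011)
    }
  }
})
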