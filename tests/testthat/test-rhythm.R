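test_that("classification rules fire on their scripted phenotypes", {
  # regular WT-like rhythm: exclusively normal
  a <- classify_rhythm(seq(0.5, 9.5, by = 1 / 0.67), 10)
  expect_equal(a$labels, "normal")
  expect_false(a$arrhythmic)

  # regular 2.5 Hz: tachyarrhythmia at the default threshold
  a2 <- classify_rhythm(seq(0.2, 29.8, by = 0.4), 30)
  expect_true("tachyarrhythmia" %in% a2$labels)
  expect_true(a2$arrhythmic)

  # 6-s silent gap: quiescence
  beats <- c(seq(0.5, 10, by = 1), seq(16.5, 29.5, by = 1))
  a3 <- classify_rhythm(beats, 30)
  expect_true("quiescence" %in% a3$labels)

  # slow but regular: bradyarrhythmia, not quiescence
  a4 <- classify_rhythm(seq(5, 25, by = 10), 30)
  expect_true("bradyarrhythmia" %in% a4$labels)
  expect_false("quiescence" %in% a4$labels)

  # zero beats: quiescence
  a5 <- classify_rhythm(numeric(0), 30)
  expect_equal(a5$labels, "quiescence")

  # jittered intervals: irregular
  set.seed(1)
  ib <- stats::rgamma(25, shape = 4, rate = 4)  # CV 0.5
  a6 <- classify_rhythm(cumsum(ib), 30)
  expect_true("irregular" %in% a6$labels)
})

test_that("raising the tachycardia threshold never adds the label", {
  beats <- seq(0.2, 29.8, by = 0.4)  # 2.5 Hz
  fired <- sapply(c(1, 2, 2.4, 2.6, 4), function(fh)
    "tachyarrhythmia" %in%
      classify_rhythm(beats, 30, thresholds = list(f_hi = fh))$labels)
  expect_false(is.unsorted(rev(fired)))  # monotone: TRUE...FALSE
  expect_true(fired[1]); expect_false(fired[5])
})

test_that("a reference cohort rate rescales the tachycardia rule", {
  beats <- seq(0.5, 29.5, by = 1 / 1.28)  # 1.28 Hz, below f_hi = 2
  expect_equal(classify_rhythm(beats, 30)$labels, "normal")
  # relative rule: 2.5 x 0.38 Hz reference = 0.95 Hz threshold
  a <- classify_rhythm(beats, 30, reference_freq = 0.38)
  expect_true("tachyarrhythmia" %in% a$labels)
})

test_that("classification is deterministic given beats and thresholds", {
  set.seed(3)
  beats <- cumsum(stats::rgamma(20, 9, 9))
  a1 <- classify_rhythm(beats, 30)
  a2 <- classify_rhythm(beats, 30)
  expect_identical(a1$labels, a2$labels)
  expect_identical(a1$evidence, a2$evidence)
})

test_that("scripted EAD bumps are detected and sub-threshold ones are not", {
  mk <- function(delta, seed = 1) {
    rec <- sim_trace_rec(
      rhythm_script(0.4, ead = data.frame(beat = 2, delta = delta,
                                          phase = 0.6)),
      duration = 30, modality = "calcium", seed = seed)
    tr <- preprocess_trace(global_trace(rec))
    m <- measure_beats(tr)
    detect_ead(tr, m)
  }
  for (seed in 1:4) {
    counts <- mk(0.15, seed)
    expect_gte(sum(counts), 1)
    expect_gte(counts[2], 1)  # on the scripted beat
    expect_equal(sum(mk(0.05, seed)), 0)
  }
})

test_that("clean template beats yield no EAD events", {
  for (md in c("voltage", "calcium")) {
    rec <- sim_trace_rec(rhythm_script(0.6, jitter_cv = 0.03),
                         duration = 20, modality = md, seed = 7)
    tr <- preprocess_trace(global_trace(rec))
    m <- measure_beats(tr)
    expect_equal(sum(detect_ead(tr, m)), 0)
  }
})

test_that("well-separated phenotype cohorts classify perfectly", {
  # every scripted parameter is at least 2x beyond its threshold
  specs <- list(
    tachy = list(rhythm = rhythm_script(4), md = "voltage",
                 tpl = fast_ap_template(), label = "tachyarrhythmia"),
    brady = list(rhythm = rhythm_script(0.1), md = "voltage", tpl = NULL,
                 label = "bradyarrhythmia"),
    quiesc = list(rhythm = rhythm_script(1, quiescent = list(c(8, 12))),
                  md = "voltage", tpl = NULL, label = "quiescence"),
    irreg = list(rhythm = rhythm_script(1, jitter_cv = 0.45),
                 md = "voltage", tpl = NULL, label = "irregular"),
    ead = list(rhythm = rhythm_script(
      0.4, ead = data.frame(beat = 2:3, delta = 0.25, phase = 0.55)),
      md = "calcium", tpl = NULL, label = "EAD"),
    normal = list(rhythm = rhythm_script(0.67, jitter_cv = 0.03),
                  md = "voltage", tpl = NULL, label = "normal"))
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    for (seed in 1:3) {
      rec <- sim_trace_rec(sp$rhythm, duration = 30, modality = sp$md,
                           seed = seed, waveform = sp$tpl)
      res <- analyze_trace(global_trace(rec))
      expect_true(sp$label %in% res$assessment$labels,
                  info = sprintf("%s seed %d got %s", nm, seed,
                                 paste(res$assessment$labels,
                                       collapse = "+")))
      if (nm == "normal")
        expect_false(res$assessment$arrhythmic)
    }
  }
})
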