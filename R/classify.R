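#' Default rhythm-classification thresholds
#'
#' All rule thresholds are configurable and every assessment records the
#' values it used. Defaults: tachyarrhythmia above 2.0 Hz (well above the
#' normal spontaneous range of matured ventricular syncytia),
#' bradyarrhythmia below 0.2 Hz, quiescence when any silent gap exceeds
#' `max(5 s, 3 x median inter-beat interval)` (the relative guard keeps
#' slow-but-regular rhythms from being called arrested), irregularity when
#' the inter-beat-interval coefficient of variation exceeds 0.20 with at
#' least 5 beats, and EADs when a secondary re-elevation of at least 10%
#' of the beat amplitude occurs during late repolarization.
#'
#' @return named list of thresholds.
#' @export
rhythm_thresholds <- function() {
  list(f_hi = 2.0,        # Hz, tachyarrhythmia
       f_lo = 0.2,        # Hz, bradyarrhythmia
       f_hi_ref_mult = 2.5,  # x reference mean frequency, when supplied
       gap_abs = 5,       # s, quiescence (absolute)
       gap_rel = 3,       # x median IBI, quiescence (relative)
       ibi_cv = 0.20,     # irregularity
       min_beats_irregular = 5L,
       ead_delta = 0.10)  # fraction of beat amplitude
}

# Mexican-hat (negative second derivative of a Gaussian) matched filter
# at scale s seconds, normalized so that convolving a Gaussian bump of
# height h and width s yields a peak response of h.
mexhat_response <- function(v, fps, s) {
  xs <- seq(-4 * s, 4 * s, by = 1 / fps)
  k <- (1 - xs^2 / s^2) * exp(-xs^2 / (2 * s^2))
  ref <- exp(-xs^2 / (2 * s^2))
  norm <- max(stats::convolve(ref, rev(k), type = "open"))
  as.numeric(stats::filter(v, k / norm, sides = 2))
}

#' Detect early afterdepolarizations within measured beats
#'
#' An EAD is a secondary depolarizing deflection of at least `delta`
#' times the beat amplitude occurring after the signal has recovered past
#' 30% but before 90% recovery completes, and not attributable to the
#' next detected beat. Deflections are scored with Mexican-hat matched
#' filters over a small set of time scales, normalized so the response to
#' a bump equals its height: a smooth monotone repolarization (of any
#' curvature) scores near zero, so the statistic isolates the
#' superimposed bump rather than its net re-elevation against the
#' ongoing decay.
#'
#' @param trace the (preprocessed) [fluor_trace()] the beats were measured
#'   on.
#' @param metrics beat table from [measure_beats()].
#' @param delta detection threshold as a fraction of beat amplitude.
#' @param scales bump time scales to probe, s; default
#'   `c(0.01, 0.02, 0.04)` for voltage and `c(0.03, 0.06, 0.1)` for
#'   calcium, spanning the physiological widths of afterdepolarization
#'   deflections for each dye's kinetics.
#' @param floor_mult per-scale noise floor: deflections must also exceed
#'   `floor_mult` (default 5) times the robust spread (mad) of that scale's response
#'   over the whole trace, so noise-dominated fine scales cannot trigger.
#' @return integer vector of EAD counts, one per row of `metrics`.
#' @export
detect_ead <- function(trace, metrics, delta = rhythm_thresholds()$ead_delta,
                       scales = NULL, floor_mult = 5) {
  stopifnot(inherits(trace, "fluor_trace"))
  fps <- trace$frame_rate
  v <- trace$values
  nT <- length(v)
  counts <- integer(nrow(metrics))
  if (!nrow(metrics)) return(counts)
  if (is.null(scales))
    scales <- if (identical(trace$modality, "calcium"))
      c(0.03, 0.06, 0.1) else c(0.01, 0.02, 0.04)
  resp <- lapply(scales, function(s) mexhat_response(v, fps, s))
  # noise floor calibrated on diastolic (inter-beat) samples, where the
  # response reflects noise alone; falls back to the whole trace when a
  # recording leaves too little diastole
  pad <- 2 * max(scales)
  quiet <- logical(nT)
  ends <- metrics$activation_time + metrics$d90
  for (k in seq_len(nrow(metrics))) {
    q0 <- if (is.na(ends[k])) NA else ends[k] + pad
    q1 <- (if (k < nrow(metrics)) metrics$onset[k + 1L]
           else (nT - 1) / fps) - pad
    if (!is.na(q0) && q1 > q0)
      quiet[(1L + ceiling(q0 * fps)):(1L + floor(q1 * fps))] <- TRUE
  }
  if (metrics$onset[1L] > 2 * pad)
    quiet[seq_len(1L + floor((metrics$onset[1L] - pad) * fps))] <- TRUE
  floors <- vapply(resp, function(r) {
    base <- if (sum(quiet) >= 50L) r[quiet] else r
    floor_mult * stats::mad(base, na.rm = TRUE)
  }, numeric(1))
  for (k in seq_len(nrow(metrics))) {
    b <- metrics[k, ]
    if (is.na(b$d30)) next
    t0 <- b$activation_time + b$d30
    t1 <- b$activation_time +
      if (!is.na(b$d90)) b$d90
      else if (k < nrow(metrics)) metrics$onset[k + 1L] - b$activation_time
      else (nT - 1) / fps - b$activation_time
    if (k < nrow(metrics)) t1 <- min(t1, metrics$onset[k + 1L])
    n_ead <- 0L
    for (j in seq_along(scales)) {
      s <- scales[j]
      # a scale is only meaningful if its support fits inside the
      # repolarization span; coarser scales respond to the decay's own
      # concavity rather than to a superimposed deflection
      if (4 * s > t1 - t0) next
      # keep the filter support clear of the sharp corners (this beat's
      # peak, the next beat's upstroke) whose curvature would otherwise
      # dominate the response; the d30/d90 crossings themselves are not
      # corners and need no margin
      lo <- max(t0, b$peak_time + 2.5 * s)
      hi <- t1 - if (k < nrow(metrics)) 0 else 0
      if (k < nrow(metrics)) hi <- min(hi, metrics$onset[k + 1L] - 2.5 * s)
      i0 <- max(1L, 1L + ceiling(lo * fps))
      i1 <- min(nT, 1L + floor(hi * fps))
      if (i1 - i0 < 2L) next
      r <- resp[[j]][i0:i1]
      r[is.na(r)] <- 0
      # count distinct suprathreshold response peaks at this scale
      above <- r >= max(delta * b$amplitude, floors[j])
      if (!any(above)) next
      runs <- rle(above)
      n_ead <- max(n_ead, sum(runs$values))
    }
    counts[k] <- n_ead
  }
  counts
}

#' Rule-based rhythm classification of one recording
#'
#' Assigns the label set {normal, tachyarrhythmia, bradyarrhythmia,
#' quiescence, irregular, EAD} from the detected beats and (optionally)
#' per-beat EAD counts. `normal` is exclusive: it is assigned iff no other
#' rule fires, and `arrhythmic` is true iff the labels differ from
#' {normal}. The decision is deterministic given beats and thresholds.
#'
#' Rules (defaults in [rhythm_thresholds()]):
#' * tachyarrhythmia: frequency above `f_hi`; when `reference_freq` is
#'   supplied (a control cohort's mean rate), `f_hi` is replaced by
#'   `f_hi_ref_mult * reference_freq`, flagging an abnormal increase
#'   relative to that reference.
#' * bradyarrhythmia: `0 < frequency < f_lo`.
#' * quiescence: zero beats, or any silent gap (including the leading and
#'   trailing gaps of the window) longer than
#'   `max(gap_abs, gap_rel * median IBI)`.
#' * irregular: IBI coefficient of variation above `ibi_cv` with at least
#'   `min_beats_irregular` beats.
#' * EAD: any beat with a detected early afterdepolarization.
#'
#' @param beat_times activation times, s.
#' @param window analysis window length, s.
#' @param ead_counts optional integer vector from [detect_ead()].
#' @param thresholds list as from [rhythm_thresholds()]; partial overrides
#'   allowed.
#' @param reference_freq optional reference mean frequency, Hz.
#' @return object of class `rhythm_assessment`: `labels`, `arrhythmic`,
#'   `evidence` (frequency, IBI CV, longest gap, EAD count), `thresholds`.
#' @export
classify_rhythm <- function(beat_times, window, ead_counts = NULL,
                            thresholds = list(), reference_freq = NULL) {
  stopifnot(window > 0)
  th <- utils::modifyList(rhythm_thresholds(), thresholds)
  f_hi <- if (!is.null(reference_freq)) th$f_hi_ref_mult * reference_freq
          else th$f_hi
  n <- length(beat_times)
  f <- as.numeric(spontaneous_frequency(beat_times, window))
  ibi <- diff(beat_times)
  gaps <- if (n) c(beat_times[1], ibi, window - beat_times[n]) else window
  longest_gap <- max(gaps)
  gap_thr <- max(th$gap_abs,
                 if (length(ibi)) th$gap_rel * stats::median(ibi) else 0)
  # irregularity is judged on the beating intervals themselves; silent
  # gaps are the quiescence rule's evidence, not irregularity's
  ibi_beat <- ibi[ibi <= gap_thr]
  ibi_cv <- if (length(ibi_beat) >= 2)
    stats::sd(ibi_beat) / mean(ibi_beat) else NA_real_
  n_ead <- if (is.null(ead_counts)) 0L else sum(ead_counts)

  labels <- character(0)
  if (f > f_hi) labels <- c(labels, "tachyarrhythmia")
  if (f > 0 && f < th$f_lo) labels <- c(labels, "bradyarrhythmia")
  if (n == 0 || longest_gap > gap_thr) labels <- c(labels, "quiescence")
  if (!is.na(ibi_cv) && n >= th$min_beats_irregular && ibi_cv > th$ibi_cv)
    labels <- c(labels, "irregular")
  if (n_ead > 0) labels <- c(labels, "EAD")
  if (!length(labels)) labels <- "normal"

  structure(list(labels = labels,
                 arrhythmic = !identical(labels, "normal"),
                 evidence = list(frequency = f, ibi_cv = ibi_cv,
                                 longest_gap = longest_gap,
                                 gap_threshold = gap_thr,
                                 n_ead = n_ead, n_beats = n),
                 thresholds = c(th, f_hi_used = f_hi)),
            class = "rhythm_assessment")
}

#' @export
print.rhythm_assessment <- function(x, ...) {
  e <- x$evidence
  cat(sprintf("<rhythm_assessment> %s%s\n",
              paste(x$labels, collapse = "+"),
              if (x$arrhythmic) " [arrhythmic]" else ""))
  cat(sprintf("  f=%.3g Hz, IBI CV=%.3g, longest gap=%.3g s, EADs=%d, beats=%d\n",
              e$frequency, e$ibi_cv, e$longest_gap, e$n_ead, e$n_beats))
  invisible(x)
}
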