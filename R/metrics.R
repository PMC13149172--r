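#' Condition a trace before beat analysis
#'
#' Optional Savitzky-Golay smoothing and slow-drift removal. Detrending
#' estimates the slow baseline as a long-window rolling percentile, fits a
#' low-order polynomial to that baseline (this removes the edge bias a
#' truncated rolling window would otherwise leave), subtracts the fit and
#' re-adds its mean — so the absolute a.u. level of the trace is preserved,
#' which matters because diastolic baseline fluorescence is itself a
#' reported metric.
#'
#' @param trace a [fluor_trace()].
#' @param smooth logical; apply Savitzky-Golay smoothing (order 3).
#' @param smooth_window smoothing window, seconds (rounded to an odd number
#'   of samples, minimum 5).
#' @param detrend logical; remove slow drift.
#' @param detrend_window rolling-percentile window, seconds.
#' @param detrend_quantile percentile tracked as the slow baseline
#'   (low, so it rides the diastolic level rather than the transients).
#' @param detrend_degree polynomial degree fitted to the rolling baseline.
#' @return a [fluor_trace()]; the parameters used are attached as the
#'   `"preprocess"` attribute (every conditioning step is logged).
#' @export
preprocess_trace <- function(trace, smooth = TRUE, smooth_window = 0.05,
                             detrend = FALSE, detrend_window = 5,
                             detrend_quantile = 0.1, detrend_degree = 2) {
  stopifnot(inherits(trace, "fluor_trace"))
  v <- trace$values
  fps <- trace$frame_rate
  nT <- length(v)
  if (detrend) {
    w <- min(max(3L, round(detrend_window * fps)), nT)
    base_raw <- zoo::rollapply(v, width = w, FUN = stats::quantile,
                               probs = detrend_quantile, names = FALSE,
                               partial = TRUE, align = "center")
    tt <- seq_len(nT) / fps
    X <- cbind(1, stats::poly(tt, degree = detrend_degree, raw = TRUE))
    fit <- stats::lm.fit(X, base_raw)
    base_fit <- drop(X %*% fit$coefficients)
    v <- v - base_fit + mean(base_fit)
  }
  if (smooth) {
    n <- round(smooth_window * fps)
    n <- max(5L, n + (1L - n %% 2L))  # odd, >= 5
    if (n < 3L) stop("smoothing window must span at least 3 samples")
    if (n > nT) stop("smoothing window longer than the trace")
    v <- signal::sgolayfilt(v, p = 3, n = n)
  }
  out <- fluor_trace(v, fps, trace$modality, trace$source, trace$origin)
  attr(out, "preprocess") <- list(smooth = smooth,
                                  smooth_window = smooth_window,
                                  detrend = detrend,
                                  detrend_window = detrend_window,
                                  detrend_quantile = detrend_quantile,
                                  detrend_degree = detrend_degree)
  out
}

# Savitzky-Golay first-derivative estimate (a.u./s), same length as v.
# The window should span roughly the upstroke duration: long enough to
# average noise, short enough not to flatten the rising limb. The filter
# half-width (where edge fits are unreliable) is attached as "halfwidth".
sg_derivative <- function(v, fps, window) {
  n <- round(window * fps)
  n <- max(5L, n + (1L - n %% 2L))
  n <- min(n, length(v) - (1L - length(v) %% 2L))
  out <- signal::sgolayfilt(v, p = 3, n = n, m = 1, ts = 1 / fps)
  attr(out, "halfwidth") <- (n - 1L) %/% 2L
  out
}

# Default derivative window by modality: matched to typical optical
# upstroke kinetics (fast voltage dyes ~20 ms, calcium dyes ~100 ms).
deriv_window_default <- function(modality) {
  if (identical(modality, "calcium")) 0.09 else 0.03
}

# Parabolic sub-sample refinement of a discrete peak at index i of y;
# returns the fractional offset in [-0.5, 0.5].
parabolic_offset <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(0)
  den <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (den >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (y[i - 1L] - y[i + 1L]) / den))
}

#' Detect spontaneous activations in a trace
#'
#' Events are contiguous excursions of the first derivative above a
#' threshold set as a fraction of the recording's maximum derivative (with
#' a robust noise floor so a beat-free trace yields no events). The
#' activation time of each event is the sub-frame (parabolic-interpolated)
#' time of the derivative peak; events closer than the refractory window
#' are merged, keeping the one with the larger peak rate.
#'
#' @param trace a (preferably [preprocess_trace()]d) [fluor_trace()].
#' @param threshold_frac derivative threshold as a fraction of the maximum
#'   smoothed derivative (default 0.2).
#' @param refractory minimum event separation, s (default 0.1).
#' @param noise_mult robust noise floor: the threshold is never below
#'   `noise_mult` times the derivative's high-frequency noise scale
#'   (`mad(diff(d))/sqrt(2)`, which ignores the slow signal component), so
#'   a beat-free noisy trace yields no events (default 8).
#' @param deriv_window Savitzky-Golay first-derivative window, s; default
#'   matched to the modality's upstroke kinetics (0.03 s voltage, 0.09 s
#'   calcium).
#' @return data frame with one row per detected beat: `onset` (time the
#'   derivative first crossed threshold, s), `time` (refined
#'   derivative-peak time, s), `peak_rate` (a.u./s). Zero rows is a valid
#'   result (flat or quiescent trace).
#' @export
detect_beats <- function(trace, threshold_frac = 0.2, refractory = 0.1,
                         noise_mult = 8, deriv_window = NULL) {
  stopifnot(inherits(trace, "fluor_trace"))
  v <- trace$values
  fps <- trace$frame_rate
  if (is.null(deriv_window)) deriv_window <- deriv_window_default(trace$modality)
  d <- sg_derivative(v, fps, deriv_window)
  td <- (seq_along(d) - 1) / fps
  empty <- data.frame(onset = numeric(0), time = numeric(0),
                      peak_rate = numeric(0))
  dmax <- max(d)
  if (!(dmax > 0)) return(empty)
  thr <- max(threshold_frac * dmax,
             noise_mult * stats::mad(diff(d)) / sqrt(2))
  r <- rle(d > thr)
  if (!any(r$values)) return(empty)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  hw <- attr(d, "halfwidth")
  ev <- lapply(which(keep), function(j) {
    i1 <- starts[j]; i2 <- ends[j]
    ipk <- i1 - 1L + which.max(d[i1:i2])
    # the filter's edge fits are unreliable; drop boundary artifacts
    if (ipk <= hw || ipk > length(d) - hw) return(NULL)
    off <- parabolic_offset(d, ipk)
    c(onset = td[i1], time = td[ipk] + off / fps, peak_rate = d[ipk])
  })
  ev <- ev[!vapply(ev, is.null, logical(1))]
  if (!length(ev)) return(empty)
  ev <- as.data.frame(do.call(rbind, ev))
  # merge events within the refractory window (keep the larger one)
  if (nrow(ev) > 1L) {
    keep_idx <- rep(TRUE, nrow(ev))
    i <- 1L
    while (i < nrow(ev)) {
      j <- i + 1L
      while (j <= nrow(ev) && keep_idx[j] == FALSE) j <- j + 1L
      if (j > nrow(ev)) break
      if (ev$time[j] - ev$time[i] < refractory) {
        if (ev$peak_rate[j] > ev$peak_rate[i]) {
          keep_idx[i] <- FALSE; i <- j
        } else keep_idx[j] <- FALSE
      } else i <- j
    }
    ev <- ev[keep_idx, , drop = FALSE]
    rownames(ev) <- NULL
  }
  ev
}

# Core single-beat measurement. v/fps: trace samples and rate; onset_time:
# detection onset (threshold crossing); end_time: next beat's onset or
# trace end; deriv: optional precomputed SG derivative. Returns a one-row
# data frame or NULL if no discernible transient.
measure_one <- function(v, fps, onset_time, end_time,
                        baseline_window = 0.05, deriv = NULL,
                        deriv_window = 0.03) {
  nT <- length(v)
  tt <- (seq_len(nT) - 1) / fps
  if (is.null(deriv)) deriv <- sg_derivative(v, fps, deriv_window)
  i_on <- max(1L, min(nT - 1L, 1L + round(onset_time * fps)))
  i_end <- min(nT, max(i_on + 1L, 1L + floor(end_time * fps)))

  # pass 1 baseline: median of the window ending at the detection onset
  bw <- which(tt >= onset_time - baseline_window & tt < onset_time)
  F_d <- if (length(bw)) stats::median(v[bw]) else v[i_on]

  # rising limb and maximum upstroke rate (smoothed derivative); the
  # last filter half-window before the peak is excluded because the
  # polynomial derivative overshoots at the peak corner, which would
  # bias the tangent back-projection of the onset
  i_pk0 <- i_on - 1L + which.max(v[i_on:i_end])
  hw <- attr(deriv, "halfwidth")
  if (is.null(hw)) hw <- 2L
  seg_hi <- if (i_pk0 - hw - i_on >= hw) i_pk0 - hw else i_pk0
  seg <- i_on:max(i_on + 1L, seg_hi)
  k <- which.max(deriv[seg])
  slope <- deriv[seg[k]]
  if (!(slope > 0)) return(NULL)
  i_d <- seg[k]
  t_d <- tt[i_d]
  v_d <- v[i_d]

  # tangent-line activation onset, then refine the baseline against it
  t_act <- t_d - (v_d - F_d) / slope
  bw2 <- which(tt >= t_act - baseline_window - 1 / fps & tt < t_act - 1 / fps)
  if (length(bw2) >= 3L) {
    F_d <- stats::median(v[bw2])
    t_act <- t_d - (v_d - F_d) / slope
  }

  # peak: median of the three samples at the discrete maximum, which
  # suppresses both the localized polynomial-smoothing overshoot at sharp
  # upstroke corners and the noise-maximum bias of a plain max, and is
  # exact on plateaus
  peak_i <- i_pk0
  peak <- stats::median(v[max(1L, peak_i - 1L):min(nT, peak_i + 1L)])
  dF <- peak - F_d
  if (!(dF > 0)) return(NULL)

  # Recovery crossing: first time after the peak at which the signal
  # falls below the level, linearly interpolated between frames. On
  # shallow decays (slow calcium tails) the first noise dip below the
  # level precedes the true crossing, so when enough samples lie in a
  # narrow band around the level the crossing is refined by a linear fit
  # of that band; on steep crossings the band holds too few samples and
  # the plain interpolation (already sub-frame accurate there) is kept.
  # The band is narrower than the gap to the diastolic level, so the
  # post-repolarization plateau never contaminates the fit.
  w_fit <- max(3L, round(2 * deriv_window * fps))
  band <- 0.07 * dF
  cross_after_peak <- function(x) {
    L <- peak - x * dF
    below <- which(v[(peak_i + 1L):i_end] < L)
    if (!length(below)) return(NA_real_)
    i1 <- peak_i + below[1L]
    frac <- (v[i1 - 1L] - L) / (v[i1 - 1L] - v[i1])
    t_interp <- tt[i1 - 1L] + frac / fps
    lo <- max(peak_i, i1 - w_fit); hi <- min(i_end, i1 + w_fit)
    inb <- lo:hi
    inb <- inb[abs(v[inb] - L) <= band]
    if (length(inb) >= 5L) {
      xs <- tt[inb]; ys <- v[inb]
      b <- stats::cov(xs, ys) / stats::var(xs)
      if (is.finite(b) && b < 0) {
        tc <- (L - (mean(ys) - b * mean(xs))) / b
        if (tc >= tt[lo] && tc <= tt[hi]) return(tc)
      }
    }
    t_interp
  }
  c30 <- cross_after_peak(0.3)
  c80 <- cross_after_peak(0.8)
  c90 <- cross_after_peak(0.9)
  # the refinement cannot be allowed to break the definitional ordering
  if (!is.na(c30) && !is.na(c80)) c80 <- max(c80, c30)
  if (!is.na(c80) && !is.na(c90)) c90 <- max(c90, c80)
  d30 <- c30 - t_act; d80 <- c80 - t_act; d90 <- c90 - t_act
  data.frame(activation_time = t_act, onset = onset_time,
             baseline = F_d, amplitude = dF,
             upstroke = slope, upstroke_norm = slope / dF,
             peak_time = tt[peak_i],
             d30 = d30, d80 = d80, d90 = d90,
             tri = d90 - d30,
             censored = is.na(d30) || is.na(d80) || is.na(d90))
}

#' Measure one beat
#'
#' Quantifies a single transient: diastolic baseline (median of the
#' pre-upstroke window), amplitude (peak minus baseline), maximum upstroke
#' rate (raw and amplitude-normalized), and durations `D30/D80/D90` from
#' the activation onset to the first linear-interpolated crossing of
#' `peak - x * amplitude` after the peak. The activation onset is the
#' intersection of the maximum-slope tangent with the baseline level
#' (the standard dF/dt-max convention, sub-frame accurate). A duration is
#' censored (`NA`) when its crossing is not reached before the next
#' activation or the end of the trace.
#'
#' @param trace a (preprocessed) [fluor_trace()].
#' @param activation_time detection onset of the beat, s (from
#'   [detect_beats()]).
#' @param next_activation_time onset of the following beat, s, or `NULL`
#'   for the last beat.
#' @param baseline_window width of the pre-upstroke baseline window, s.
#' @param deriv_window derivative window, s (default by modality as in
#'   [detect_beats()]).
#' @return one-row data frame of beat metrics, or `NULL` with a message if
#'   the beat shows no discernible transient (amplitude <= 0).
#' @export
measure_beat <- function(trace, activation_time, next_activation_time = NULL,
                         baseline_window = 0.05, deriv_window = NULL) {
  stopifnot(inherits(trace, "fluor_trace"))
  if (is.null(deriv_window))
    deriv_window <- deriv_window_default(trace$modality)
  end_time <- if (is.null(next_activation_time))
    (length(trace$values) - 1) / trace$frame_rate else next_activation_time
  out <- measure_one(trace$values, trace$frame_rate, activation_time,
                     end_time, baseline_window,
                     deriv_window = deriv_window)
  if (is.null(out))
    message("beat at ", signif(activation_time, 4),
            " s rejected: no discernible transient")
  out
}

#' Measure every detected beat of a trace
#'
#' @param trace a (preprocessed) [fluor_trace()].
#' @param beats data frame from [detect_beats()]; detected automatically
#'   when `NULL`.
#' @param baseline_window pre-upstroke baseline window, s.
#' @param ... passed to [detect_beats()] when `beats` is `NULL`.
#' @return data frame with one row per accepted beat (columns as in
#'   [measure_beat()] plus `beat` index and `rr_prev`, the interval from
#'   the previous activation). Beats with no discernible transient are
#'   dropped; their count is attached as attribute `"n_rejected"`.
#' @export
measure_beats <- function(trace, beats = NULL, baseline_window = 0.05,
                          deriv_window = NULL, ...) {
  if (is.null(deriv_window))
    deriv_window <- deriv_window_default(trace$modality)
  if (is.null(beats))
    beats <- detect_beats(trace, deriv_window = deriv_window, ...)
  empty_metrics <- function() {
    data.frame(activation_time = numeric(0), onset = numeric(0),
               baseline = numeric(0), amplitude = numeric(0),
               upstroke = numeric(0), upstroke_norm = numeric(0),
               peak_time = numeric(0), d30 = numeric(0), d80 = numeric(0),
               d90 = numeric(0), tri = numeric(0), censored = logical(0),
               beat = integer(0), rr_prev = numeric(0))
  }
  nB <- nrow(beats)
  if (!nB) {
    out <- empty_metrics()
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  dur <- (length(trace$values) - 1) / trace$frame_rate
  dv <- sg_derivative(trace$values, trace$frame_rate, deriv_window)
  rows <- vector("list", nB)
  for (k in seq_len(nB)) {
    nxt <- if (k < nB) beats$onset[k + 1L] else dur
    m <- measure_one(trace$values, trace$frame_rate, beats$onset[k], nxt,
                     baseline_window, deriv = dv,
                     deriv_window = deriv_window)
    if (!is.null(m)) {
      m$beat <- k
      rows[[k]] <- m
    }
  }
  kept <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[kept])
  if (is.null(out)) {
    out <- empty_metrics()
    attr(out, "n_rejected") <- nB
    return(out)
  }
  out$rr_prev <- c(NA_real_, diff(out$activation_time))
  attr(out, "n_rejected") <- sum(!kept)
  rownames(out) <- NULL
  out
}

#' Fridericia rate correction
#'
#' Divides a duration by the cube root of the preceding inter-beat
#' interval, `D / RR^(1/3)`, normalizing action-potential (or transient)
#' durations for spontaneous rate. Applied per beat; the first beat of a
#' recording has no preceding interval and returns `NA` (excluded from
#' corrected means).
#'
#' @param d80 duration(s), s; vectorized.
#' @param rr_prev preceding inter-beat interval(s), s; `NA` allowed.
#' @return corrected duration(s), s.
#' @export
fridericia_correct <- function(d80, rr_prev) {
  if (any(!is.na(rr_prev) & rr_prev <= 0))
    stop("'rr_prev' must be positive")
  d80 / rr_prev^(1 / 3)
}

#' Spontaneous activation frequency
#'
#' For `n >= 2` beats the rate is `(n - 1) / (t_n - t_1)`; with one or no
#' beats the rate is 0 and the result carries `attr(, "quiescent") = TRUE`.
#'
#' @param times activation times, s.
#' @param window analysis window length, s (recorded for provenance).
#' @return frequency in Hz with attribute `quiescent`.
#' @export
spontaneous_frequency <- function(times, window) {
  stopifnot(window > 0)
  n <- length(times)
  f <- if (n >= 2) (n - 1) / (times[n] - times[1]) else 0
  attr(f, "quiescent") <- n <= 1
  f
}

sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Per-recording summary of beat metrics
#'
#' Aggregates a beat-metrics table into the one-row-per-syncytium record
#' used by the cohort statistics: spontaneous frequency, mean and SEM of
#' every metric (duration metrics over non-censored beats only, so
#' truncated beats cannot bias durations downward, while all beats count
#' toward frequency), and the Fridericia-corrected D80.
#'
#' @param metrics data frame from [measure_beats()].
#' @param window analysis window, s.
#' @param recording_id,modality carried into the summary row.
#' @return one-row data frame (class `syncytium_summary`).
#' @export
summarize_syncytium <- function(metrics, window, recording_id = "recording",
                                modality = "voltage") {
  ok <- metrics[!metrics$censored, , drop = FALSE]
  f <- spontaneous_frequency(metrics$activation_time, window)
  d80c <- fridericia_correct(ok$d80, ok$rr_prev)
  m <- function(x) if (length(x) && any(is.finite(x)))
    mean(x, na.rm = TRUE) else NA_real_
  out <- data.frame(
    recording_id = recording_id, modality = modality,
    n_beats = nrow(metrics), frequency = as.numeric(f),
    quiescent = attr(f, "quiescent"),
    baseline = m(metrics$baseline), baseline_sem = sem(metrics$baseline),
    amplitude = m(metrics$amplitude), amplitude_sem = sem(metrics$amplitude),
    upstroke = m(metrics$upstroke), upstroke_sem = sem(metrics$upstroke),
    upstroke_norm = m(metrics$upstroke_norm),
    d30 = m(ok$d30), d80 = m(ok$d80), d80_sem = sem(ok$d80),
    d90 = m(ok$d90), tri = m(ok$tri), tri_sem = sem(ok$tri),
    d80c = m(d80c),
    n_censored = sum(metrics$censored), window = window)
  class(out) <- c("syncytium_summary", class(out))
  out
}

#' Isoproterenol response ratio
#'
#' Per-syncytium ratio of a metric after vs before beta-adrenergic
#' stimulation. Recordings are paired by `recording_id`; the group-level
#' response is the mean of per-syncytium ratios (not the ratio of group
#' means). Syncytia with a zero pre-treatment value are excluded with a
#' message.
#'
#' @param pre,post summary data frames (rows from [summarize_syncytium()])
#'   for the same syncytia before and after treatment.
#' @param metric column name to compare (e.g. `"frequency"`, `"d80"`).
#' @return data frame `recording_id`, `pre`, `post`, `ratio`, with the mean
#'   ratio attached as attribute `"mean_ratio"`.
#' @export
iso_response <- function(pre, post, metric) {
  stopifnot(metric %in% names(pre), metric %in% names(post))
  ids <- intersect(pre$recording_id, post$recording_id)
  if (!length(ids)) stop("no paired recordings between 'pre' and 'post'")
  p <- pre[match(ids, pre$recording_id), metric]
  q <- post[match(ids, post$recording_id), metric]
  bad <- !is.na(p) & p == 0
  if (any(bad)) {
    message("excluding ", sum(bad), " syncytium/ia with zero pre-treatment ",
            metric)
    ids <- ids[!bad]; q <- q[!bad]; p <- p[!bad]
  }
  out <- data.frame(recording_id = ids, pre = p, post = q, ratio = q / p)
  attr(out, "mean_ratio") <- mean(out$ratio, na.rm = TRUE)
  out
}
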