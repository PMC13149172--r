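#' Rhythm script for the simulator
#'
#' Describes when a synthetic syncytium activates: a base spontaneous rate
#' with optional inter-beat jitter, silent (quiescent) episodes, scripted
#' early-afterdepolarization (EAD) beats, and sustained tachyarrhythmic
#' segments. Inter-beat intervals are Gamma-distributed with mean `1/f` and
#' coefficient of variation `jitter_cv` (deterministic when `jitter_cv = 0`),
#' giving positive support and direct control of irregularity.
#'
#' @param base_frequency spontaneous activation rate, Hz, `>= 0` (0 = fully
#'   quiescent recording).
#' @param jitter_cv coefficient of variation of inter-beat intervals,
#'   dimensionless, `>= 0`.
#' @param quiescent list of `c(start_s, duration_s)` silent episodes; beats
#'   falling inside an episode are suppressed.
#' @param ead data frame with columns `beat` (1-based index), `delta`
#'   (relative bump height in (0, 1)) and `phase` (fraction of the
#'   repolarization span at which the bump peaks, in (0.3, 0.9)).
#' @param tachy list of `c(start_s, duration_s, frequency_hz)` segments in
#'   which the scripted frequency overrides the base rate.
#' @return an object of class `rhythm_script`.
#' @export
rhythm_script <- function(base_frequency, jitter_cv = 0,
                          quiescent = list(), ead = NULL, tachy = list()) {
  if (base_frequency < 0) stop("'base_frequency' must be >= 0")
  if (jitter_cv < 0) stop("'jitter_cv' must be >= 0")
  if (is.null(ead))
    ead <- data.frame(beat = integer(), delta = numeric(), phase = numeric())
  stopifnot(all(c("beat", "delta", "phase") %in% names(ead)))
  if (nrow(ead) && (any(ead$delta <= 0 | ead$delta >= 1) ||
                    any(ead$phase <= 0 | ead$phase >= 1)))
    stop("EAD 'delta' and 'phase' must lie in (0, 1)")
  structure(list(base_frequency = base_frequency, jitter_cv = jitter_cv,
                 quiescent = quiescent, ead = ead, tachy = tachy),
            class = "rhythm_script")
}

#' Draw beat times from a rhythm script
#'
#' Uses the current RNG state; [simulate_recording()] seeds it. The first
#' beat lands half an interval after the recording starts so short movies
#' at frequency `f` contain `floor(duration * f)` beats when regular.
#'
#' @param script a [rhythm_script()].
#' @param duration recording length, s.
#' @return strictly increasing numeric vector of activation times in
#'   `[0, duration)`.
#' @export
script_beat_times <- function(script, duration) {
  f_at <- function(t) {
    for (seg in script$tachy)
      if (t >= seg[1] && t < seg[1] + seg[2]) return(seg[3])
    script$base_frequency
  }
  draw_ibi <- function(f) {
    if (f <= 0) return(Inf)
    if (script$jitter_cv == 0) return(1 / f)
    shape <- 1 / script$jitter_cv^2
    stats::rgamma(1L, shape = shape, rate = shape * f)
  }
  beats <- numeric(0)
  t <- 0
  first <- TRUE
  repeat {
    ibi <- draw_ibi(f_at(t))
    if (!is.finite(ibi)) {
      # quiescent until the next tachy segment, if any
      starts <- vapply(script$tachy, `[`, numeric(1), 1L)
      nxt <- starts[starts > t]
      if (!length(nxt)) break
      t <- min(nxt)
      next
    }
    t <- t + if (first) 0.5 * ibi else ibi
    first <- FALSE
    if (t >= duration) break
    beats <- c(beats, t)
  }
  for (ep in script$quiescent)
    beats <- beats[beats < ep[1] | beats >= ep[1] + ep[2]]
  beats
}

#' Wavefront propagation model
#'
#' Kinematic activation-delay field over the pixel grid: planar wavefronts
#' travel along a fixed direction at speed `v`; target (centrifugal) waves
#' spread radially from an origin; the rotating pattern is an Archimedean
#' spiral activation-time field with a given angular period, adequate to
#' exercise conduction-velocity heterogeneity. `speed = Inf` yields
#' simultaneous (global) activation.
#'
#' @param pattern `"planar"`, `"target"`, or `"rotating"`.
#' @param speed wavefront speed, cm/s, `> 0` (may be `Inf`).
#' @param angle planar propagation direction, radians (0 = along columns).
#' @param origin `(row, col)` pixel of the source (target/rotating);
#'   default the grid center.
#' @param angular_period rotation period for the rotating pattern, s.
#' @return an object of class `propagation_model`.
#' @export
propagation_model <- function(pattern = c("planar", "target", "rotating"),
                              speed, angle = 0, origin = NULL,
                              angular_period = 1) {
  pattern <- match.arg(pattern)
  if (!(speed > 0)) stop("'speed' must be > 0")
  structure(list(pattern = pattern, speed = speed, angle = angle,
                 origin = origin, angular_period = angular_period),
            class = "propagation_model")
}

#' Per-pixel activation delay field
#'
#' @param model a [propagation_model()].
#' @param height,width grid size in pixels.
#' @param pixel_pitch cm per pixel.
#' @return `height x width` matrix of delays in seconds, minimum 0.
#' @export
delay_field <- function(model, height, width, pixel_pitch) {
  y <- matrix((seq_len(height) - 1) * pixel_pitch, height, width)
  x <- matrix((seq_len(width) - 1) * pixel_pitch, height, width, byrow = TRUE)
  if (is.infinite(model$speed)) return(matrix(0, height, width))
  org <- model$origin
  if (is.null(org)) org <- c((height + 1) / 2, (width + 1) / 2)
  y0 <- (org[1] - 1) * pixel_pitch
  x0 <- (org[2] - 1) * pixel_pitch
  switch(model$pattern,
    planar = {
      proj <- x * cos(model$angle) + y * sin(model$angle)
      (proj - min(proj)) / model$speed
    },
    target = sqrt((x - x0)^2 + (y - y0)^2) / model$speed,
    rotating = {
      r <- sqrt((x - x0)^2 + (y - y0)^2)
      phi <- atan2(y - y0, x - x0)
      P <- model$angular_period
      P * (((phi + pi) / (2 * pi) + r / (model$speed * P)) %% 1)
    })
}

#' Default waveform templates by modality
#'
#' Voltage defaults emulate a fast optical action potential (20 ms upstroke,
#' APD30 0.16 s, APD90 0.21 s); calcium transients are slower with a nonzero
#' diastolic baseline (100 ms upstroke, CaTD30 0.55 s, CaTD90 1.0 s,
#' baseline 0.46 a.u., amplitude 0.15 a.u.).
#'
#' @param modality `"voltage"` or `"calcium"`.
#' @return a [waveform_template()].
#' @export
default_waveform <- function(modality = c("voltage", "calcium")) {
  modality <- match.arg(modality)
  if (modality == "voltage")
    solve_template(0.02, 0.16, 0.21, amplitude = 1, baseline = 0)
  else
    solve_template(0.10, 0.55, 1.00, amplitude = 0.15, baseline = 0.46)
}

#' Simulation configuration
#'
#' Bundles everything [simulate_recording()] needs; the seed fully
#' determines the output. The default noise level gives a peak
#' signal-to-noise ratio of 20 (`noise_sd = amplitude / 20`).
#'
#' @param height,width grid size in pixels (use 1x1 for trace-level work).
#' @param pixel_pitch cm per pixel.
#' @param frame_rate frames per second, Hz.
#' @param duration recording length, s.
#' @param modality `"voltage"` or `"calcium"`.
#' @param waveform a [waveform_template()]; default per modality.
#' @param rhythm a [rhythm_script()].
#' @param propagation a [propagation_model()].
#' @param noise_sd additive white-noise standard deviation, a.u.;
#'   `NULL` = amplitude / 20; use 0 for noiseless.
#' @param bleach_rate photobleaching rate, fraction of baseline per second
#'   (monoexponential additive drift `F0 * (exp(-rate * t) - 1)`).
#' @param ead_width Gaussian half-width of injected EAD bumps, s;
#'   `NULL` scales it to the repolarization span (`0.05 * tau_r`, at
#'   least 25 ms so the deflection is resolvable at typical frame
#'   rates).
#' @param seed integer RNG seed.
#' @param recording_id identifier.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(height = 64, width = 64, pixel_pitch = 0.01,
                       frame_rate = 100, duration = 10,
                       modality = c("voltage", "calcium"),
                       waveform = NULL,
                       rhythm = rhythm_script(1),
                       propagation = propagation_model("planar", 10),
                       noise_sd = NULL, bleach_rate = 0, ead_width = NULL,
                       seed = 1L, recording_id = "sim") {
  modality <- match.arg(modality)
  if (is.null(waveform)) waveform <- default_waveform(modality)
  if (is.null(noise_sd)) noise_sd <- waveform$amplitude / 20
  if (is.null(ead_width)) ead_width <- max(0.025, 0.05 * waveform$tau_r)
  stopifnot(height >= 1, width >= 1, pixel_pitch > 0, frame_rate > 0,
            duration > 0, noise_sd >= 0, bleach_rate >= 0)
  structure(list(height = height, width = width, pixel_pitch = pixel_pitch,
                 frame_rate = frame_rate, duration = duration,
                 modality = modality, waveform = waveform, rhythm = rhythm,
                 propagation = propagation, noise_sd = noise_sd,
                 bleach_rate = bleach_rate, ead_width = ead_width,
                 seed = as.integer(seed),
                 recording_id = as.character(recording_id)),
            class = "sim_config")
}

#' Simulate one optical-mapping recording
#'
#' Kinematic (template-superposition) generation: beat times are drawn from
#' the rhythm script; each pixel activates at beat time plus its propagation
#' delay; the pixel trace is a superposition of waveform templates in which
#' a new beat truncates an unfinished repolarization by starting its
#' upstroke from the instantaneous signal value (continuous by
#' construction). Scripted EADs are additive Gaussian bumps of height
#' `delta * amplitude` centered at the scripted repolarization phase.
#' White noise and a monoexponential photobleaching drift are added last.
#'
#' Because generation is kinematic, the ground truth (beat times, per-beat
#' durations at any recovery fraction, conduction speed, baseline,
#' amplitude) is exact, not itself an estimate.
#'
#' @param config a [sim_config()].
#' @return list with elements `movie` (a [fluor_movie()]) and `truth`, a
#'   list holding `beats` (data frame: one row per beat with `time`,
#'   `ibi_prev`, `d30`, `d80`, `d90`, `tri`, `baseline`, `amplitude`,
#'   `censored`, `ead_delta`, `ead_phase`), `cv` (scripted speed, cm/s),
#'   `pattern`, `scripted` (character vector of scripted arrhythmic
#'   features) and `config`.
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tpl <- config$waveform
  nT <- round(config$duration * config$frame_rate)
  if (nT < 2) stop("recording too short")
  tgrid <- (seq_len(nT) - 1) / config$frame_rate
  beats <- script_beat_times(config$rhythm, config$duration)
  if (length(beats) >= 2 && min(diff(beats)) <= tpl$t_up)
    stop("unphysical rhythm: inter-beat interval shorter than the upstroke")

  H <- config$height; W <- config$width; P <- H * W
  dly <- delay_field(config$propagation, H, W, config$pixel_pitch)
  dvec <- as.vector(dly)  # column-major (row, col) order, matches frames

  F0 <- tpl$baseline
  V <- matrix(F0, nT, P)
  K <- length(beats)
  v0 <- F0
  v0s <- numeric(K)
  if (K > 0) {
    for (k in seq_len(K)) {
      v0s[k] <- v0
      act <- beats[k] + dvec  # per-pixel activation, length P
      S <- outer(tgrid, act, "-")
      m <- S >= 0
      if (any(m)) V[m] <- template_eval(tpl, S[m], v0 = v0)
      if (k < K) v0 <- template_eval(tpl, beats[k + 1] - beats[k], v0 = v0)
    }
    # EAD bumps on the repolarization limb
    ead <- config$rhythm$ead
    ead <- ead[ead$beat <= K, , drop = FALSE]
    if (nrow(ead)) {
      for (j in seq_len(nrow(ead))) {
        k <- ead$beat[j]
        # phase is a recovery fraction; the bump peaks when the template
        # has recovered that fraction, at tau_r * phase^(1/p) past the peak
        ctr <- beats[k] + dvec + tpl$t_up +
          ead$phase[j]^(1 / tpl$p) * tpl$tau_r
        G <- outer(tgrid, ctr, "-")
        V <- V + ead$delta[j] * tpl$amplitude *
          exp(-G^2 / (2 * config$ead_width^2))
      }
    }
  }
  if (config$bleach_rate > 0)
    V <- V + F0 * (exp(-config$bleach_rate * tgrid) - 1)
  if (config$noise_sd > 0)
    V <- V + stats::rnorm(length(V), sd = config$noise_sd)

  frames <- array(V, dim = c(nT, H, W))
  movie <- fluor_movie(frames, config$frame_rate, config$pixel_pitch,
                       config$modality, config$recording_id)

  dx <- function(x) template_duration(tpl, x)
  nxt <- if (K) c(diff(beats), config$duration - beats[K]) else numeric(0)
  truth_beats <- data.frame(
    beat = seq_len(K),
    time = beats,
    ibi_prev = if (K) c(NA_real_, diff(beats)) else numeric(0),
    d30 = rep(dx(0.3), K), d80 = rep(dx(0.8), K), d90 = rep(dx(0.9), K),
    tri = rep(dx(0.9) - dx(0.3), K),
    baseline = rep(F0, K), amplitude = rep(tpl$amplitude, K),
    upstroke = rep(if (tpl$t_up > 0) tpl$amplitude / tpl$t_up else Inf, K),
    censored = if (K) nxt < dx(0.9) else logical(0),
    ead_delta = rep(0, K), ead_phase = rep(NA_real_, K))
  if (K && nrow(config$rhythm$ead)) {
    e <- config$rhythm$ead[config$rhythm$ead$beat <= K, , drop = FALSE]
    truth_beats$ead_delta[e$beat] <- e$delta
    truth_beats$ead_phase[e$beat] <- e$phase
  }
  scripted <- character(0)
  if (length(config$rhythm$tachy)) scripted <- c(scripted, "tachyarrhythmia")
  if (nrow(config$rhythm$ead)) scripted <- c(scripted, "EAD")
  if (length(config$rhythm$quiescent) || config$rhythm$base_frequency == 0)
    scripted <- c(scripted, "quiescence")

  list(movie = movie,
       truth = list(beats = truth_beats, cv = config$propagation$speed,
                    pattern = config$propagation$pattern,
                    scripted = scripted, config = config))
}

#' Generate a labeled cohort of synthetic recordings
#'
#' One recording per functional syncytium; per-recording seeds are derived
#' deterministically from the master seed, so the whole cohort is
#' reproducible from a single integer. The returned ground-truth tables are
#' the oracle for downstream parameter-recovery tests.
#'
#' @param groups named list; each element is a list with `n` (number of
#'   recordings) and `config` — either a [sim_config()] used for every
#'   recording of the group or a `function(i)` returning one (for
#'   within-group variation).
#' @param seed master integer seed.
#' @return list with `recordings` (list of [simulate_recording()] results),
#'   `table` (data frame `recording_id`, `group`, `seed`, scripted feature
#'   summary) and `beats` (combined ground-truth beat table with
#'   `recording_id` and `group` columns).
#' @export
generate_cohort <- function(groups, seed = 1L) {
  if (!length(groups) || is.null(names(groups)))
    stop("'groups' must be a non-empty named list")
  total <- sum(vapply(groups, function(g) as.integer(g$n), integer(1)))
  if (total < 1) stop("cohort is empty")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, total)
  recordings <- vector("list", total)
  rows <- vector("list", total)
  beats <- vector("list", total)
  idx <- 0L
  for (gname in names(groups)) {
    g <- groups[[gname]]
    for (i in seq_len(g$n)) {
      idx <- idx + 1L
      cfg <- if (is.function(g$config)) g$config(i) else g$config
      cfg$seed <- seeds[idx]
      cfg$recording_id <- sprintf("%s_%02d", gname, i)
      rec <- simulate_recording(cfg)
      recordings[[idx]] <- rec
      rows[[idx]] <- data.frame(
        recording_id = cfg$recording_id, group = gname, seed = seeds[idx],
        scripted = paste(rec$truth$scripted, collapse = "+"),
        jitter_cv = cfg$rhythm$jitter_cv,
        base_frequency = cfg$rhythm$base_frequency,
        true_cv = cfg$propagation$speed)
      b <- rec$truth$beats
      if (nrow(b)) {
        b$recording_id <- cfg$recording_id
        b$group <- gname
      }
      beats[[idx]] <- b
    }
  }
  list(recordings = recordings,
       table = do.call(rbind, rows),
       beats = do.call(rbind, beats[vapply(beats, nrow, integer(1)) > 0]))
}
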