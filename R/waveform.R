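#' Parametric transient waveform template
#'
#' The simulator builds every action potential or calcium transient from a
#' five-parameter template: the signal sits at baseline `F0` before
#' activation, rises linearly to `F0 + A` over the upstroke duration `t_up`,
#' then repolarizes as
#' \deqn{F(\tau) = F_0 + A (1 - (\tau/\tau_r)^p), \quad \tau \in [0, \tau_r],}
#' clamped at `F0` afterwards. The implied duration at recovery fraction
#' `x` (time from activation onset until the signal has recovered `x` of its
#' amplitude) has the closed form
#' \deqn{D_x = t_{up} + \tau_r x^{1/p},}
#' which is what makes the generator's APD/CaTD ground truth exact.
#'
#' @param t_up upstroke duration, seconds, `>= 0`.
#' @param tau_r repolarization span, seconds, `> 0`.
#' @param p shape exponent, dimensionless, `> 0`. `p = 1` gives linear
#'   repolarization; `p < 1` front-loads recovery (more triangulated late
#'   phase); `p > 1` back-loads it.
#' @param amplitude peak minus baseline `A`, a.u., `> 0`.
#' @param baseline diastolic level `F0`, a.u.
#' @return an object of class `waveform_template`.
#' @seealso [solve_template()], [template_duration()]
#' @export
waveform_template <- function(t_up, tau_r, p, amplitude = 1, baseline = 0) {
  if (t_up < 0) stop("'t_up' must be >= 0")
  if (tau_r <= 0) stop("'tau_r' must be > 0")
  if (p <= 0) stop("'p' must be > 0")
  if (amplitude <= 0) stop("'amplitude' must be > 0")
  structure(list(t_up = t_up, tau_r = tau_r, p = p,
                 amplitude = amplitude, baseline = baseline),
            class = "waveform_template")
}

#' @export
print.waveform_template <- function(x, ...) {
  cat(sprintf(
    "<waveform_template> t_up=%g s, tau_r=%g s, p=%.4g, A=%g, F0=%g\n",
    x$t_up, x$tau_r, x$p, x$amplitude, x$baseline))
  cat(sprintf("  D30=%.4g  D80=%.4g  D90=%.4g  tri=%.4g s\n",
              template_duration(x, 0.3), template_duration(x, 0.8),
              template_duration(x, 0.9),
              template_duration(x, 0.9) - template_duration(x, 0.3)))
  invisible(x)
}

#' Duration at a recovery fraction
#'
#' Closed-form `D_x = t_up + tau_r * x^(1/p)`: the time from activation
#' onset until the template has recovered fraction `x` of its amplitude
#' (APD30/80/90 or CaTD30/80/90 for `x = 0.3, 0.8, 0.9`).
#'
#' @param template a [waveform_template()].
#' @param x recovery fraction(s) in (0, 1]; vectorized.
#' @return duration(s) in seconds.
#' @export
template_duration <- function(template, x) {
  stopifnot(all(x > 0), all(x <= 1))
  template$t_up + template$tau_r * x^(1 / template$p)
}

#' Solve a template from two target durations
#'
#' Inverts `D_x = t_up + tau_r * x^(1/p)` for the repolarization parameters
#' given the upstroke time and durations at two recovery fractions
#' `0 < a < b <= 1`:
#' \deqn{p = \frac{\ln(a/b)}{\ln((D_a - t_{up})/(D_b - t_{up}))}, \qquad
#'       \tau_r = \frac{D_b - t_{up}}{b^{1/p}}.}
#' Used to configure the generator so a cohort's true APD/CaTD values match
#' any prescribed pair (e.g. a target D80 and triangulation).
#'
#' @param t_up upstroke duration, s.
#' @param d_a duration at fraction `a`, s; must satisfy `t_up < d_a < d_b`.
#' @param d_b duration at fraction `b`, s.
#' @param a,b recovery fractions, `0 < a < b <= 1` (defaults 0.3 and 0.9).
#' @param amplitude,baseline passed through to [waveform_template()].
#' @return a [waveform_template()] reproducing both durations.
#' @export
solve_template <- function(t_up, d_a, d_b, a = 0.3, b = 0.9,
                           amplitude = 1, baseline = 0) {
  if (!(a > 0 && a < b && b <= 1))
    stop("recovery fractions must satisfy 0 < a < b <= 1")
  if (!(t_up < d_a && d_a < d_b))
    stop("durations must satisfy t_up < d_a < d_b")
  p <- log(a / b) / log((d_a - t_up) / (d_b - t_up))
  tau_r <- (d_b - t_up) / b^(1 / p)
  waveform_template(t_up, tau_r, p, amplitude, baseline)
}

#' Evaluate a template
#'
#' Value of the waveform at time `s` after activation onset. During the
#' upstroke the signal ramps linearly from `v0` (the instantaneous value at
#' onset, `baseline` for a fully recovered preparation) to the peak; this is
#' what lets successive beats truncate an unfinished repolarization without
#' discontinuity.
#'
#' @param template a [waveform_template()].
#' @param s time since activation onset, seconds; vectorized. Negative
#'   values return `v0`.
#' @param v0 signal value at activation onset (default: the baseline).
#' @return numeric vector of fluorescence values.
#' @export
template_eval <- function(template, s, v0 = template$baseline) {
  F0 <- template$baseline
  A <- template$amplitude
  peak <- F0 + A
  out <- rep(v0, length.out = length(s))
  if (template$t_up > 0) {
    up <- s >= 0 & s < template$t_up
    out[up] <- v0 + (peak - v0) * s[up] / template$t_up
  }
  dec <- s >= template$t_up
  tau <- pmin((s[dec] - template$t_up) / template$tau_r, 1)
  out[dec] <- F0 + A * (1 - tau^template$p)
  out
}
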