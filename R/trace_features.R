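# Per-beat morphometrics of a single conditioned trace.
#
# Conventions shared by all features:
#  * amplitude is the min-max range of the samples inside the beat window,
#    so every feature is invariant under positive affine rescaling;
#  * level-crossing times are linearly interpolated between the two
#    bracketing samples;
#  * ties are broken towards the earliest sample (deterministic).

#' Construct a beat window
#'
#' A beat window holds the conditioned samples of one cardiac cycle for one
#' pixel, plus its time base. [segment_beats()] produces these; this
#' constructor is handy for building windows directly from a vector.
#'
#' @param values numeric samples of one beat.
#' @param dt_ms sampling interval in ms.
#' @param t0_ms time of the first sample in ms.
#' @return a `beat_window`.
#' @export
beat_window <- function(values, dt_ms = 1, t0_ms = 0) {
  assert_that(is.numeric(values) && length(values) >= 5L,
              "a beat window needs at least 5 samples")
  structure(list(values = as.numeric(values), i0 = NA_integer_,
                 i1 = NA_integer_, t0_ms = t0_ms,
                 t1_ms = t0_ms + (length(values) - 1) * dt_ms,
                 anchor_ms = t0_ms, dt_ms = dt_ms),
            class = "beat_window")
}

.check_beat <- function(beat) {
  assert_that(inherits(beat, "beat_window"), "beat must be a beat_window")
  if (!all(is.finite(beat$values)))
    abort_trimap("non-finite samples in beat window", "trimap_data_error")
  invisible(beat)
}

.beat_amplitude <- function(v) {
  rng <- range(v)
  if (diff(rng) <= 0)
    abort_trimap("beat has zero amplitude", "trimap_degenerate_error")
  rng
}

#' Activation time of a beat
#'
#' The activation time is the time of maximum first derivative of the
#' upstroke, estimated from forward differences and reported at the midpoint
#' of the steepest inter-sample interval, with parabolic sub-sample
#' refinement when both neighbouring differences are available. Ties are
#' broken towards the earliest interval.
#'
#' @param beat a [beat_window()].
#' @return activation time in ms (absolute, i.e. including the window's
#'   `t0_ms`).
#' @export
activation_time <- function(beat) {
  .check_beat(beat)
  v <- beat$values
  assert_that(length(v) >= 5L, "beat must have >= 5 samples")
  d <- diff(v)
  # earliest tie, robust to float dust in nominally equal differences
  tol <- 1e-9 * max(diff(range(v)), .Machine$double.eps)
  j <- which(d >= max(d) - tol)[1]
  off <- 0
  if (j > 1L && j < length(d)) {
    den <- d[j - 1] - 2 * d[j] + d[j + 1]
    if (is.finite(den) && den < 0) off <- 0.5 * (d[j - 1] - d[j + 1]) / den
    off <- max(-0.5, min(0.5, off))
  }
  beat$t0_ms + (j - 0.5 + off) * beat$dt_ms
}

# Interpolated time (ms, relative to window start) of the last upward
# crossing of `level` strictly before sample `pk`.
.last_up_cross <- function(v, pk, level, dt) {
  if (pk < 2L) return(NA_real_)
  i <- which(v[seq_len(pk - 1)] < level & v[2:pk] >= level)
  if (!length(i)) return(NA_real_)
  .cross_time(v, max(i), level, dt)
}

# First upward crossing of `level` before `pk` that occurs at or after
# time `after_ms` (used so the 90% crossing follows the 20% one).
.first_up_cross_after <- function(v, pk, level, dt, after_ms) {
  if (pk < 2L) return(NA_real_)
  i <- which(v[seq_len(pk - 1)] < level & v[2:pk] >= level)
  if (!length(i)) return(NA_real_)
  t <- vapply(i, function(ii) .cross_time(v, ii, level, dt), numeric(1))
  t <- t[t >= after_ms]
  if (!length(t)) return(NA_real_)
  t[1]
}

#' Rise time of a beat (20-90% of the upstroke)
#'
#' Time between the `lo` and `hi` fractional-amplitude crossings on the
#' upstroke: the last `lo`-crossing before the peak and the first
#' `hi`-crossing after it, both linearly interpolated.
#'
#' @param beat a [beat_window()].
#' @param lo,hi amplitude fractions defining the upstroke span.
#' @return rise time in ms.
#' @export
rise_time <- function(beat, lo = 0.2, hi = 0.9) {
  .check_beat(beat)
  v <- beat$values
  rng <- .beat_amplitude(v)
  amp <- diff(rng)
  pk <- which.max(v)
  t_lo <- .last_up_cross(v, pk, rng[1] + lo * amp, beat$dt_ms)
  if (is.na(t_lo))
    abort_trimap(sprintf("%.0f%% level never crossed on the upstroke", 100 * lo),
                 "trimap_morphology_error")
  t_hi <- .first_up_cross_after(v, pk, rng[1] + hi * amp, beat$dt_ms, t_lo)
  if (is.na(t_hi))
    abort_trimap(sprintf("%.0f%% level never crossed on the upstroke", 100 * hi),
                 "trimap_morphology_error")
  t_hi - t_lo
}

#' Duration at 80% repolarization (APD80 / CaTD80)
#'
#' Interval from the activation time ([activation_time()]) to the
#' linearly-interpolated down-crossing of 20% of the beat amplitude after
#' the peak, i.e. 80% recovery from peak towards the per-beat baseline.
#' Beats that never recover to the 20% level (e.g. motion-distorted
#' repolarization) raise an incomplete-repolarization error: the parameter
#' is undefined, as in recordings without electromechanical uncoupling.
#'
#' @param beat a [beat_window()].
#' @return duration in ms.
#' @export
duration80 <- function(beat) {
  .check_beat(beat)
  v <- beat$values
  rng <- .beat_amplitude(v)
  level <- rng[1] + 0.2 * diff(rng)
  t_act <- activation_time(beat)
  pk <- which.max(v)
  n <- length(v)
  if (pk >= n)
    abort_trimap("no repolarization phase after the peak",
                 "trimap_incomplete_repolarization_error")
  i <- which(v[pk:(n - 1)] >= level & v[(pk + 1):n] < level)
  if (!length(i))
    abort_trimap("signal does not recover to the 20% level inside the window",
                 "trimap_incomplete_repolarization_error")
  i <- pk + i[1] - 1L
  t_cross <- beat$t0_ms + .cross_time(v, i, level, beat$dt_ms)
  t_cross - t_act
}

#' Calcium decay time constant
#'
#' Fits `F(t) = A * exp(-(t - t50) / tau) + C` by least squares to the late
#' decay phase — from the 50%-recovery crossing after the peak to the end of
#' the window (the last 50% of the decay). The fit is separable: for a
#' candidate tau the amplitude and offset are solved linearly, and tau is
#' optimized on a log scale. The offset term accommodates diastolic
#' fluorescence that does not return to zero; set `offset = FALSE` for a
#' pure exponential.
#'
#' @param beat a [beat_window()].
#' @param offset include a constant offset C in the model.
#' @param max_rel_residual fit rejection threshold: RMS residual as a
#'   fraction of the decay segment's range.
#' @return tau in ms.
#' @export
decay_tau <- function(beat, offset = TRUE, max_rel_residual = 0.2) {
  .check_beat(beat)
  v <- beat$values
  rng <- .beat_amplitude(v)
  level <- rng[1] + 0.5 * diff(rng)
  pk <- which.max(v)
  n <- length(v)
  i <- if (pk < n) which(v[pk:(n - 1)] >= level & v[(pk + 1):n] < level) else integer()
  if (!length(i))
    abort_trimap("no 50%-recovery crossing after the peak: cannot fit decay",
                 "trimap_fit_error")
  i50 <- pk + i[1]            # first sample below the 50% level
  y <- v[i50:n]
  if (length(y) < 8L)
    abort_trimap("fewer than 8 samples in the 50-100% decay phase",
                 "trimap_fit_error")
  if (y[length(y)] >= y[1])
    abort_trimap("decay segment is not decreasing: cannot fit decay",
                 "trimap_fit_error")
  t <- (seq_along(y) - 1) * beat$dt_ms
  dur <- max(t[length(t)], beat$dt_ms)
  sse_for <- function(ltau) {
    e <- exp(-t / exp(ltau))
    X <- if (offset) cbind(e, 1) else cbind(e)
    sum(.lm.fit(X, y)$residuals^2)
  }
  opt <- stats::optimize(sse_for, c(log(beat$dt_ms / 2), log(20 * dur)),
                         tol = 1e-8)
  tau <- exp(opt$minimum)
  e <- exp(-t / tau)
  X <- if (offset) cbind(e, 1) else cbind(e)
  cf <- .lm.fit(X, y)
  if (cf$coefficients[1] <= 0)
    abort_trimap("decay fit has non-positive amplitude", "trimap_fit_error")
  rel <- sqrt(mean(cf$residuals^2)) / max(diff(range(y)), .Machine$double.eps)
  if (!is.finite(tau) || rel > max_rel_residual)
    abort_trimap(sprintf(
      "decay fit rejected: relative residual %.3f > %.2f (tau=%.2f ms, n=%d)",
      rel, max_rel_residual, tau, length(y)), "trimap_fit_error")
  tau
}

#' Flag motion-distorted beats
#'
#' Uncoupled (pharmacologically arrested) hearts show a monotone
#' repolarization; residual contraction superimposes oscillations on the
#' late phase of the optical signal. The detector smooths the post-peak
#' segment (5 ms moving average) and measures every "rebound" — a rise from
#' a local minimum to the next local maximum. The beat is flagged
#' `motion_artifact` when any rebound exceeds `big_rebound` of the beat
#' amplitude, or more than `max_rebounds` rebounds exceed `rebound_tol`.
#' Beats flagged here have their repolarization parameters (APD80/CaTD80,
#' tau) excluded from summaries.
#'
#' @param beat a [beat_window()].
#' @param rebound_tol minimal rebound (fraction of amplitude) that counts.
#' @param big_rebound rebound fraction that flags on its own.
#' @param max_rebounds maximum tolerated count of counted rebounds.
#' @return `"ok"` or `"motion_artifact"`.
#' @export
flag_motion_artifact <- function(beat, rebound_tol = 0.05, big_rebound = 0.3,
                                 max_rebounds = 2L) {
  .check_beat(beat)
  v <- beat$values
  rng <- .beat_amplitude(v)
  amp <- diff(rng)
  pk <- which.max(v)
  if (pk >= length(v) - 2L) return("ok")
  s <- .moving_average(v[pk:length(v)], .kernel_width(5, beat$dt_ms))
  rising <- diff(s) > 0
  r <- rle(rising)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- which(r$values)   # runs of rising samples = rebounds
  rebounds <- (s[ends[pos] + 1L] - s[starts[pos]]) / amp
  if (any(rebounds > big_rebound) ||
      sum(rebounds > rebound_tol) > max_rebounds) "motion_artifact" else "ok"
}

#' All morphometric features of one beat
#'
#' Convenience wrapper computing activation time, rise time, duration at 80%
#' recovery, decay tau (calcium only), and the motion-artifact quality flag.
#' Repolarization features of flagged beats, and features whose morphology
#' checks fail, are returned as `NA` rather than raising.
#'
#' @param beat a [beat_window()].
#' @param channel `"vm"` or `"ca"` (tau is fitted only for calcium).
#' @param tau_offset include an offset term in the decay fit.
#' @return list with `t_act_ms`, `rt_ms`, `dur80_ms`, `tau_ms`, `quality`.
#' @export
trace_features <- function(beat, channel = c("vm", "ca"), tau_offset = TRUE) {
  channel <- match.arg(channel)
  .check_beat(beat)
  safe <- function(expr) tryCatch(expr, trimap_error = function(e) NA_real_)
  quality <- flag_motion_artifact(beat)
  t_act <- safe(activation_time(beat))
  rt <- safe(rise_time(beat))
  dur <- tau <- NA_real_
  if (quality == "ok") {
    dur <- safe(duration80(beat))
    if (channel == "ca") tau <- safe(decay_tau(beat, offset = tau_offset))
  }
  list(t_act_ms = t_act, rt_ms = rt, dur80_ms = dur, tau_ms = tau,
       quality = quality)
}
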