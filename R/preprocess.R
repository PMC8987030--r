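# Tissue masking --------------------------------------------------------------

#' Compute a tissue mask by intensity thresholding
#'
#' A pixel is included when its time-mean intensity is at least
#' `threshold_frac` times the maximum time-mean intensity over all pixels.
#' Background and boundary pixels excluded here are dropped from every map
#' statistic downstream.
#'
#' @param stack a [movie_stack()].
#' @param threshold_frac fraction of the maximum mean intensity, in (0, 1).
#' @return a `tissue_mask`: list with logical `mask` (height x width) and
#'   `threshold_frac`.
#' @export
compute_mask <- function(stack, threshold_frac = 0.3) {
  assert_that(inherits(stack, "movie_stack"), "stack must be a movie_stack")
  assert_that(threshold_frac > 0 && threshold_frac < 1,
              "threshold_frac must be in (0, 1)")
  mean_img <- apply(stack$data, c(2, 3), mean)
  mask <- mean_img >= threshold_frac * max(mean_img)
  if (sum(mask) < 0.01 * length(mask))
    abort_trimap("fewer than 1% of pixels pass the intensity threshold",
                 "trimap_empty_mask_error")
  structure(list(mask = mask, threshold_frac = threshold_frac),
            class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %d x %d px, %d in mask (%.1f%%), threshold %.2f\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask), x$threshold_frac))
  invisible(x)
}

# Trace conditioning -----------------------------------------------------------

#' Condition a raw pixel trace
#'
#' Prepares a raw fluorescence time series for morphometric analysis:
#' optional polarity flip (voltage-dye fluorescence decreases on
#' depolarization, so the vm channel is inverted), polynomial baseline
#' subtraction (the baseline is fitted to the diastolic, lowest-quintile
#' samples so the beat morphology does not leak into the trend estimate),
#' a short moving-average temporal filter, and min-max
#' normalization to \[0, 1\] — per beat when `beat_windows` is supplied,
#' globally otherwise. Absolute amplitude is never interpreted
#' physiologically; all downstream features are fractions of per-beat
#' amplitude.
#'
#' @param values raw intensity series.
#' @param dt_ms sampling interval in ms.
#' @param flip_polarity invert the trace before processing.
#' @param detrend_order order of the polynomial baseline removed by least
#'   squares (0 disables; 1 removes linear drift).
#' @param temporal_kernel_ms moving-average window in ms (values `<= dt_ms`
#'   disable smoothing).
#' @param beat_windows optional list of [beat windows][segment_beats] for
#'   per-beat normalization.
#' @return a `conditioned_trace`: list with `values`, `dt_ms`,
#'   `polarity_flipped`, `baseline_model`.
#' @export
condition_trace <- function(values, dt_ms, flip_polarity = FALSE,
                            detrend_order = 1L, temporal_kernel_ms = 3,
                            beat_windows = NULL) {
  assert_that(is.numeric(values) && length(values) >= 4L,
              "values must be a numeric series of length >= 4")
  assert_that(all(is.finite(values)), "values must be finite",
              class = "trimap_data_error")
  v <- as.numeric(values)
  if (flip_polarity) v <- -v
  baseline_model <- "none"
  if (detrend_order >= 1L) {
    v <- .detrend_baseline(v, detrend_order)
    baseline_model <- sprintf("diastolic polynomial order %d", detrend_order)
  }
  w <- .kernel_width(temporal_kernel_ms, dt_ms)
  if (w > 1L) {
    if (!is.null(beat_windows)) {
      shortest <- min(vapply(beat_windows, function(b) b$i1 - b$i0 + 1L,
                             integer(1)))
      if (shortest < w)
        abort_trimap("beat window shorter than temporal kernel",
                     "trimap_usage_error")
    }
    v <- .moving_average(v, w)
  }
  scale0 <- max(1, max(abs(values)))   # input scale, not residual float dust
  normalize <- function(x) {
    rng <- range(x)
    if (diff(rng) <= 1e-9 * scale0)
      abort_trimap("zero beat amplitude: cannot normalize",
                   "trimap_degenerate_error")
    (x - rng[1]) / diff(rng)
  }
  if (is.null(beat_windows)) {
    v <- normalize(v)
  } else {
    for (b in beat_windows) {
      idx <- b$i0:b$i1
      v[idx] <- normalize(v[idx])
    }
  }
  structure(list(values = v, dt_ms = dt_ms, polarity_flipped = flip_polarity,
                 baseline_model = baseline_model),
            class = "conditioned_trace")
}

# Spatial filtering ------------------------------------------------------------

# 1-D truncated, renormalized Gaussian smoothing matrix (n x n).
.gauss_smoother <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1, i - r):min(n, i + r)
    kk <- k[j - i + r + 1]
    S[i, j] <- kk / sum(kk)
  }
  S
}

#' Mask-normalized per-frame Gaussian smoothing
#'
#' Smooths every frame with a separable Gaussian restricted to masked
#' pixels: the image is multiplied by the mask, smoothed, and divided by the
#' smoothed mask, so background intensity never bleeds into the tissue.
#' Pixels outside the mask are left untouched. `sigma_px = 0` is the
#' identity.
#'
#' @param stack a [movie_stack()].
#' @param sigma_px Gaussian standard deviation in px (>= 0).
#' @param mask optional [compute_mask()] result; `NULL` smooths the whole
#'   frame.
#' @return a smoothed [movie_stack()].
#' @export
spatial_filter <- function(stack, sigma_px, mask = NULL) {
  assert_that(inherits(stack, "movie_stack"), "stack must be a movie_stack")
  assert_that(is.numeric(sigma_px) && sigma_px >= 0, "sigma_px must be >= 0")
  if (sigma_px == 0) return(stack)
  d <- dim(stack$data)
  Sh <- .gauss_smoother(d[2], sigma_px)
  Sw <- .gauss_smoother(d[3], sigma_px)
  m <- if (is.null(mask)) matrix(TRUE, d[2], d[3]) else mask$mask
  mnum <- m * 1
  denom <- Sh %*% mnum %*% t(Sw)
  out <- stack$data
  for (k in seq_len(d[1])) {
    frame <- matrix(stack$data[k, , ], d[2], d[3])
    sm <- (Sh %*% (frame * mnum) %*% t(Sw)) / denom
    frame[m] <- sm[m]
    out[k, , ] <- frame
  }
  movie_stack(out, stack$dt_ms, stack$pixel_mm, stack$channel, stack$meta)
}

# Beat segmentation ------------------------------------------------------------

.beat_window <- function(values, i0, i1, anchor_i, dt_ms) {
  structure(list(values = values[i0:i1], i0 = i0, i1 = i1,
                 t0_ms = (i0 - 1) * dt_ms, t1_ms = (i1 - 1) * dt_ms,
                 anchor_ms = (anchor_i - 1) * dt_ms, dt_ms = dt_ms),
            class = "beat_window")
}

#' Segment a conditioned trace into beat windows
#'
#' Detects upstrokes as upward crossings of 50% of the global amplitude with
#' a refractory lockout of half the cycle length, then cuts one fixed-length
#' window per beat, anchored a little before each upstroke so that both the
#' diastolic baseline and the full repolarization fall inside the window.
#' First and last partial beats are discarded.
#'
#' @param trace a [condition_trace()] result (typically of the spatially
#'   averaged signal).
#' @param bcl_ms pacing basic cycle length in ms, or `NULL` to infer the
#'   cycle length as the median inter-upstroke interval.
#' @param lead_frac fraction of the cycle length included before each
#'   upstroke anchor.
#' @return list of `beat_window` objects (fields `values`, `i0`, `i1`,
#'   `t0_ms`, `t1_ms`, `anchor_ms`, `dt_ms`).
#' @export
segment_beats <- function(trace, bcl_ms = NULL, lead_frac = 0.15) {
  assert_that(inherits(trace, "conditioned_trace"),
              "trace must be a conditioned_trace")
  v <- trace$values
  dt <- trace$dt_ms
  n <- length(v)
  if (!is.null(bcl_ms))
    assert_that(n * dt >= 1.5 * bcl_ms,
                "recording must be at least 1.5 BCL long")
  rng <- range(v)
  if (diff(rng) <= 1e-12)
    abort_trimap("flat trace: no beats detected", "trimap_no_beats_error")
  level <- rng[1] + 0.5 * diff(rng)
  up <- which(v[-n] < level & v[-1] >= level)
  if (length(up) == 0L)
    abort_trimap("no upstroke crossings found", "trimap_no_beats_error")
  lockout_ms <- if (!is.null(bcl_ms)) 0.5 * bcl_ms else {
    if (length(up) > 1L) 0.5 * stats::median(diff(up)) * dt else 0
  }
  lockout <- max(1, round(lockout_ms / dt))
  anchors <- up[1]
  for (i in up[-1]) if (i - anchors[length(anchors)] >= lockout)
    anchors <- c(anchors, i)
  cycle_ms <- if (!is.null(bcl_ms)) bcl_ms else {
    if (length(anchors) < 2L)
      abort_trimap("cannot infer cycle length from a single beat",
                   "trimap_no_beats_error")
    stats::median(diff(anchors)) * dt
  }
  lead <- round(lead_frac * cycle_ms / dt)
  len <- round(cycle_ms / dt)
  windows <- list()
  for (a in anchors) {
    i0 <- a - lead
    i1 <- i0 + len - 1L
    if (i0 < 1L || i1 > n) next   # partial beat at either end
    windows[[length(windows) + 1L]] <- .beat_window(v, i0, i1, a, dt)
  }
  if (length(windows) == 0L)
    abort_trimap("no complete beats inside the recording",
                 "trimap_no_beats_error")
  windows
}
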