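#' @keywords internal
"_PACKAGE"

# Condition helpers -----------------------------------------------------------

# All package errors carry class "trimap_error" plus a specific subclass so
# callers (and tests) can distinguish usage errors from data pathologies.
abort_trimap <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "trimap_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

assert_that <- function(cond, message, class = "trimap_usage_error") {
  if (!isTRUE(cond)) abort_trimap(message, class)
  invisible(TRUE)
}

# Imaging-system constants ----------------------------------------------------

#' Optical-mapping system constants
#'
#' Small closed-form helpers for the acquisition geometry and timing of a
#' tandem-lens optical-mapping system: the pixel edge length projected onto
#' the tissue, the pacing rate implied by a basic cycle length (BCL), and the
#' sampling frequency implied by the frame interval.
#'
#' @param sensor_mm sensor edge length in mm.
#' @param n_px number of pixels along the sensor edge.
#' @param magnification optical magnification of the tandem lens pair.
#' @param bcl_ms basic cycle length (pacing interval) in ms.
#' @param dt_ms sampling interval in ms.
#'
#' @return `pixel_size_mm()`: pixel edge length in mm. `pacing_rate_bpm()`:
#'   heart rate in beats per minute. `sampling_frequency_khz()`: sampling
#'   frequency in kHz.
#'
#' @examples
#' pixel_size_mm(10, 100, 1)     # 0.1 mm
#' pacing_rate_bpm(150)          # 400 bpm
#' sampling_frequency_khz(1)     # 1 kHz
#' @export
pixel_size_mm <- function(sensor_mm = 10, n_px = 100, magnification = 1) {
  assert_that(sensor_mm > 0 && n_px > 0 && magnification > 0,
              "sensor_mm, n_px and magnification must be positive")
  sensor_mm / (n_px * magnification)
}

#' @rdname pixel_size_mm
#' @export
pacing_rate_bpm <- function(bcl_ms) {
  assert_that(all(bcl_ms > 0), "bcl_ms must be positive")
  60000 / bcl_ms
}

#' @rdname pixel_size_mm
#' @export
sampling_frequency_khz <- function(dt_ms) {
  assert_that(all(dt_ms > 0), "dt_ms must be positive")
  1 / dt_ms
}

# Numeric helpers -------------------------------------------------------------

# Linear interpolation of the time at which a sampled signal crosses `level`
# between samples i and i+1 (0-based time = (i-1)*dt relative to first sample).
.cross_time <- function(v, i, level, dt) {
  if (v[i + 1] == v[i]) return((i - 1) * dt)
  (i - 1) * dt + dt * (level - v[i]) / (v[i + 1] - v[i])
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards (simulators must not disturb the session RNG).
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Odd moving-average kernel width (samples) for a kernel length given in ms.
.kernel_width <- function(kernel_ms, dt_ms) {
  if (is.null(kernel_ms) || kernel_ms <= dt_ms) return(1L)
  w <- max(1L, round(kernel_ms / dt_ms))
  if (w %% 2L == 0L) w <- w + 1L
  as.integer(w)
}

# Polynomial baseline removal anchored on the diastolic samples: the
# polynomial is fitted by least squares to the samples at or below the
# `frac` quantile (the diastolic plateau between beats), then subtracted
# from the whole trace. Fitting to diastole only keeps the systolic
# morphology (upstroke, plateau, exponential decay) out of the baseline
# estimate, so a drift-free trace is left essentially unchanged.
.detrend_baseline <- function(v, order, frac = 0.2) {
  if (order < 1L) return(v)
  t <- seq_along(v) / length(v)
  X <- cbind(1, stats::poly(t, degree = order, raw = TRUE))
  idx <- which(v <= stats::quantile(v, frac, names = FALSE))
  if (length(idx) <= ncol(X)) idx <- seq_along(v)
  cf <- stats::lm.fit(X[idx, , drop = FALSE], v[idx])$coefficients
  cf[!is.finite(cf)] <- 0
  v - as.vector(X %*% cf)
}

# Centered moving average preserving length (edges use shrinking windows).
.moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
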