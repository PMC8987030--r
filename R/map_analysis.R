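# Per-pixel parameter maps and recording-level reductions ---------------------

.map_kinds <- c("activation", "rise_time", "dur80", "tau", "delay", "nadh")

.parameter_map <- function(values, kind) {
  structure(list(values = values, kind = kind), class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<parameter_map> kind=%s  %d x %d px, %d defined, range %.2f..%.2f\n",
              x$kind, nrow(x$values), ncol(x$values), length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

# Extract all per-pixel features of one channel in a single pass.
#
# Returns matrices (height x width, NA where undefined) for activation time
# (relative to each beat's anchor), rise time, dur80 and tau, plus the
# per-pixel fraction of beats flagged as motion artifact.
.recording_features <- function(stack, mask, windows, channel,
                                flip_polarity = (channel == "vm"),
                                detrend_order = 1L, temporal_kernel_ms = 0,
                                beat_policy = "beat_average",
                                single_beat_k = 1L, tau_offset = TRUE,
                                act_kernel_ms = 3,
                                need = c("activation", "rise_time", "dur80",
                                         "tau")) {
  d <- dim(stack$data)
  n <- d[1]
  m <- mask$mask
  px <- which(as.vector(m))
  V <- matrix(stack$data, n, d[2] * d[3])[, px, drop = FALSE]
  if (flip_polarity) V <- -V
  if (detrend_order >= 1L)
    V <- apply(V, 2, .detrend_baseline, order = detrend_order)
  w <- .kernel_width(temporal_kernel_ms, stack$dt_ms)
  if (w > 1L) V <- apply(V, 2, .moving_average, w = w)

  nw <- length(windows)
  len <- windows[[1]]$i1 - windows[[1]]$i0 + 1L
  idx <- vapply(windows, function(b) b$i0:b$i1, integer(len))  # len x nw
  rel_t0 <- windows[[1]]$t0_ms - windows[[1]]$anchor_ms
  dt <- stack$dt_ms
  want_tau <- channel == "ca" && "tau" %in% need
  out <- list(act = rep(NA_real_, length(px)), rt = rep(NA_real_, length(px)),
              dur = rep(NA_real_, length(px)), tau = rep(NA_real_, length(px)),
              artifact_frac = rep(NA_real_, length(px)))
  safe <- function(expr) tryCatch(expr, trimap_error = function(e) NA_real_)
  for (j in seq_along(px)) {
    B <- matrix(V[idx, j], len, nw)
    rng <- apply(B, 2, range)
    amp <- rng[2, ] - rng[1, ]
    ok_amp <- amp > 0
    if (!any(ok_amp)) next
    B[, ok_amp] <- sweep(sweep(B[, ok_amp, drop = FALSE], 2,
                               rng[1, ok_amp], "-"),
                         2, amp[ok_amp], "/")
    # Motion artifact is a recording-level property (contraction affects
    # every beat), so probing three beats per pixel suffices; if any probed
    # beat is flagged, all beats of the pixel are treated as flagged.
    ok_idx <- which(ok_amp)
    probe <- ok_idx[unique(round(seq(1, length(ok_idx),
                                     length.out = min(3L, length(ok_idx)))))]
    flags <- vapply(probe, function(k)
      safe(flag_motion_artifact(beat_window(B[, k], dt, rel_t0)) ==
             "motion_artifact"), numeric(1))
    out$artifact_frac[j] <- mean(flags, na.rm = TRUE)
    clean <- if (any(flags == 1, na.rm = TRUE)) integer(0) else ok_idx
    w_act <- .kernel_width(act_kernel_ms, dt)
    feat_of <- function(bw, allow_repol) {
      # Activation for the map comes from a lightly smoothed beat: the
      # symmetric kernel does not bias the (symmetric) derivative peak but
      # damps its jitter. Crossing-based features stay unsmoothed.
      act_bw <- if (w_act > 1L)
        beat_window(.moving_average(bw$values, w_act), dt, bw$t0_ms) else bw
      c(act = if ("activation" %in% need) safe(activation_time(act_bw)) else NA,
        rt  = if ("rise_time" %in% need) safe(rise_time(bw)) else NA,
        dur = if (allow_repol && "dur80" %in% need) safe(duration80(bw)) else NA,
        tau = if (allow_repol && want_tau)
          safe(decay_tau(bw, offset = tau_offset)) else NA)
    }
    if (beat_policy == "beat_average") {
      use <- if (length(clean)) clean else which(ok_amp)
      bw <- beat_window(rowMeans(B[, use, drop = FALSE]), dt, rel_t0)
      f <- feat_of(bw, allow_repol = length(clean) > 0)
    } else if (beat_policy == "median_over_beats") {
      per <- vapply(which(ok_amp), function(k)
        feat_of(beat_window(B[, k], dt, rel_t0),
                allow_repol = k %in% clean), numeric(4))
      f <- apply(per, 1, stats::median, na.rm = TRUE)
      names(f) <- c("act", "rt", "dur", "tau")
    } else {  # single_beat_k
      k <- min(single_beat_k, nw)
      f <- feat_of(beat_window(B[, k], dt, rel_t0), allow_repol = k %in% clean)
    }
    out$act[j] <- f[["act"]]; out$rt[j] <- f[["rt"]]
    out$dur[j] <- f[["dur"]]; out$tau[j] <- f[["tau"]]
  }
  to_map <- function(v) {
    mm <- matrix(NA_real_, d[2], d[3])
    mm[px] <- v
    mm
  }
  list(activation = to_map(out$act), rise_time = to_map(out$rt),
       dur80 = to_map(out$dur), tau = to_map(out$tau),
       artifact_frac = to_map(out$artifact_frac))
}

#' Build a per-pixel parameter map
#'
#' Conditions every masked pixel trace (polarity, linear detrend, optional
#' temporal smoothing, per-beat min-max normalization), extracts the
#' requested morphometric feature beat by beat, and aggregates across beats
#' by the chosen policy. Activation values are reported relative to each
#' beat's upstroke anchor, giving all recordings a common time origin.
#'
#' @param stack a [movie_stack()] (spatially filtered upstream if desired).
#' @param mask a [compute_mask()] result.
#' @param feature one of `"activation"`, `"rise_time"`, `"dur80"`, `"tau"`.
#' @param beat_policy `"beat_average"` (ensemble-average aligned beats, then
#'   measure), `"median_over_beats"` (measure each beat, take the median),
#'   or `"single_beat_k"`.
#' @param bcl_ms pacing cycle length for beat segmentation (`NULL` to
#'   auto-detect).
#' @param windows precomputed [segment_beats()] windows (skips detection).
#' @param max_undefined_frac map-quality threshold: error if more than this
#'   fraction of masked pixels has no defined value.
#' @param ... further options passed to the feature extractor
#'   (`flip_polarity`, `detrend_order`, `temporal_kernel_ms`,
#'   `single_beat_k`, `tau_offset`).
#' @return a `parameter_map`.
#' @export
build_map <- function(stack, mask, feature = c("activation", "rise_time",
                                               "dur80", "tau"),
                      beat_policy = c("beat_average", "median_over_beats",
                                      "single_beat_k"),
                      bcl_ms = NULL, windows = NULL,
                      max_undefined_frac = 0.5, ...) {
  feature <- match.arg(feature)
  beat_policy <- match.arg(beat_policy)
  assert_that(inherits(stack, "movie_stack"), "stack must be a movie_stack")
  assert_that(inherits(mask, "tissue_mask"), "mask must be a tissue_mask")
  if (is.null(windows)) windows <- .global_windows(stack, mask, bcl_ms, ...)
  dots <- list(...)
  cond <- dots[names(dots) %in% c("flip_polarity", "detrend_order",
                                  "temporal_kernel_ms", "single_beat_k",
                                  "tau_offset", "act_kernel_ms")]
  maps <- do.call(.recording_features,
                  c(list(stack = stack, mask = mask, windows = windows,
                         channel = stack$channel, beat_policy = beat_policy,
                         need = feature), cond))
  vals <- maps[[feature]]
  frac_undef <- 1 - sum(is.finite(vals[mask$mask])) / sum(mask$mask)
  if (frac_undef > max_undefined_frac)
    abort_trimap(sprintf(
      "map quality: %.0f%% of masked pixels undefined for feature '%s'",
      100 * frac_undef, feature), "trimap_map_quality_error")
  .parameter_map(vals, feature)
}

# Beat windows from the spatially averaged conditioned trace.
.global_windows <- function(stack, mask, bcl_ms,
                            flip_polarity = (stack$channel == "vm"),
                            detrend_order = 1L, temporal_kernel_ms = 3, ...) {
  d <- dim(stack$data)
  mvec <- as.vector(mask$mask)
  mean_trace <- matrix(stack$data, d[1], d[2] * d[3])[, mvec, drop = FALSE] |>
    rowMeans()
  ct <- condition_trace(mean_trace, stack$dt_ms, flip_polarity = flip_polarity,
                        detrend_order = detrend_order,
                        temporal_kernel_ms = temporal_kernel_ms)
  segment_beats(ct, bcl_ms = bcl_ms)
}

# Conduction velocity ----------------------------------------------------------

.bilinear <- function(img, r, c_) {
  h <- nrow(img); w <- ncol(img)
  if (r < 1 || r > h || c_ < 1 || c_ > w) return(NA_real_)
  r0 <- floor(r); c0 <- floor(c_)
  r1 <- min(r0 + 1, h); c1 <- min(c0 + 1, w)
  fr <- r - r0; fc <- c_ - c0
  v <- c(img[r0, c0], img[r0, c1], img[r1, c0], img[r1, c1])
  if (any(!is.finite(v))) return(NA_real_)
  (1 - fr) * ((1 - fc) * v[1] + fc * v[2]) + fr * ((1 - fc) * v[3] + fc * v[4])
}

#' Conduction velocity from an activation map
#'
#' Samples activation times along two line profiles through the stimulus
#' site — parallel and perpendicular to the fiber axis — and regresses
#' distance (mm) on activation time (ms); the slope is the conduction
#' speed. The first `exclude_px` pixels around the stimulus are skipped
#' (virtual-electrode distortion), and a profile whose line fit has
#' r-squared below `min_r2` raises an unreliable-CV error, mirroring the
#' fit-acceptance threshold used for restitution models.
#'
#' @param act_map activation `parameter_map` (ms), or a plain matrix.
#' @param stim_rc stimulus (row, col) in px.
#' @param fiber_axis_deg fiber orientation, degrees from the +col axis
#'   towards +row.
#' @param pixel_mm pixel edge length in mm.
#' @param profile_len_px profile half-length in px.
#' @param exclude_px radius around the stimulus excluded from the fit.
#' @param band_px half-width of the lateral averaging band: each profile
#'   sample is the mean of `2 * band_px + 1` bilinear samples taken
#'   perpendicular to the profile, damping per-pixel activation jitter.
#' @param min_r2 minimum line-fit r-squared.
#' @return a `cv_result`: list with `cv_l`, `cv_t` (mm/ms), `ar`,
#'   `fit_r2_l`, `fit_r2_t`.
#' @export
conduction_velocity <- function(act_map, stim_rc, fiber_axis_deg, pixel_mm,
                                profile_len_px = 25L, exclude_px = 3L,
                                band_px = 1L, min_r2 = 0.5) {
  img <- if (inherits(act_map, "parameter_map")) act_map$values else act_map
  assert_that(is.matrix(img), "act_map must be a parameter_map or matrix")
  th <- fiber_axis_deg * pi / 180
  # Each half-profile (towards and away from the stimulus along the axis)
  # is fitted on its own: a wave radiating from the electrode is linear in
  # |r| on each side but not across the origin. The reported speed is the
  # mean of the usable sides.
  profile_cv <- function(dr, dc, label) {
    lat <- -band_px:band_px
    side_fit <- function(sgn) {
      r_off <- sgn * (exclude_px:profile_len_px)
      t_ms <- vapply(r_off, function(r) {
        v <- vapply(lat, function(b)
          .bilinear(img, stim_rc[1] + r * dr - b * dc,
                    stim_rc[2] + r * dc + b * dr), numeric(1))
        if (all(!is.finite(v))) NA_real_ else mean(v, na.rm = TRUE)
      }, numeric(1))
      ok <- is.finite(t_ms)
      if (sum(ok) < 5) return(NULL)
      dist_mm <- abs(r_off[ok]) * pixel_mm
      # Regress the noisy variable (activation time) on the exact one
      # (distance) and invert the slope: r-squared matches the
      # distance-on-time fit, without errors-in-regressor attenuation.
      fit <- stats::lm(t_ms[ok] ~ dist_mm)
      sl <- unname(stats::coef(fit)[2])
      ss_tot <- sum((t_ms[ok] - mean(t_ms[ok]))^2)
      r2 <- if (ss_tot > 0)
        1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
      list(r2 = r2, slope = sl)
    }
    sides <- Filter(Negate(is.null), list(side_fit(1), side_fit(-1)))
    if (!length(sides))
      abort_trimap(sprintf("activation undefined along the %s profile", label),
                   "trimap_unreliable_cv_error")
    r2 <- vapply(sides, `[[`, numeric(1), "r2")
    slopes <- vapply(sides, `[[`, numeric(1), "slope")
    if (any(!is.finite(r2)) || min(r2) < min_r2)
      abort_trimap(sprintf("unreliable CV: %s profile fit r2 = %.2f < %.2f",
                           label, min(r2, na.rm = TRUE), min_r2),
                   "trimap_unreliable_cv_error")
    if (any(!is.finite(slopes)) || any(abs(slopes) <= 0))
      abort_trimap(sprintf("unreliable CV: %s profile has a flat slope",
                           label), "trimap_unreliable_cv_error")
    list(cv = mean(1 / abs(slopes)), r2 = min(r2))
  }
  l <- profile_cv(sin(th), cos(th), "longitudinal")
  t <- profile_cv(cos(th), -sin(th), "transverse")
  structure(list(cv_l = l$cv, cv_t = t$cv, ar = l$cv / t$cv,
                 fit_r2_l = l$r2, fit_r2_t = t$r2), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> CV_L=%.3f CV_T=%.3f mm/ms  AR=%.2f  (r2 %.3f/%.3f)\n",
              x$cv_l, x$cv_t, x$ar, x$fit_r2_l, x$fit_r2_t))
  invisible(x)
}

# Vm-Ca delay and NADH ---------------------------------------------------------

#' Vm-to-calcium activation delay
#'
#' Per-pixel delay between voltage and calcium activation,
#' `t_act(ca) - t_act(vm)`, positive when calcium follows voltage; the
#' recording-level value is the mean over masked pixels. (The sign
#' convention is chosen so that a prolonged Vm upstroke with unchanged
#' calcium release *decreases* the delay.)
#'
#' @param act_vm,act_ca activation maps (ms) on the same raster.
#' @param mask a [compute_mask()] result.
#' @return list with `delay_ms` (scalar mean) and `map` (a
#'   `parameter_map`).
#' @export
vm_ca_delay <- function(act_vm, act_ca, mask) {
  v <- if (inherits(act_vm, "parameter_map")) act_vm$values else act_vm
  c_ <- if (inherits(act_ca, "parameter_map")) act_ca$values else act_ca
  assert_that(identical(dim(v), dim(c_)), "activation maps differ in shape")
  assert_that(identical(dim(v), dim(mask$mask)),
              "mask shape differs from the maps")
  delay <- c_ - v
  delay[!mask$mask] <- NA_real_
  list(delay_ms = mean(delay[mask$mask], na.rm = TRUE),
       map = .parameter_map(delay, "delay"))
}

#' NADH autofluorescence intensity
#'
#' Mean of the absolute autofluorescence intensity over all masked pixels
#' and all frames of the recording. No normalization is applied here; see
#' [normalize_nadh()].
#'
#' @param stack the NADH [movie_stack()].
#' @param mask a [compute_mask()] result.
#' @return mean intensity (a.u.).
#' @export
nadh_intensity <- function(stack, mask) {
  assert_that(inherits(stack, "movie_stack"), "stack must be a movie_stack")
  if (!any(mask$mask))
    abort_trimap("empty mask", "trimap_empty_mask_error")
  d <- dim(stack$data)
  mean(matrix(stack$data, d[1], d[2] * d[3])[, as.vector(mask$mask)])
}

#' Normalize an NADH intensity series to its first recording
#'
#' Each value in an ordered per-heart series is divided by the reference
#' element (the first recording of that heart by default), removing
#' between-heart staining and illumination differences.
#'
#' @param series numeric vector of raw NADH intensities, in recording
#'   order.
#' @param ref_index index of the reference recording (default the first).
#' @return normalized series; element `ref_index` is exactly 1.
#' @export
normalize_nadh <- function(series, ref_index = 1L) {
  assert_that(length(series) >= 1L, "series must be non-empty")
  assert_that(ref_index >= 1L && ref_index <= length(series),
              "ref_index out of range")
  ref <- series[ref_index]
  if (!is.finite(ref) || ref <= 0)
    abort_trimap("reference NADH intensity must be positive",
                 "trimap_degenerate_error")
  series / ref
}

# Recording summary -------------------------------------------------------------

#' Summarize a processed recording into the ten parameters
#'
#' Reduces per-pixel feature maps, the conduction-velocity result and the
#' NADH intensity of one co-registered triple recording to a single
#' ten-parameter record. Repolarization parameters (APD80, CaTD80, Ca tau)
#' are reported unavailable — with the reason — when the majority of beats
#' carries motion artifact, as in recordings without electromechanical
#' uncoupling.
#'
#' @param vm_maps,ca_maps named lists of feature maps for the vm / ca
#'   channel (`rise_time`, `dur80`, `tau`, `artifact_frac` as produced
#'   internally; any may be missing).
#' @param cv a `cv_result` or `NULL`.
#' @param delay_ms scalar Vm-Ca delay or `NA`.
#' @param nadh_raw scalar NADH intensity or `NA`.
#' @param mask a [compute_mask()] result.
#' @param reduce `"mean"` or `"median"` over masked pixels.
#' @param artifact_threshold fraction of artifact-flagged beats above which
#'   repolarization parameters are declared unavailable.
#' @param heart_id,condition,bcl_ms provenance carried into the record.
#' @return a `recording_parameters` object (also a one-row data.frame via
#'   [as.data.frame()]).
#' @export
summarize_recording <- function(vm_maps = list(), ca_maps = list(), cv = NULL,
                                delay_ms = NA_real_, nadh_raw = NA_real_,
                                mask = NULL, reduce = c("mean", "median"),
                                artifact_threshold = 0.5,
                                heart_id = NA_character_,
                                condition = NA_character_,
                                bcl_ms = NA_real_) {
  reduce <- match.arg(reduce)
  red <- function(map) {
    if (is.null(map)) return(NA_real_)
    v <- map[if (is.null(mask)) is.finite(map) else mask$mask]
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    if (reduce == "mean") mean(v) else stats::median(v)
  }
  artifact_frac <- function(maps) {
    af <- maps$artifact_frac
    if (is.null(af)) 0 else mean(af[is.finite(af)] , na.rm = TRUE)
  }
  vm_art <- artifact_frac(vm_maps); ca_art <- artifact_frac(ca_maps)
  repol_ok <- max(vm_art, ca_art, na.rm = TRUE) <= artifact_threshold
  p <- list(
    vm_rt = red(vm_maps$rise_time),
    apd80 = if (repol_ok) red(vm_maps$dur80) else NA_real_,
    cv_l = if (!is.null(cv)) cv$cv_l else NA_real_,
    cv_t = if (!is.null(cv)) cv$cv_t else NA_real_,
    ar = if (!is.null(cv)) cv$ar else NA_real_,
    ca_rt = red(ca_maps$rise_time),
    catd80 = if (repol_ok) red(ca_maps$dur80) else NA_real_,
    ca_tau = if (repol_ok) red(ca_maps$tau) else NA_real_,
    vm_ca_delay = delay_ms,
    nadh = NA_real_,            # filled in once the per-heart series is known
    nadh_raw = nadh_raw)
  reasons <- character(0)
  if (!repol_ok)
    reasons <- c(apd80 = "motion_artifact", catd80 = "motion_artifact",
                 ca_tau = "motion_artifact")
  available <- !vapply(p, is.na, logical(1))
  # NADH counts as measured once the raw intensity exists; the normalized
  # value is only defined relative to the heart's first recording.
  available["nadh"] <- is.finite(p$nadh_raw)
  structure(c(p, list(available = available,
                      unavailable_reason = reasons,
                      artifact_frac = max(vm_art, ca_art, na.rm = TRUE),
                      heart_id = heart_id, condition = condition,
                      bcl_ms = bcl_ms)),
            class = "recording_parameters")
}

#' @export
as.data.frame.recording_parameters <- function(x, ...) {
  data.frame(heart_id = x$heart_id, condition = x$condition, bcl_ms = x$bcl_ms,
             vm_rt = x$vm_rt, apd80 = x$apd80, cv_l = x$cv_l, cv_t = x$cv_t,
             ar = x$ar, ca_rt = x$ca_rt, catd80 = x$catd80, ca_tau = x$ca_tau,
             vm_ca_delay = x$vm_ca_delay, nadh = x$nadh, nadh_raw = x$nadh_raw,
             n_available = sum(x$available[.param_names]),
             stringsAsFactors = FALSE)
}

#' @export
print.recording_parameters <- function(x, ...) {
  cat(sprintf("<recording_parameters> heart=%s condition=%s BCL=%s ms\n",
              x$heart_id, x$condition, format(x$bcl_ms)))
  for (nm in .param_names)
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(x[[nm]])) {
                  r <- x$unavailable_reason[nm]
                  paste0("unavailable", if (!is.na(r)) paste0(" (", r, ")"))
                } else format(signif(x[[nm]], 4))))
  invisible(x)
}
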