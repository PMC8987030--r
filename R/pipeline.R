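# Recording-level and study-level orchestration -------------------------------

#' Analysis options
#'
#' Collected tunables of the recording pipeline. Defaults: tissue threshold
#' at 30% of the maximum mean intensity; spatial Gaussian smoothing of
#' sigma 1 px; no temporal smoothing (at 1 kHz a moving average materially
#' biases 2-8 ms upstrokes, so denoising is done spatially and by ensemble
#' averaging of beats); linear detrend; ensemble-average beat policy;
#' decay fits with an offset term; masked-mean map reduction; CV profiles
#' of 25 px skipping 3 px around the electrode, accepted at r2 >= 0.5.
#'
#' @param threshold_frac tissue mask threshold (fraction of max mean
#'   intensity).
#' @param sigma_px spatial Gaussian sigma in px (0 disables).
#' @param temporal_kernel_ms temporal moving-average length in ms (0
#'   disables).
#' @param detrend_order polynomial order of the baseline removed per pixel.
#' @param flip_vm invert the vm channel (voltage dye brightens at rest).
#' @param beat_policy `"beat_average"`, `"median_over_beats"`, or
#'   `"single_beat_k"`.
#' @param tau_offset include an offset term in calcium decay fits.
#' @param act_kernel_ms symmetric moving-average length (ms) applied only
#'   for the activation estimate of the per-pixel maps (0 disables).
#' @param reduce `"mean"` or `"median"` reduction of maps to scalars.
#' @param profile_len_px,exclude_px,min_r2 see [conduction_velocity()].
#' @param artifact_threshold see [summarize_recording()].
#' @param coregister estimate and apply channel translations before
#'   analysis (reference: vm).
#' @param max_shift_px search bound for co-registration.
#' @return named list of options.
#' @export
analysis_options <- function(threshold_frac = 0.3, sigma_px = 1,
                             temporal_kernel_ms = 0, detrend_order = 1L,
                             flip_vm = TRUE,
                             beat_policy = c("beat_average",
                                             "median_over_beats",
                                             "single_beat_k"),
                             tau_offset = TRUE, act_kernel_ms = 3,
                             reduce = c("mean", "median"),
                             profile_len_px = 25L, exclude_px = 3L,
                             min_r2 = 0.5, artifact_threshold = 0.5,
                             coregister = FALSE, max_shift_px = 10L) {
  list(threshold_frac = threshold_frac, sigma_px = sigma_px,
       temporal_kernel_ms = temporal_kernel_ms, detrend_order = detrend_order,
       flip_vm = flip_vm, beat_policy = match.arg(beat_policy),
       tau_offset = tau_offset, act_kernel_ms = act_kernel_ms,
       reduce = match.arg(reduce),
       profile_len_px = profile_len_px, exclude_px = exclude_px,
       min_r2 = min_r2, artifact_threshold = artifact_threshold,
       coregister = coregister, max_shift_px = max_shift_px)
}

#' Analyze one co-registered triple recording
#'
#' Runs the full single-recording pipeline: tissue masking on the vm
#' channel, optional co-registration (vm as reference) and spatial
#' smoothing, beat segmentation on the spatially averaged vm trace,
#' per-pixel morphometrics of both beat channels, conduction-velocity
#' estimation from the vm activation map, the Vm-Ca activation delay, and
#' the NADH intensity; all reduced to one ten-parameter record.
#'
#' @param vm,ca,nadh [movie_stack()]s of the three channels (any may be
#'   `NULL` except `vm` when beats are analyzed; an NADH-only call computes
#'   just the intensity).
#' @param stim_rc stimulus (row, col) in px.
#' @param fiber_axis_deg fiber orientation in degrees.
#' @param bcl_ms pacing cycle length (`NULL` auto-detects).
#' @param options an [analysis_options()] list.
#' @param heart_id,condition provenance labels.
#' @param keep_maps also return the per-pixel feature maps.
#' @return a `recording_parameters` object; with `keep_maps = TRUE`, a list
#'   `(params, maps, mask, windows)`.
#' @export
analyze_recording <- function(vm = NULL, ca = NULL, nadh = NULL,
                              stim_rc = NULL, fiber_axis_deg = 0,
                              bcl_ms = NULL, options = analysis_options(),
                              heart_id = NA_character_,
                              condition = NA_character_, keep_maps = FALSE) {
  opts <- options
  mask_src <- if (!is.null(vm)) vm else if (!is.null(nadh)) nadh else ca
  assert_that(!is.null(mask_src), "at least one channel is required")
  mask <- compute_mask(mask_src, opts$threshold_frac)

  if (isTRUE(opts$coregister) && !is.null(vm)) {
    for (nm in c("ca", "nadh")) {
      mov <- get(nm)
      if (is.null(mov)) next
      al <- coregister(vm, mov, max_shift_px = opts$max_shift_px)
      assign(nm, apply_shift(mov, al$shift_rc))
    }
  }
  vm_maps <- ca_maps <- list()
  cv <- NULL
  delay <- NA_real_
  windows <- NULL
  cv_reason <- NULL
  if (!is.null(vm)) {
    vm_f <- spatial_filter(vm, opts$sigma_px, mask)
    windows <- .global_windows(vm_f, mask, bcl_ms,
                               flip_polarity = opts$flip_vm,
                               detrend_order = opts$detrend_order)
    vm_maps <- .recording_features(
      vm_f, mask, windows, "vm", flip_polarity = opts$flip_vm,
      detrend_order = opts$detrend_order,
      temporal_kernel_ms = opts$temporal_kernel_ms,
      beat_policy = opts$beat_policy, tau_offset = opts$tau_offset,
      act_kernel_ms = opts$act_kernel_ms)
    if (!is.null(stim_rc))
      cv <- tryCatch(
        conduction_velocity(vm_maps$activation, stim_rc, fiber_axis_deg,
                            vm$pixel_mm, profile_len_px = opts$profile_len_px,
                            exclude_px = opts$exclude_px, min_r2 = opts$min_r2),
        trimap_error = function(e) { cv_reason <<- conditionMessage(e); NULL })
  }
  if (!is.null(ca) && !is.null(windows)) {
    ca_f <- spatial_filter(ca, opts$sigma_px, mask)
    ca_maps <- .recording_features(
      ca_f, mask, windows, "ca", flip_polarity = FALSE,
      detrend_order = opts$detrend_order,
      temporal_kernel_ms = opts$temporal_kernel_ms,
      beat_policy = opts$beat_policy, tau_offset = opts$tau_offset,
      act_kernel_ms = opts$act_kernel_ms)
    if (length(vm_maps))
      delay <- vm_ca_delay(vm_maps$activation, ca_maps$activation,
                           mask)$delay_ms
  }
  nadh_raw <- if (!is.null(nadh)) nadh_intensity(nadh, mask) else NA_real_
  params <- summarize_recording(
    vm_maps = vm_maps, ca_maps = ca_maps, cv = cv, delay_ms = delay,
    nadh_raw = nadh_raw, mask = mask, reduce = opts$reduce,
    artifact_threshold = opts$artifact_threshold,
    heart_id = heart_id, condition = condition,
    bcl_ms = if (is.null(bcl_ms)) NA_real_ else bcl_ms)
  if (!is.null(cv_reason))
    params$unavailable_reason <- c(params$unavailable_reason,
                                   cv_l = cv_reason, cv_t = cv_reason,
                                   ar = cv_reason)
  if (!keep_maps) return(params)
  list(params = params,
       maps = list(vm = vm_maps, ca = ca_maps),
       mask = mask, windows = windows)
}

#' Per-heart NADH normalization of a parameter table
#'
#' Fills the `nadh` column with each recording's `nadh_raw` divided by the
#' first (in row order) finite `nadh_raw` of the same heart.
#'
#' @param params data.frame with `heart_id` and `nadh_raw` columns.
#' @return the data.frame with `nadh` filled.
#' @export
normalize_nadh_by_heart <- function(params) {
  assert_that(all(c("heart_id", "nadh_raw") %in% names(params)),
              "params must have heart_id and nadh_raw columns")
  params$nadh <- NA_real_
  for (h in unique(params$heart_id)) {
    i <- which(params$heart_id == h & is.finite(params$nadh_raw))
    if (!length(i)) next
    params$nadh[i] <- normalize_nadh(params$nadh_raw[i])
  }
  params
}

#' Analyze every recording of a manifest
#'
#' Reads the three channel files of each manifest entry, runs
#' [analyze_recording()], normalizes NADH per heart, and (optionally)
#' writes the parameter table, per-pixel maps (float TIFF + CSV), and a QC
#' report to `out_dir`.
#'
#' @param manifest data.frame (see [read_manifest()]) or a path to the CSV.
#' @param options an [analysis_options()] list.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param strict abort on the first failing entry instead of flagging it.
#' @return data.frame of per-recording parameters (one row per entry, NA
#'   and `error` column for failed entries).
#' @export
analyze_manifest <- function(manifest, options = analysis_options(),
                             out_dir = NULL, strict = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  manifest <- validate_manifest(manifest)
  rows <- list()
  qc <- list()
  for (i in seq_len(nrow(manifest))) {
    e <- manifest[i, ]
    res <- tryCatch({
      vm <- read_movie(e$vm_path)
      ca <- read_movie(e$ca_path)
      nadh <- read_movie(e$nadh_path)
      out <- analyze_recording(vm, ca, nadh,
                               stim_rc = c(e$stim_row, e$stim_col),
                               fiber_axis_deg = e$fiber_axis_deg,
                               bcl_ms = e$bcl_ms, options = options,
                               heart_id = e$heart_id, condition = e$condition,
                               keep_maps = !is.null(out_dir))
      out
    }, trimap_error = function(err) err, error = function(err) err)
    if (inherits(res, "error")) {
      if (strict)
        abort_trimap(sprintf("entry %d (%s/%s): %s", i, e$heart_id,
                             e$condition, conditionMessage(res)),
                     "trimap_run_error")
      row <- data.frame(heart_id = e$heart_id, condition = e$condition,
                        bcl_ms = e$bcl_ms, vm_rt = NA, apd80 = NA, cv_l = NA,
                        cv_t = NA, ar = NA, ca_rt = NA, catd80 = NA,
                        ca_tau = NA, vm_ca_delay = NA, nadh = NA,
                        nadh_raw = NA, n_available = 0L)
      row$error <- conditionMessage(res)
      qc[[i]] <- list(entry = i, status = "failed",
                      message = conditionMessage(res))
    } else {
      params <- if (!is.null(out_dir)) res$params else res
      row <- as.data.frame(params)
      row$error <- NA_character_
      qc[[i]] <- list(entry = i, status = "ok",
                      n_available = row$n_available,
                      artifact_frac = params$artifact_frac,
                      unavailable = as.list(params$unavailable_reason))
      if (!is.null(out_dir)) {
        tag <- sprintf("%s_%s_bcl%g", e$heart_id, e$condition, e$bcl_ms)
        for (ch in c("vm", "ca")) for (ft in names(res$maps[[ch]])) {
          map <- res$maps[[ch]][[ft]]
          if (all(!is.finite(map))) next
          export_map(.parameter_map(map, ft), out_dir,
                     paste(tag, ch, ft, sep = "_"))
        }
      }
    }
    rows[[i]] <- row
  }
  params <- do.call(rbind, rows)
  params <- normalize_nadh_by_heart(params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(params, file.path(out_dir, "parameters.csv"),
                     row.names = FALSE)
    jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  params
}

#' Export a parameter map as float TIFF and CSV
#'
#' @param map a `parameter_map`.
#' @param dir output directory (created if missing).
#' @param name basename without extension.
#' @return paths of the two written files, invisibly.
#' @export
export_map <- function(map, dir, name) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- map$values
  tif <- file.path(dir, paste0(name, ".tif"))
  vv <- v
  vv[!is.finite(vv)] <- min(v[is.finite(v)], 0)
  lo <- min(vv); hi <- max(vv)
  tiff::writeTIFF((vv - lo) / max(hi - lo, 1e-12), tif,
                  bits.per.sample = 32L)
  csv <- file.path(dir, paste0(name, ".csv"))
  idx <- which(is.finite(v), arr.ind = TRUE)
  utils::write.csv(data.frame(row = idx[, 1], col = idx[, 2],
                              value = v[idx]),
                   csv, row.names = FALSE)
  invisible(c(tif, csv))
}

# Restitution study -------------------------------------------------------------

#' Restitution study over a parameter table
#'
#' For every parameter, fits its default restitution model (see
#' [default_restitution_models()]) separately per condition and pooled over
#' both, across the available BCLs, and compares pooled vs separate fits
#' with the extra sum-of-squares F test. Parameters without enough distinct
#' BCLs for the model are skipped with a reason. Fit acceptance (r2 > 0.5)
#' is reported per fit, not silently enforced.
#'
#' @param params data.frame with `condition`, `bcl_ms` and parameter
#'   columns.
#' @param reference,treatment condition labels compared.
#' @param parameters parameter columns to fit.
#' @param models named model map overriding the defaults.
#' @return data.frame with one row per parameter: model, per-condition r2,
#'   F, p, and `skipped` reason where applicable.
#' @export
restitution_study <- function(params, reference, treatment,
                              parameters = intersect(.param_names,
                                                     names(params)),
                              models = default_restitution_models()) {
  assert_that(all(c("condition", "bcl_ms") %in% names(params)),
              "params must have condition and bcl_ms columns")
  rows <- lapply(parameters, function(pm) {
    model <- if (pm %in% names(models)) models[[pm]] else "linear"
    p_need <- switch(model, exp_plateau = 3L, poly3 = 4L, linear = 2L) + 1L
    sub <- params[params$condition %in% c(reference, treatment) &
                    is.finite(params[[pm]]), c("condition", "bcl_ms", pm)]
    counts <- tapply(sub$bcl_ms, sub$condition, function(x) length(unique(x)))
    base <- data.frame(parameter = pm, model = model, r2_reference = NA_real_,
                       r2_treatment = NA_real_, F = NA_real_, p = NA_real_,
                       skipped = NA_character_)
    if (length(counts) < 2L || any(counts < p_need)) {
      base$skipped <- sprintf("needs >= %d BCLs per condition", p_need)
      return(base)
    }
    fit_of <- function(cond) {
      s <- sub[sub$condition == cond, ]
      fit_restitution(s$bcl_ms, s[[pm]], model)
    }
    res <- tryCatch({
      f_ref <- fit_of(reference)
      f_trt <- fit_of(treatment)
      f_pool <- fit_restitution(sub$bcl_ms, sub[[pm]], model)
      ft <- extra_ss_f_test(f_pool, list(f_ref, f_trt))
      base$r2_reference <- f_ref$r2
      base$r2_treatment <- f_trt$r2
      base$F <- ft$F
      base$p <- ft$p
      base
    }, trimap_error = function(e) {
      base$skipped <- conditionMessage(e)
      base
    })
    res
  })
  do.call(rbind, rows)
}
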