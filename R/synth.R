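# Synthetic triple-channel recordings with closed-form ground truth.
#
# The simulator is kinematic, not reaction-diffusion: an elliptical wave of
# constant longitudinal/transverse speed sweeps a tissue silhouette, and
# every pixel plays a template waveform delayed by its analytic activation
# time. Each morphological truth (rise time, APD80/CaTD80, decay tau, Vm-Ca
# delay) is placed into the template in closed form, so the whole analysis
# pipeline can be verified by parameter recovery.

.param_names <- c("vm_rt", "apd80", "cv_l", "cv_t", "ar", "ca_rt", "catd80",
                  "ca_tau", "vm_ca_delay", "nadh")

#' Simulation configuration
#'
#' Defines one synthetic recording: raster geometry, pacing, the true value
#' of every measured parameter, noise, and optional motion artifact. The
#' defaults emulate the acquisition used throughout: 100 x 100 px at 0.1 mm,
#' 1 kHz, 2 s, pacing from a central electrode at BCL 200 ms, with
#' mouse-like parameter values (4 ms Vm rise time, 40 ms APD80, 0.5/0.25
#' mm/ms conduction speeds, 3 ms Vm-Ca delay).
#'
#' @param height,width raster size in px.
#' @param pixel_mm pixel edge length in mm.
#' @param dt_ms sampling interval in ms.
#' @param duration_ms recording length in ms.
#' @param bcl_ms pacing basic cycle length in ms.
#' @param stim_rc stimulus (row, col); default raster center.
#' @param fiber_axis_deg fiber orientation, degrees from the +col axis
#'   towards +row.
#' @param cv_l_true,cv_t_true longitudinal/transverse conduction speed,
#'   mm/ms (`cv_l_true >= cv_t_true > 0`).
#' @param vm_rt_true,ca_rt_true 20-90% rise times, ms.
#' @param apd80_true,catd80_true durations at 80% recovery, ms.
#' @param tau_true calcium decay constant, ms.
#' @param delay_true Vm-to-Ca activation delay, ms (positive: calcium
#'   follows voltage).
#' @param nadh_level_true mean NADH intensity, a.u.
#' @param noise_sigma Gaussian noise s.d. as a fraction of beat amplitude
#'   (SNR = 1/noise_sigma).
#' @param motion_artifact list `(on, amplitude, freq_hz)`: repolarization-
#'   windowed sinusoid emulating contraction artifact.
#' @param nadh_drift_mult multiplicative NADH level at the end of the
#'   recording (1 = no drift), linear in time.
#' @param plateau_ms template plateau length between upstroke and decay.
#' @param silhouette `"ellipse"` (inscribed, 90% semi-axes) or `"full"`.
#' @param seed integer seed; rendering is deterministic given the seed.
#' @return a `sim_config` list, validated for mutual feasibility.
#' @export
sim_config <- function(height = 100L, width = 100L, pixel_mm = 0.1,
                       dt_ms = 1, duration_ms = 2000, bcl_ms = 200,
                       stim_rc = NULL, fiber_axis_deg = 0,
                       cv_l_true = 0.5, cv_t_true = 0.25,
                       vm_rt_true = 4, ca_rt_true = 8,
                       apd80_true = 40, catd80_true = 60, tau_true = 30,
                       delay_true = 3, nadh_level_true = 1200,
                       noise_sigma = 0,
                       motion_artifact = list(on = FALSE, amplitude = 0.3,
                                              freq_hz = 8),
                       nadh_drift_mult = 1, plateau_ms = 2,
                       silhouette = c("ellipse", "full"), seed = 1L) {
  silhouette <- match.arg(silhouette)
  if (is.null(stim_rc)) stim_rc <- c(round(height / 2), round(width / 2))
  cfg <- list(height = as.integer(height), width = as.integer(width),
              pixel_mm = pixel_mm, dt_ms = dt_ms, duration_ms = duration_ms,
              bcl_ms = bcl_ms, stim_rc = stim_rc,
              fiber_axis_deg = fiber_axis_deg,
              cv_l_true = cv_l_true, cv_t_true = cv_t_true,
              vm_rt_true = vm_rt_true, ca_rt_true = ca_rt_true,
              apd80_true = apd80_true, catd80_true = catd80_true,
              tau_true = tau_true, delay_true = delay_true,
              nadh_level_true = nadh_level_true, noise_sigma = noise_sigma,
              motion_artifact = motion_artifact,
              nadh_drift_mult = nadh_drift_mult, plateau_ms = plateau_ms,
              silhouette = silhouette, seed = as.integer(seed))
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a `sim_config` list.
#' @export
validate_sim_config <- function(cfg) {
  assert_that(cfg$cv_l_true >= cfg$cv_t_true && cfg$cv_t_true > 0,
              "speeds must satisfy cv_l_true >= cv_t_true > 0",
              class = "trimap_config_error")
  assert_that(cfg$height >= 8L && cfg$width >= 8L, "raster must be >= 8 px",
              class = "trimap_config_error")
  durs <- c(cfg$vm_rt_true, cfg$ca_rt_true, cfg$apd80_true, cfg$catd80_true,
            cfg$tau_true)
  assert_that(all(durs > 0) && all(durs < cfg$bcl_ms),
              "all durations must be positive and shorter than bcl_ms",
              class = "trimap_config_error")
  if (cfg$apd80_true <= cfg$vm_rt_true + cfg$plateau_ms)
    abort_trimap("infeasible template: apd80_true must exceed rise + plateau",
                 "trimap_config_error")
  if (cfg$catd80_true - cfg$tau_true * log(2.5) <=
      cfg$ca_rt_true + cfg$plateau_ms)
    abort_trimap(paste0("infeasible template: catd80_true - tau*log(2.5) must ",
                        "exceed ca rise + plateau"), "trimap_config_error")
  s <- cfg$stim_rc
  assert_that(s[1] >= 1 && s[1] <= cfg$height && s[2] >= 1 && s[2] <= cfg$width,
              "stim_rc must lie inside the raster", class = "trimap_config_error")
  cfg
}

#' Tissue silhouette of a simulated recording
#'
#' @param cfg a [sim_config()].
#' @return logical height x width matrix.
#' @export
silhouette_mask <- function(cfg) {
  if (cfg$silhouette == "full") return(matrix(TRUE, cfg$height, cfg$width))
  r <- matrix(seq_len(cfg$height), cfg$height, cfg$width)
  c_ <- matrix(seq_len(cfg$width), cfg$height, cfg$width, byrow = TRUE)
  cr <- (cfg$height + 1) / 2; cc <- (cfg$width + 1) / 2
  ((r - cr) / (0.45 * cfg$height))^2 + ((c_ - cc) / (0.45 * cfg$width))^2 <= 1
}

#' Analytic activation field of the elliptical wave
#'
#' `t_act(x, y) = sqrt(u^2 / cv_l^2 + v^2 / cv_t^2)` where (u, v) are the mm
#' offsets from the stimulus site rotated into the fiber frame. Times are
#' relative to the stimulus; the pattern repeats every pacing cycle.
#'
#' @param cfg a [sim_config()].
#' @return numeric height x width matrix of activation times in ms.
#' @export
activation_field <- function(cfg) {
  r <- matrix(seq_len(cfg$height), cfg$height, cfg$width)
  c_ <- matrix(seq_len(cfg$width), cfg$height, cfg$width, byrow = TRUE)
  dx <- (c_ - cfg$stim_rc[2]) * cfg$pixel_mm
  dy <- (r - cfg$stim_rc[1]) * cfg$pixel_mm
  th <- cfg$fiber_axis_deg * pi / 180
  u <- cos(th) * dx + sin(th) * dy
  v <- -sin(th) * dx + cos(th) * dy
  sqrt((u / cfg$cv_l_true)^2 + (v / cfg$cv_t_true)^2)
}

#' Unit-amplitude waveform templates
#'
#' Builds the action-potential and calcium-transient templates so that the
#' standard morphometric definitions recover the configured truths exactly:
#' a raised-cosine upstroke whose 20-90% span equals the rise time and whose
#' maximum derivative sits at template time 0 (the activation time); a short
#' plateau; and for Vm an exponential repolarization whose 20% down-crossing
#' falls exactly `apd80_true` after activation. The calcium decay has two
#' phases: a linear early phase from peak to the 50% level, then a single
#' exponential with constant `tau_true`, positioned so the 20% down-crossing
#' falls `catd80_true` after activation.
#'
#' @param cfg a [sim_config()].
#' @return list of vectorized functions `ap(u)`, `cat(u)` of time since
#'   activation (ms), plus the analytic anchor times.
#' @export
waveform_templates <- function(cfg) {
  validate_sim_config(cfg)
  P <- cfg$plateau_ms
  make_upstroke <- function(rt) {
    force(rt)
    function(u) 0.5 * (1 - cos(pi * (u + rt) / (2 * rt)))
  }
  rt_v <- cfg$vm_rt_true
  tau_rep <- (cfg$apd80_true - rt_v - P) / log(5)
  ap <- function(u) {
    y <- numeric(length(u))
    up <- u >= -rt_v & u < rt_v
    y[up] <- make_upstroke(rt_v)(u[up])
    y[u >= rt_v & u < rt_v + P] <- 1
    dec <- u >= rt_v + P
    y[dec] <- exp(-(u[dec] - rt_v - P) / tau_rep)
    y
  }
  rt_c <- cfg$ca_rt_true
  u50 <- cfg$catd80_true - cfg$tau_true * log(2.5)  # 50% down-crossing time
  cat_ <- function(u) {
    y <- numeric(length(u))
    up <- u >= -rt_c & u < rt_c
    y[up] <- make_upstroke(rt_c)(u[up])
    y[u >= rt_c & u < rt_c + P] <- 1
    lin <- u >= rt_c + P & u < u50
    y[lin] <- 1 - 0.5 * (u[lin] - rt_c - P) / (u50 - rt_c - P)
    dec <- u >= u50
    y[dec] <- 0.5 * exp(-(u[dec] - u50) / cfg$tau_true)
    y
  }
  list(ap = ap, cat = cat_, vm_upstroke_halfspan_ms = rt_v,
       ca_upstroke_halfspan_ms = rt_c, vm_rep_tau_ms = tau_rep,
       ca_t50_ms = u50)
}

#' Ground truth implied by a simulation configuration
#'
#' @param cfg a [sim_config()].
#' @return list with the named ten-parameter vector `params`, the analytic
#'   per-pixel activation field, the silhouette, and the stimulus times.
#' @export
ground_truth <- function(cfg) {
  validate_sim_config(cfg)
  stim_times <- .stim_times(cfg)
  params <- c(vm_rt = cfg$vm_rt_true, apd80 = cfg$apd80_true,
              cv_l = cfg$cv_l_true, cv_t = cfg$cv_t_true,
              ar = cfg$cv_l_true / cfg$cv_t_true,
              ca_rt = cfg$ca_rt_true, catd80 = cfg$catd80_true,
              ca_tau = cfg$tau_true, vm_ca_delay = cfg$delay_true,
              nadh = cfg$nadh_level_true)
  list(params = params, act_field = activation_field(cfg),
       silhouette = silhouette_mask(cfg), stim_times_ms = stim_times)
}

.stim_times <- function(cfg, first_ms = 20) {
  seq(first_ms, cfg$duration_ms - 1, by = cfg$bcl_ms)
}

# Evaluate a periodic template over a frames x pixels phase matrix.
.periodic_response <- function(tmpl, t_ms, act_ms, bcl, lead) {
  v <- outer(t_ms, act_ms, "-")            # frames x npx, ms since activation
  phi <- ((v + lead) %% bcl) - lead        # wrap into [-lead, bcl - lead)
  matrix(tmpl(as.vector(phi)), nrow = length(t_ms))
}

#' Render a synthetic triple-channel recording
#'
#' Produces the three co-registered movie stacks implied by a
#' [sim_config()]: the Vm channel (dye polarity inverted: fluorescence drops
#' on depolarization), the calcium channel (delayed by the configured Vm-Ca
#' delay), and the NADH channel (slow intensity field without beats).
#' Gaussian noise is added everywhere at `noise_sigma` of the beat
#' amplitude; an optional repolarization-windowed sinusoid emulates motion
#' artifact. Rendering is deterministic for a given `seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `vm`, `ca`, `nadh` ([movie_stack()]s) and `truth`
#'   ([ground_truth()]).
#' @export
render_recording <- function(cfg) {
  validate_sim_config(cfg)
  truth <- ground_truth(cfg)
  tm <- waveform_templates(cfg)
  sil <- truth$silhouette
  act <- truth$act_field
  t_ms <- (seq_len(round(cfg$duration_ms / cfg$dt_ms)) - 1) * cfg$dt_ms
  first <- truth$stim_times_ms[1]
  npx <- cfg$height * cfg$width
  amp <- 600; vm_base <- 2000; ca_base <- 800; bg <- 50
  lead_v <- cfg$vm_rt_true + 1
  lead_c <- cfg$ca_rt_true + 1

  resp_vm <- .periodic_response(tm$ap, t_ms, first + as.vector(act),
                                cfg$bcl_ms, lead_v)
  resp_ca <- .periodic_response(tm$cat, t_ms,
                                first + as.vector(act) + cfg$delay_true,
                                cfg$bcl_ms, lead_c)
  if (isTRUE(cfg$motion_artifact$on)) {
    ma <- cfg$motion_artifact
    art_t <- ma$amplitude * sin(2 * pi * ma$freq_hz * t_ms / 1000)
    win_vm <- .artifact_window(tm, t_ms, first + as.vector(act), cfg, "vm")
    win_ca <- .artifact_window(tm, t_ms,
                               first + as.vector(act) + cfg$delay_true,
                               cfg, "ca")
    resp_vm <- resp_vm + art_t * win_vm
    resp_ca <- resp_ca + art_t * win_ca
  }
  sil_v <- as.vector(sil)
  frame_of <- function(resp, base, sign) {
    m <- matrix(bg, length(t_ms), npx)
    m[, sil_v] <- base + sign * amp * resp[, sil_v]
    m
  }
  vm_m <- frame_of(resp_vm, vm_base, -1)   # dye polarity: down on depolarization
  ca_m <- frame_of(resp_ca, ca_base, +1)
  drift <- 1 + (cfg$nadh_drift_mult - 1) * t_ms / max(t_ms)
  nadh_m <- matrix(bg, length(t_ms), npx)
  nadh_m[, sil_v] <- outer(drift * cfg$nadh_level_true, rep(1, sum(sil_v)))

  with_seed(cfg$seed, {
    if (cfg$noise_sigma > 0) {
      sd_beat <- cfg$noise_sigma * amp
      vm_m <- vm_m + stats::rnorm(length(vm_m), 0, sd_beat)
      ca_m <- ca_m + stats::rnorm(length(ca_m), 0, sd_beat)
      nadh_m <- nadh_m + stats::rnorm(length(nadh_m),
                                      0, cfg$noise_sigma * cfg$nadh_level_true)
    }
  })
  as_stack <- function(m, channel) {
    movie_stack(array(m, dim = c(length(t_ms), cfg$height, cfg$width)),
                dt_ms = cfg$dt_ms, pixel_mm = cfg$pixel_mm, channel = channel,
                meta = list(simulated = "TRUE", seed = cfg$seed,
                            bcl_ms = cfg$bcl_ms))
  }
  list(vm = as_stack(vm_m, "vm"), ca = as_stack(ca_m, "ca"),
       nadh = as_stack(nadh_m, "nadh"), truth = truth)
}

# Repolarization-phase window (frames x pixels, 0/1 with cosine tapers) in
# which the motion-artifact sinusoid is active.
.artifact_window <- function(tm, t_ms, act_ms, cfg, channel) {
  rt <- if (channel == "vm") cfg$vm_rt_true else cfg$ca_rt_true
  u0 <- rt + cfg$plateau_ms + 15   # leave the peak region artifact-free
  u1 <- 0.85 * cfg$bcl_ms
  lead <- rt + 1
  v <- outer(t_ms, act_ms, "-")
  phi <- ((v + lead) %% cfg$bcl_ms) - lead
  taper <- 5
  w <- pmin(pmax((phi - u0) / taper, 0), 1) *
       pmin(pmax((u1 - phi) / taper, 0), 1)
  0.5 * (1 - cos(pi * pmin(w, 1)))   # smooth on/off
}

# Condition scripts ------------------------------------------------------------

#' Condition scripts for simulated experiments
#'
#' Expands a base configuration into the per-condition configurations of a
#' simulated experiment, applying multiplicative effects to the named
#' truths. The qualitative patterns mirror the pharmacology they emulate:
#' an electromechanical uncoupler removes motion artifact and prolongs both
#' rise times while lowering NADH; an Ito blocker prolongs APD80 and Ca rise
#' time and slows transverse conduction; an ICaL blocker prolongs only the
#' calcium rise time; no-flow ischemia raises NADH first (minute 1), then
#' slows CV_T (minute 3), then prolongs Vm RT (minute 5), and reperfusion
#' restores every truth to baseline.
#'
#' @param base a [sim_config()] for the reference condition.
#' @param scenario one of `"uncoupler"`, `"ito_block"`, `"ical_block"`,
#'   `"ischemia_reperfusion"`.
#' @param effects named list of effect multipliers overriding the defaults
#'   `rt_mult = 1.2, apd_mult = 1.25, cvt_mult = 0.8, nadh_mult = 1.3,
#'   ca_rt_mult = 1.3, nadh_uncoupler_mult = 0.85`.
#' @return named list of `sim_config`s, one per condition/timepoint; each
#'   has `$condition` set.
#' @export
condition_script <- function(base,
                             scenario = c("uncoupler", "ito_block",
                                          "ical_block",
                                          "ischemia_reperfusion"),
                             effects = list()) {
  scenario <- match.arg(scenario)
  validate_sim_config(base)
  eff <- utils::modifyList(
    list(rt_mult = 1.2, apd_mult = 1.25, cvt_mult = 0.8, nadh_mult = 1.3,
         ca_rt_mult = 1.3, nadh_uncoupler_mult = 0.85), effects)
  mod <- function(cfg, condition, ..., artifact = FALSE) {
    ch <- list(...)
    for (nm in names(ch)) cfg[[nm]] <- cfg[[nm]] * ch[[nm]]
    cfg$motion_artifact$on <- artifact
    cfg <- validate_sim_config(cfg)
    cfg$condition <- condition
    cfg
  }
  out <- switch(scenario,
    uncoupler = list(
      control = mod(base, "control", artifact = TRUE),
      blebbistatin = mod(base, "blebbistatin",
                         vm_rt_true = eff$rt_mult, ca_rt_true = eff$rt_mult,
                         nadh_level_true = eff$nadh_uncoupler_mult)),
    ito_block = list(
      blebbistatin = mod(base, "blebbistatin"),
      ito_block = mod(base, "ito_block",
                      apd80_true = eff$apd_mult, ca_rt_true = eff$rt_mult,
                      cv_t_true = eff$cvt_mult)),
    ical_block = list(
      blebbistatin = mod(base, "blebbistatin"),
      ical_block = mod(base, "ical_block", ca_rt_true = eff$ca_rt_mult)),
    ischemia_reperfusion = {
      cfgs <- list(baseline = mod(base, "baseline"))
      for (m in 1:5) {
        ch <- list()
        if (m >= 1) ch$nadh_level_true <- eff$nadh_mult
        if (m >= 3) ch$cv_t_true <- eff$cvt_mult
        if (m >= 5) ch$vm_rt_true <- eff$rt_mult
        cfgs[[paste0("ischemia_", m)]] <-
          do.call(mod, c(list(base, paste0("ischemia_", m)), ch))
      }
      for (m in 1:5)
        cfgs[[paste0("reperfusion_", m)]] <- mod(base, paste0("reperfusion_", m))
      cfgs
    })
  out
}

# Measurement-level panel simulation ------------------------------------------

#' Simulate per-heart recording parameters for a condition script
#'
#' Measurement-level surrogate for a full rendered experiment: for each
#' simulated heart, every true parameter receives a log-normal
#' between-heart multiplier (shared across conditions of that heart), and
#' each recording adds independent Gaussian measurement noise. The
#' anisotropic ratio is always computed from the (noisy) conduction speeds,
#' keeping it self-consistent. Used to exercise the ten-parameter-panel
#' statistics at scale without rendering movies.
#'
#' @param base a [sim_config()].
#' @param scenario passed to [condition_script()].
#' @param n_hearts number of simulated hearts.
#' @param noise_frac s.d. of the per-recording measurement noise, as a
#'   fraction of the parameter value.
#' @param heart_sdlog s.d. (log scale) of the between-heart multipliers.
#' @param bcl_ms BCL recorded in the output rows.
#' @param seed integer seed.
#' @param effects passed to [condition_script()].
#' @return data.frame with columns `heart_id`, `condition`, `bcl_ms`, and
#'   the ten parameters.
#' @export
simulate_panel_parameters <- function(base, scenario, n_hearts = 5,
                                      noise_frac = 0.03, heart_sdlog = 0.05,
                                      bcl_ms = 150, seed = 1L,
                                      effects = list()) {
  cfgs <- condition_script(base, scenario, effects)
  base_names <- setdiff(.param_names, "ar")
  with_seed(seed, {
    rows <- list()
    for (h in seq_len(n_hearts)) {
      mult <- stats::rlnorm(length(base_names), 0, heart_sdlog)
      names(mult) <- base_names
      for (nm in names(cfgs)) {
        tr <- ground_truth(cfgs[[nm]])$params
        noisy <- tr[base_names] * mult *
          (1 + stats::rnorm(length(base_names), 0, noise_frac))
        vals <- c(noisy, ar = unname(noisy["cv_l"] / noisy["cv_t"]))
        rows[[length(rows) + 1L]] <- data.frame(
          heart_id = paste0("heart_", h), condition = nm, bcl_ms = bcl_ms,
          as.list(vals[.param_names]))
      }
    }
    do.call(rbind, rows)
  })
}
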