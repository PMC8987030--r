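test_that("activation time sits at the steepest rise, earliest tie first", {
  # single steepest step between samples 3 and 4 -> midpoint 2.5 ms
  expect_equal(activation_time(beat_window(c(0, 0, 0, 1, 1, 1), 1)), 2.5)
  # constant-derivative ramp: earliest tie -> midpoint of the first interval
  ramp <- beat_window(seq(0, 1, by = 0.1), 1)
  expect_equal(activation_time(ramp), 0.5)
  # time-base shift moves the reported activation accordingly
  expect_equal(activation_time(beat_window(c(0, 0, 0, 1, 1, 1), 1, t0_ms = 100)),
               102.5)
})

test_that("activation of a logistic upstroke matches the analytic inflection", {
  t <- seq(0, 60, by = 1)
  v <- 1 / (1 + exp(-(t - 25) / 2))   # inflection (max derivative) at 25 ms
  est <- activation_time(beat_window(v, 1))
  # oracle: dense-grid argmax of the analytic derivative
  tt <- seq(0, 60, by = 1e-3)
  oracle <- tt[which.max(exp(-(tt - 25) / 2) / (1 + exp(-(tt - 25) / 2))^2)]
  expect_equal(oracle, 25, tolerance = 1e-6)
  expect_lt(abs(est - oracle), 0.5)
})

test_that("rise time of a linear ramp is amplitude-invariant and exact", {
  ramp <- beat_window(seq(0, 1, by = 0.1), 1)     # 0 -> 1 over 10 ms
  expect_equal(rise_time(ramp), 7)                # (0.9 - 0.2) x 10 ms
  scaled <- beat_window(5 * seq(0, 1, by = 0.1) + 2, 1)
  expect_equal(rise_time(scaled), 7)              # positive affine invariance
  # a trace peaking at its first sample has no upstroke to cross
  expect_error(rise_time(beat_window(c(1, 0.8, 0.5, 0.2, 0), 1)),
               class = "trimap_morphology_error")
})

test_that("rise time recovers the configured template span", {
  cfg <- sim_config(vm_rt_true = 3)
  tm <- waveform_templates(cfg)
  u <- seq(-30, 169, by = 1)
  rt <- rise_time(beat_window(tm$ap(u), 1))
  expect_equal(rt, 3, tolerance = 0.1 / 3)
})

test_that("duration80 follows square-pulse geometry and template truth", {
  # up-step between 9 and 10 ms, down-step between 59 and 60 ms
  v <- c(rep(0, 10), rep(1, 50), rep(0, 40))
  apd <- duration80(beat_window(v, 1))
  expect_lt(abs(apd - 50), 0.5)
  cfg <- sim_config(apd80_true = 40)
  tm <- waveform_templates(cfg)
  u <- seq(-30, 169, by = 1)
  expect_lt(abs(duration80(beat_window(tm$ap(u), 1)) - 40), 1)
})

test_that("incomplete repolarization is an error, not a number", {
  # oscillating repolarization that never descends below the 20% level
  osc <- c(rep(0, 10), seq(0, 1, length.out = 6),
           0.6 + 0.2 * sin(2 * pi * 8 * (1:120) / 1000))
  expect_error(duration80(beat_window(osc, 1)),
               class = "trimap_incomplete_repolarization_error")
})

test_that("decay tau recovers exact exponentials to 4 digits", {
  t <- seq(0, 199, by = 1)
  for (tau in c(30, 50)) {
    v <- c(rep(0, 5), 1, exp(-(seq_len(194)) / tau))
    expect_equal(decay_tau(beat_window(v, 1), offset = FALSE), tau,
                 tolerance = 1e-4)
    # offset model tolerates a diastolic pedestal
    v2 <- c(rep(0.05, 5), 1, 0.95 * exp(-(seq_len(194)) / tau) + 0.05)
    expect_equal(decay_tau(beat_window(v2, 1), offset = TRUE), tau,
                 tolerance = 1e-3)
  }
})

test_that("decay tau under 1% noise recovers truth over 100 seeds", {
  t <- seq_len(150)
  errs <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      v <- c(rep(0, 5), 1, exp(-(seq_len(144)) / 30) + 0.05) +
        rnorm(150, 0, 0.01)
      decay_tau(beat_window(v, 1)) - 30
    })
  }, numeric(1))
  expect_lt(abs(median(errs)), 1.5)
})

test_that("non-decaying segments are a fit error", {
  expect_error(decay_tau(beat_window(seq(0, 1, length.out = 40), 1)),
               class = "trimap_fit_error")
})

test_that("motion artifact flagging separates real from negligible wobble", {
  cfg <- sim_config()
  tm <- waveform_templates(cfg)
  u <- seq(-30, 169, by = 1)
  clean <- tm$ap(u)
  expect_equal(flag_motion_artifact(beat_window(clean, 1)), "ok")
  wob <- function(a) clean + ifelse(u > 15, a * sin(2 * pi * 8 * u / 1000), 0)
  expect_equal(flag_motion_artifact(beat_window(wob(0.4), 1)),
               "motion_artifact")
  expect_equal(flag_motion_artifact(beat_window(wob(0.02), 1)), "ok")
})

test_that("features are shift-equivariant and respect ordering", {
  cfg <- sim_config()
  tm <- waveform_templates(cfg)
  u <- seq(-30, 169, by = 1)
  v <- tm$ap(u)
  b0 <- beat_window(v, 1, t0_ms = 0)
  b1 <- beat_window(v, 1, t0_ms = 17)   # same samples, shifted time base
  expect_equal(activation_time(b1) - activation_time(b0), 17)
  expect_equal(rise_time(b1), rise_time(b0))
  expect_equal(duration80(b1), duration80(b0))
  # ordering: activation precedes the peak; rise time below duration80
  t_act <- activation_time(b0)
  t_peak <- b0$t0_ms + (which.max(v) - 1) * b0$dt_ms
  expect_lt(t_act, t_peak)
  expect_lte(rise_time(b0), duration80(b0))
})

test_that("features recover a grid of generator truths at SNR 20", {
  # vm-style templates: rise time x APD80; ca-style: decay tau
  err_rt <- c(); err_apd <- c(); err_tau <- c()
  seed <- 0
  for (rt in c(2, 4, 8)) for (apd in c(30, 50, 70)) {
    seed <- seed + 1
    cfg <- sim_config(vm_rt_true = rt, apd80_true = apd)
    tm <- waveform_templates(cfg)
    bw <- averaged_template_beat(tm$ap, nbeats = 60, noise = 0.05,
                                 seed = seed)
    err_rt <- c(err_rt, abs(rise_time(bw) - rt) / rt)
    err_apd <- c(err_apd, abs(duration80(bw) - apd) / apd)
  }
  for (tau in c(20, 50, 80)) {
    seed <- seed + 1
    cfg <- sim_config(tau_true = tau, ca_rt_true = 6,
                      catd80_true = 6 + 2 + tau * log(2.5) + 15,
                      bcl_ms = 300)
    tm <- waveform_templates(cfg)
    bw <- averaged_template_beat(tm$cat, bcl_ms = 300, nbeats = 60,
                                 noise = 0.05, seed = seed)
    err_tau <- c(err_tau, abs(decay_tau(bw) - tau) / tau)
  }
  expect_lte(median(err_rt), 0.05)
  expect_lte(median(err_apd), 0.05)
  expect_lte(median(err_tau), 0.05)
})

test_that("trace_features degrades gracefully instead of raising", {
  cfg <- sim_config()
  tm <- waveform_templates(cfg)
  u <- seq(-30, 169, by = 1)
  win <- pmin(pmax((u - 15) / 10, 0), 1) * pmin(pmax((160 - u) / 10, 0), 1)
  art <- tm$ap(u) + win * 0.25 * sin(2 * pi * 8 * u / 1000)
  f <- trace_features(beat_window(art, 1), "vm")
  expect_equal(f$quality, "motion_artifact")
  expect_true(is.finite(f$t_act_ms) && is.finite(f$rt_ms))
  expect_true(is.na(f$dur80_ms))
  fca <- trace_features(beat_window(tm$cat(u), 1), "ca")
  expect_equal(fca$quality, "ok")
  expect_true(is.finite(fca$tau_ms))
})
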