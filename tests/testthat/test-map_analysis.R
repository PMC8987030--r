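test_that("activation map matches the analytic wave field", {
  fx <- cached_recording(height = 32, width = 32, duration_ms = 1200,
                         noise_sigma = 0, seed = 1, key = "clean32")
  rec <- fx$rec
  mask <- compute_mask(rec$vm, 0.3)
  map <- build_map(rec$vm, mask, "activation", bcl_ms = 200)
  truth <- rec$truth$act_field
  sel <- mask$mask & is.finite(map$values)
  # maps share a per-recording origin; compare after removing the offset
  resid <- (map$values[sel] - truth[sel])
  resid <- resid - mean(resid)
  expect_lt(sqrt(mean(resid^2)), 0.5)
})

test_that("a simultaneous flash yields a constant activation map", {
  n <- 600; h <- 16; w <- 16
  cfg <- sim_config()
  tm <- waveform_templates(cfg)
  u <- ((seq_len(n) - 1 - 100 + 5) %% 200) - 5
  trace <- tm$ap(u)
  data <- array(rep(2000 - 600 * trace, h * w), c(n, h, w))
  stack <- movie_stack(data, 1, 0.1, "vm")
  mask <- compute_mask(stack, 0.3)
  map <- build_map(stack, mask, "activation", bcl_ms = 200)
  vals <- map$values[mask$mask]
  expect_lt(diff(range(vals, na.rm = TRUE)), 0.5)  # within dt/2
})

test_that("motion artifact degrades the dur80 map into a quality error", {
  fx <- cached_recording(height = 24, width = 24, duration_ms = 1000,
                         noise_sigma = 0, seed = 5,
                         motion_artifact = list(on = TRUE, amplitude = 0.3,
                                                freq_hz = 8),
                         key = "artifact24")
  rec <- fx$rec
  mask <- compute_mask(rec$vm, 0.3)
  expect_error(build_map(rec$vm, mask, "dur80", bcl_ms = 200),
               class = "trimap_map_quality_error")
})

test_that("conduction velocity reads slope geometry exactly", {
  # radial wave: activation rises 0.2 ms per pixel of distance
  r <- matrix(1:40, 40, 40); c_ <- t(r)
  act <- 0.2 * sqrt((r - 20)^2 + (c_ - 20)^2)
  cv <- conduction_velocity(act, c(20, 20), 0, 0.1, profile_len_px = 15,
                            band_px = 0)
  expect_equal(cv$cv_l, 0.5, tolerance = 1e-9)   # 0.1 mm / 0.2 ms
  expect_equal(cv$cv_t, 0.5, tolerance = 1e-9)
  expect_gt(cv$fit_r2_l, 0.999)
})

test_that("elliptical and isotropic wave fields give the true AR", {
  cfg <- sim_config(height = 64, width = 64)         # cv 0.5 / 0.25
  cvr <- conduction_velocity(activation_field(cfg), cfg$stim_rc, 0,
                             cfg$pixel_mm)
  expect_equal(cvr$cv_l, 0.5, tolerance = 0.02)
  expect_equal(cvr$cv_t, 0.25, tolerance = 0.02 * 0.25 / 0.5)
  expect_equal(cvr$ar, 2, tolerance = 0.05)
  iso <- sim_config(height = 64, width = 64, cv_l_true = 0.4,
                    cv_t_true = 0.4)
  cvi <- conduction_velocity(activation_field(iso), iso$stim_rc, 0,
                             iso$pixel_mm)
  expect_equal(cvi$ar, 1, tolerance = 0.02)
})

test_that("CV estimates rotate with the fiber axis", {
  base <- conduction_velocity(
    activation_field(sim_config(height = 64, width = 64)),
    c(32, 32), 0, 0.1)
  for (th in c(30, 90, 135)) {
    cfg <- sim_config(height = 64, width = 64, fiber_axis_deg = th)
    rot <- conduction_velocity(activation_field(cfg), cfg$stim_rc, th,
                               cfg$pixel_mm)
    expect_lt(abs(rot$cv_l - base$cv_l) / base$cv_l, 0.03)
    expect_lt(abs(rot$cv_t - base$cv_t) / base$cv_t, 0.03)
  }
})

test_that("unreliable activation profiles raise rather than report", {
  act <- matrix(runif(1600, 0, 10), 40, 40)   # spatially random activation
  withr::with_seed(3, {
    expect_error(conduction_velocity(act, c(20, 20), 0, 0.1),
                 class = "trimap_unreliable_cv_error")
  })
})

test_that("the Vm-Ca delay map follows its sign convention", {
  act_vm <- matrix(seq(0, 5, length.out = 400), 20, 20)
  mask <- structure(list(mask = matrix(TRUE, 20, 20), threshold_frac = 0.3),
                    class = "tissue_mask")
  d <- vm_ca_delay(act_vm, act_vm + 3, mask)
  expect_equal(d$delay_ms, 3)
  expect_equal(vm_ca_delay(act_vm, act_vm, mask)$delay_ms, 0)
  # invariant to a common time origin shift
  expect_equal(vm_ca_delay(act_vm + 11, act_vm + 14, mask)$delay_ms, 3)
  expect_error(vm_ca_delay(act_vm, act_vm[1:10, ], mask),
               class = "trimap_usage_error")
})

test_that("delay recovery from a noisy simulation is within SE scaling", {
  fx <- cached_recording(height = 32, width = 32, duration_ms = 1200,
                         noise_sigma = 0.05, seed = 9, delay_true = 5,
                         key = "delay32")
  rec <- fx$rec
  p <- analyze_recording(rec$vm, rec$ca, stim_rc = fx$cfg$stim_rc,
                         bcl_ms = 200)
  expect_equal(p$vm_ca_delay, 5, tolerance = 0.2 / 5)
})

test_that("NADH intensity is the masked mean and normalizes to the first", {
  h <- 16; w <- 16
  mask_m <- matrix(TRUE, h, w)
  mask <- structure(list(mask = mask_m, threshold_frac = 0.3),
                    class = "tissue_mask")
  const <- movie_stack(array(1200, c(3, h, w)), 1, 0.1, "nadh")
  expect_equal(nadh_intensity(const, mask), 1200)
  img <- matrix(1000, h, w); img[, 9:16] <- 2000
  two <- movie_stack(array(rep(img, each = 3), c(3, h, w)), 1, 0.1, "nadh")
  expect_equal(nadh_intensity(two, mask), 1500)
  expect_equal(normalize_nadh(c(1200, 1320, 1080)), c(1.00, 1.10, 0.90))
  expect_equal(normalize_nadh(1200), 1)
  expect_error(normalize_nadh(c(0, 1)), class = "trimap_degenerate_error")
  empty <- structure(list(mask = matrix(FALSE, h, w), threshold_frac = 0.3),
                     class = "tissue_mask")
  expect_error(nadh_intensity(const, empty), class = "trimap_empty_mask_error")
})

test_that("AR is invariant to a common speed scale", {
  for (s in c(0.5, 1, 2.2)) {
    cfg <- sim_config(height = 48, width = 48, cv_l_true = 0.3 * s,
                      cv_t_true = 0.15 * s)
    cvr <- conduction_velocity(activation_field(cfg), cfg$stim_rc, 0,
                               cfg$pixel_mm)
    expect_equal(cvr$ar, 2, tolerance = 0.05)
  }
})

test_that("an NADH-only recording populates only the NADH fields", {
  h <- 16; w <- 16
  nadh <- movie_stack(array(1100, c(4, h, w)), 1, 0.1, "nadh")
  p <- analyze_recording(nadh = nadh)
  expect_equal(p$nadh_raw, 1100)
  expect_true(all(is.na(unlist(p[c("vm_rt", "apd80", "cv_l", "ca_rt",
                                   "catd80", "ca_tau", "vm_ca_delay")]))))
  expect_true(p$available[["nadh"]])
})
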