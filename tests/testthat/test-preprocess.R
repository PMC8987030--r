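test_that("intensity threshold mask recovers a two-level image exactly", {
  h <- 20; w <- 20
  inside <- matrix(FALSE, h, w); inside[5:15, 6:16] <- TRUE
  img <- ifelse(inside, 1000, 10)
  data <- array(0, c(3, h, w)); for (k in 1:3) data[k, , ] <- img
  stack <- movie_stack(data, 1, 0.1, "vm")
  expect_identical(compute_mask(stack, 0.5)$mask, inside)
  # near-zero threshold keeps every positive pixel
  expect_true(all(compute_mask(stack, 1e-6)$mask))
})

test_that("mask is monotone in the threshold and can run empty", {
  stack <- make_pattern_stack()
  fracs <- c(0.2, 0.4, 0.6, 0.8)
  masks <- lapply(fracs, function(f) compute_mask(stack, f)$mask)
  for (i in seq_len(length(masks) - 1))
    expect_true(all(masks[[i + 1]] <= masks[[i]]))  # raising never adds pixels
  # a single dominant pixel leaves < 1% of the raster above threshold
  h <- 20; w <- 20
  img <- matrix(1, h, w); img[10, 10] <- 1e6
  data <- array(0, c(2, h, w)); for (k in 1:2) data[k, , ] <- img
  expect_error(compute_mask(movie_stack(data, 1, 0.1, "vm"), 0.5),
               class = "trimap_empty_mask_error")
})

test_that("mask recovers the simulated silhouette under 2% noise", {
  fx <- cached_recording(height = 32, width = 32, duration_ms = 800,
                         noise_sigma = 0.02, seed = 7)
  mask <- compute_mask(fx$rec$vm, 0.3)
  agreement <- mean(mask$mask == fx$rec$truth$silhouette)
  expect_gte(agreement, 0.99)
})

test_that("conditioning flips, detrends, and normalizes per beat", {
  cfg <- sim_config()
  tm <- waveform_templates(cfg)
  u <- seq(-30, 569, by = 1)
  template <- tm$ap(((u + 10) %% 200) - 10)
  # a downward AP train (dye polarity) spans [0, 1] upward after conditioning
  raw_down <- 2000 - 600 * template
  ct <- condition_trace(raw_down, 1, flip_polarity = TRUE, detrend_order = 0,
                        temporal_kernel_ms = 0)
  expect_equal(range(ct$values), c(0, 1))
  expect_gt(stats::cor(ct$values, template), 0.9999)
  # injected linear drift (+0.5 amplitude per second) is removed
  drift <- 0.5 * seq_along(u) / 1000
  ct2 <- condition_trace(template + drift, 1, detrend_order = 1,
                         temporal_kernel_ms = 0)
  ref <- (template - min(template)) / diff(range(template))
  expect_lt(sqrt(mean((ct2$values - ref)^2)), 0.01)
  # constant traces cannot be normalized
  expect_error(condition_trace(rep(3, 100), 1),
               class = "trimap_degenerate_error")
})

test_that("conditioning is idempotent on conditioned traces", {
  cfg <- sim_config()
  tm <- waveform_templates(cfg)
  u <- seq(-30, 569, by = 1)
  v <- tm$ap(((u + 10) %% 200) - 10)
  once <- condition_trace(v, 1, detrend_order = 0, temporal_kernel_ms = 0)
  twice <- condition_trace(once$values, 1, detrend_order = 0,
                           temporal_kernel_ms = 0)
  expect_lt(max(abs(twice$values - once$values)), 1e-9)
})

test_that("kernel shorter than a beat window is required", {
  ct <- condition_trace(sin(seq(0, 20, by = 0.1)) + 2, 1, detrend_order = 0,
                        temporal_kernel_ms = 0)
  short <- list(beat_window(rep(c(0, 1), 3), 1))
  short[[1]]$i0 <- 1L; short[[1]]$i1 <- 6L
  expect_error(condition_trace(seq_len(200), 1, temporal_kernel_ms = 50,
                               beat_windows = short),
               class = "trimap_usage_error")
})

test_that("spatial filter is identity at sigma 0 and on uniform images", {
  stack <- make_pattern_stack(frames = 3)
  expect_identical(spatial_filter(stack, 0)$data, stack$data)
  uni <- movie_stack(array(42, c(2, 16, 16)), 1, 0.1, "vm")
  expect_equal(spatial_filter(uni, 1.5)$data, uni$data, tolerance = 1e-12)
})

test_that("spatial filter matches a direct convolution oracle on a delta", {
  h <- 21; w <- 21
  img <- matrix(0, h, w); img[11, 11] <- 1
  data <- array(0, c(2, h, w)); for (k in 1:2) data[k, , ] <- img
  stack <- movie_stack(data, 1, 0.1, "vm")
  out <- spatial_filter(stack, 1)$data[1, , ]
  # oracle: explicit 2-D truncated-Gaussian convolution
  r <- ceiling(3 * 1)
  k1 <- dnorm(-r:r); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  oracle <- matrix(0, h, w)
  for (dr in -r:r) for (dc in -r:r)
    oracle[11 + dr, 11 + dc] <- K[dr + r + 1, dc + r + 1]
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)  # unit mass preserved
})

test_that("mask-normalized smoothing does not bleed background in", {
  h <- 16; w <- 16
  inside <- matrix(FALSE, h, w); inside[4:12, 4:12] <- TRUE
  img <- ifelse(inside, 1000, 0)
  data <- array(0, c(2, h, w)); for (k in 1:2) data[k, , ] <- img
  stack <- movie_stack(data, 1, 0.1, "vm")
  mask <- structure(list(mask = inside, threshold_frac = 0.5),
                    class = "tissue_mask")
  sm <- spatial_filter(stack, 1.5, mask)$data[1, , ]
  expect_equal(sm[inside], rep(1000, sum(inside)), tolerance = 1e-9)
  expect_identical(sm[!inside], img[!inside])  # untouched outside
})

test_that("beat segmentation finds the paced rhythm", {
  fx <- cached_recording(height = 32, width = 32, duration_ms = 2000,
                         noise_sigma = 0, seed = 1, key = "seg2000")
  mask <- compute_mask(fx$rec$vm, 0.3)
  win <- trimap:::.global_windows(fx$rec$vm, mask, bcl_ms = 200)
  expect_true(length(win) %in% 9:10)
  anchors <- vapply(win, `[[`, numeric(1), "anchor_ms")
  expect_true(all(abs(diff(anchors) - 200) <= 1))
  expect_lte(length(win) * 200, 2000)  # beat count x BCL within duration
})

test_that("segmentation honors a different BCL and rejects flat traces", {
  cfg <- sim_config(height = 16, width = 16, duration_ms = 1400, bcl_ms = 150,
                    apd80_true = 35, catd80_true = 48, tau_true = 20)
  rec <- render_recording(cfg)
  mask <- compute_mask(rec$vm, 0.3)
  win <- trimap:::.global_windows(rec$vm, mask, bcl_ms = 150)
  anchors <- vapply(win, `[[`, numeric(1), "anchor_ms")
  expect_true(all(abs(diff(anchors) - 150) <= 1))
  flat <- structure(list(values = rep(0.5, 400), dt_ms = 1,
                         polarity_flipped = FALSE, baseline_model = "none"),
                    class = "conditioned_trace")
  expect_error(segment_beats(flat, 200), class = "trimap_no_beats_error")
})
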