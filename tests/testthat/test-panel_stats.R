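test_that("noise-free model data are recovered exactly", {
  x <- seq(100, 250, by = 25)
  # exponential plateau: Y_M = 60, Y_0 = 30, k = 0.02
  y <- 60 - (60 - 30) * exp(-0.02 * x)
  fit <- fit_restitution(x, y, "exp_plateau")
  expect_equal(unname(fit$params["Y_M"]), 60, tolerance = 1e-4)
  expect_equal(unname(fit$params["Y_0"]), 30, tolerance = 1e-4)
  expect_equal(unname(fit$params["k"]), 0.02, tolerance = 1e-4)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  # exact line
  fl <- fit_restitution(x, 5 + 0.1 * x, "linear")
  expect_equal(unname(fl$params), c(5, 0.1), tolerance = 1e-10)
  expect_lt(fl$ss_resid, 1e-18)
  # cubic polynomial
  fp <- fit_restitution(x, 1 + 0.1 * x - 1e-4 * x^2 + 1e-7 * x^3, "poly3")
  expect_equal(unname(fp$params), c(1, 0.1, -1e-4, 1e-7), tolerance = 1e-6)
})

test_that("noisy exponential plateau rate is recovered in the median", {
  x <- rep(seq(100, 250, by = 25), 2)
  y0 <- 60 - (60 - 30) * exp(-0.02 * x)
  khat <- vapply(1:200, function(s) {
    withr::with_seed(s, {
      y <- y0 + rnorm(length(x), 0, 0.02 * diff(range(y0)))
      unname(fit_restitution(x, y, "exp_plateau")$params["k"])
    })
  }, numeric(1))
  expect_lt(abs(median(khat) - 0.02) / 0.02, 0.10)
})

test_that("extra sum-of-squares F test matches the hand-computed formula", {
  # fixed 12-point dataset split into two conditions, linear model
  x <- c(100, 120, 140, 160, 180, 200)
  y1 <- c(21.2, 23.9, 25.1, 27.8, 28.9, 31.4)
  y2 <- c(22.8, 24.1, 26.9, 28.3, 30.7, 32.1)
  f1 <- fit_restitution(x, y1, "linear")
  f2 <- fit_restitution(x, y2, "linear")
  fp <- fit_restitution(c(x, x), c(y1, y2), "linear")
  got <- extra_ss_f_test(fp, list(f1, f2))
  # oracle: explicit SS decomposition from closed-form simple regression
  ss_line <- function(x, y) {
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - b * mean(x)
    sum((y - a - b * x)^2)
  }
  ss_sep <- ss_line(x, y1) + ss_line(x, y2)
  ss_pool <- ss_line(c(x, x), c(y1, y2))
  Fref <- ((ss_pool - ss_sep) / (10 - 8)) / (ss_sep / 8)
  expect_equal(got$F, Fref, tolerance = 1e-10)
  expect_equal(got$p, pf(Fref, 2, 8, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("identical conditions give F near 0 and p near 1", {
  x <- seq(100, 250, by = 30)
  y <- 50 - 20 * exp(-0.02 * x)
  f1 <- fit_restitution(x, y, "linear")
  fp <- fit_restitution(c(x, x), c(y, y), "linear")
  got <- extra_ss_f_test(fp, list(f1, f1))
  expect_lt(got$F, 1e-6)
  expect_gt(got$p, 0.999)
})

test_that("a strong condition shift is detected in nearly every replicate", {
  x <- rep(seq(100, 250, by = 30), 2)
  hits <- vapply(1:200, function(s) {
    withr::with_seed(s, {
      noise <- 0.3
      y1 <- 5 + 0.1 * x + rnorm(length(x), 0, noise)
      y2 <- 5 + 0.1 * x + 10 * noise + rnorm(length(x), 0, noise)
      f1 <- fit_restitution(x, y1, "linear")
      f2 <- fit_restitution(x, y2, "linear")
      fp <- fit_restitution(c(x, x), c(y1, y2), "linear")
      extra_ss_f_test(fp, list(f1, f2))$p < 0.001
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("paired t matches the direct formula and handles degeneracy", {
  a <- c(10, 12, 9, 11, 10); b <- c(12, 14, 10, 13, 12)
  got <- paired_t_test(a, b)
  d <- a - b
  tref <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(got$t, tref, tolerance = 1e-10)
  expect_equal(got$p, 2 * pt(abs(tref), 4, lower.tail = FALSE),
               tolerance = 1e-10)
  same <- paired_t_test(a, a)
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  const <- paired_t_test(a + 1, a)
  expect_true(const$degenerate)
})

test_that("BH step-up matches exhaustive enumeration on the fixed example", {
  p <- c(0.001, 0.01, 0.03, 0.04, 0.2, 0.5)
  got <- bh_adjust(p, q = 0.2)
  # oracle: enumerate thresholds i*q/m and take the largest passing rank
  m <- length(p); o <- order(p)
  pass <- which(p[o] <= (seq_len(m) / m) * 0.2)
  ref <- rep(FALSE, m)
  ref[o[seq_len(max(pass))]] <- TRUE
  expect_identical(got$reject, ref)
  expect_identical(got$reject, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(got$p_adjusted, p.adjust(p, "BH"))
  # rejection iff adjusted p <= q
  expect_identical(got$reject, got$p_adjusted <= 0.2)
})

test_that("BH edge cases and q-monotonicity behave", {
  expect_identical(bh_adjust(rep(1, 5), 0.2)$reject, rep(FALSE, 5))
  expect_true(bh_adjust(0.04, 0.2)$reject)       # single p <= q
  expect_length(bh_adjust(numeric(0))$reject, 0)
  withr::with_seed(42, {
    for (i in 1:20) {
      p <- runif(8)^2
      r1 <- bh_adjust(p, 0.1)$reject
      r2 <- bh_adjust(p, 0.3)$reject
      expect_true(all(r2 >= r1))                 # larger q never removes one
    }
  })
})

test_that("TPP percent changes, SEM, and flags are correct", {
  mk <- function(cond, vals)
    data.frame(heart_id = paste0("h", seq_along(vals)), condition = cond,
               bcl_ms = 150, ca_rt = vals)
  df <- rbind(mk("ref", c(100, 100, 100, 100)), mk("trt", c(120, 120, 120, 120)))
  tpp <- build_tpp(df, "trt", "ref", parameters = "ca_rt")
  expect_equal(tpp$mean_pct, 20)
  expect_equal(tpp$sem_pct, 0)
  # identical conditions: zero change, no significance
  df2 <- rbind(mk("ref", c(90, 100, 110, 105)), mk("trt", c(90, 100, 110, 105)))
  tpp2 <- build_tpp(df2, "trt", "ref", parameters = "ca_rt")
  expect_equal(tpp2$mean_pct, 0)
  expect_false(any(tpp2$significant))
  expect_error(build_tpp(df, "trt", "absent"), class = "trimap_usage_error")
})

test_that("TPP is scale-free in the raw parameter units", {
  base <- simulate_panel_parameters(sim_config(height = 16, width = 16),
                                    "ical_block", n_hearts = 5, seed = 3)
  scaled <- base
  scaled$ca_rt <- scaled$ca_rt * 7.3
  t1 <- build_tpp(base, "ical_block", "blebbistatin")
  t2 <- build_tpp(scaled, "ical_block", "blebbistatin")
  expect_equal(t1$mean_pct, t2$mean_pct, tolerance = 1e-12)
  expect_equal(t1$p_raw, t2$p_raw, tolerance = 1e-12)
})

test_that("an isolated calcium effect is flagged and detected", {
  base <- sim_config(height = 16, width = 16)
  hits_ca <- 0; reps <- 40
  for (r in seq_len(reps)) {
    df <- simulate_panel_parameters(base, "ical_block", n_hearts = 5,
                                    seed = 300 + r)
    tpp <- build_tpp(df, "ical_block", "blebbistatin")
    sig <- tpp$parameter[tpp$significant]
    if ("ca_rt" %in% sig) hits_ca <- hits_ca + 1
  }
  expect_gte(hits_ca / reps, 0.95)   # the true effect is essentially always found
})

test_that("the global-null family-wise BH rejection rate is near nominal", {
  # 400 null panels of 10 paired t-tests, n = 5 hearts
  withr::with_seed(77, {
    any_rej <- vapply(1:400, function(r) {
      p <- vapply(1:10, function(j)
        paired_t_test(rnorm(5), rnorm(5))$p, numeric(1))
      any(bh_adjust(p, 0.2)$reject)
    }, logical(1))
  })
  # under independence the family-wise rate at q = 0.2 is near 0.2
  expect_lt(abs(mean(any_rej) - 0.2), 0.07)
})

test_that("normality check calibrates and detects", {
  withr::with_seed(5, {
    rej <- vapply(1:500, function(s) normality_check(rnorm(20))$p < 0.05,
                  logical(1))
    expect_lt(abs(mean(rej) - 0.05), 0.02)
    power <- vapply(1:100, function(s) {
      x <- c(rnorm(10, -5, 0.5), rnorm(10, 5, 0.5))
      normality_check(x)$p < 0.05
    }, logical(1))
    expect_gte(mean(power), 0.9)
  })
  expect_error(normality_check(rep(1, 10)), class = "trimap_degenerate_error")
  expect_error(normality_check(c(1, 2)), class = "trimap_usage_error")
})
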