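# Restitution-curve fitting and ten-parameter-panel statistics ----------------

#' Default restitution model per parameter
#'
#' Parameters exhibiting restitution (both conduction velocities, the
#' anisotropic ratio, APD80, CaTD80, and the calcium decay constant) use
#' the exponential plateau model; the Vm-Ca delay uses a third-order
#' polynomial; everything else a simple linear model.
#' @return named character vector mapping parameter to model.
#' @export
default_restitution_models <- function() {
  c(cv_t = "exp_plateau", cv_l = "exp_plateau", ar = "exp_plateau",
    apd80 = "exp_plateau", catd80 = "exp_plateau", ca_tau = "exp_plateau",
    vm_ca_delay = "poly3",
    vm_rt = "linear", ca_rt = "linear", nadh = "linear")
}

.rest_fit <- function(model, params, ss_resid, df, r2, n) {
  structure(list(model = model, params = params, ss_resid = ss_resid,
                 df = df, r2 = r2, n = n),
            class = "restitution_fit")
}

#' @export
print.restitution_fit <- function(x, ...) {
  cat(sprintf("<restitution_fit> %s  n=%d df=%d  r2=%.4f  SS=%.4g\n",
              x$model, x$n, x$df, x$r2, x$ss_resid))
  print(signif(x$params, 5))
  invisible(x)
}

#' Fit a restitution model
#'
#' Least-squares fit of one of three models of parameter-versus-BCL
#' dependence:
#' \itemize{
#'   \item `exp_plateau`: `Y = Y_M - (Y_M - Y_0) * exp(-k * X)`, fitted by
#'     nonlinear least squares with multi-start initialization
#'     (`Y_M = max(Y)`, `Y_0 = min(Y)`, `k in {0.005, 0.02, 0.05}` per ms)
#'     and the box constraint `k > 0`;
#'   \item `poly3`: `Y = B0 + B1 X + B2 X^2 + B3 X^3`;
#'   \item `linear`: `Y = a + b X`.
#' }
#' A fit with `r2 <= 0.5` is still returned (the acceptance threshold is
#' applied by callers that report fit quality), but non-convergence from
#' every start raises a fit error.
#'
#' @param x predictor (BCL, ms).
#' @param y response (parameter values).
#' @param model `"exp_plateau"`, `"poly3"`, or `"linear"`.
#' @return a `restitution_fit` with `params`, `ss_resid`, `df = n - p`,
#'   `r2`.
#' @export
fit_restitution <- function(x, y, model = c("exp_plateau", "poly3", "linear")) {
  model <- match.arg(model)
  assert_that(length(x) == length(y) && all(is.finite(x)) && all(is.finite(y)),
              "x and y must be finite and of equal length")
  n <- length(y)
  p <- switch(model, exp_plateau = 3L, poly3 = 4L, linear = 2L)
  assert_that(n >= p + 1L,
              sprintf("model '%s' needs at least %d points", model, p + 1L))
  ss_tot <- sum((y - mean(y))^2)
  if (model == "linear") {
    fit <- stats::lm(y ~ x)
    ss <- sum(stats::residuals(fit)^2)
    params <- stats::setNames(stats::coef(fit), c("a", "b"))
  } else if (model == "poly3") {
    fit <- stats::lm(y ~ x + I(x^2) + I(x^3))
    ss <- sum(stats::residuals(fit)^2)
    params <- stats::setNames(stats::coef(fit), c("B0", "B1", "B2", "B3"))
  } else {
    dat <- data.frame(x = x, y = y)
    best <- NULL
    for (k0 in c(0.005, 0.02, 0.05)) {
      start <- list(ym = max(y), y0 = min(y), k = k0)
      fit <- tryCatch(
        stats::nls(y ~ ym - (ym - y0) * exp(-k * x), data = dat,
                   start = start, algorithm = "port",
                   lower = c(ym = -Inf, y0 = -Inf, k = 1e-8),
                   control = stats::nls.control(maxiter = 200,
                                                warnOnly = FALSE)),
        error = function(e) NULL)
      if (is.null(fit))
        fit <- tryCatch(
          minpack.lm::nlsLM(y ~ ym - (ym - y0) * exp(-k * x), data = dat,
                            start = start, lower = c(-Inf, -Inf, 1e-8),
                            control = minpack.lm::nls.lm.control(maxiter = 200)),
          error = function(e) NULL)
      if (!is.null(fit)) {
        ssf <- sum(stats::residuals(fit)^2)
        if (is.null(best) || ssf < best$ss) best <- list(fit = fit, ss = ssf)
      }
    }
    if (is.null(best))
      abort_trimap("exponential plateau fit did not converge from any start",
                   "trimap_fit_error")
    ss <- best$ss
    params <- stats::setNames(stats::coef(best$fit), c("Y_M", "Y_0", "k"))
  }
  r2 <- if (ss_tot > 0) 1 - ss / ss_tot else NA_real_
  .rest_fit(model, params, ss, n - p, r2, n)
}

#' Extra sum-of-squares F test
#'
#' Compares a pooled fit (one curve for all conditions) against separate
#' per-condition fits of the same model:
#' `F = ((SS_pooled - SS_sep) / (df_pooled - df_sep)) / (SS_sep / df_sep)`,
#' with the p value from the F distribution on
#' `(df_pooled - df_sep, df_sep)` degrees of freedom. A negative numerator
#' (numerical artifact) is clipped to zero; a perfect separate fit with a
#' non-zero pooled SS is reported as `p = 0` with a flag.
#'
#' @param fit_pooled `restitution_fit` on the combined data.
#' @param fits_separate list of `restitution_fit`s, one per condition.
#' @return list with `F`, `p`, the df pair, and `degenerate` flag.
#' @export
extra_ss_f_test <- function(fit_pooled, fits_separate) {
  assert_that(inherits(fit_pooled, "restitution_fit"),
              "fit_pooled must be a restitution_fit")
  assert_that(length(fits_separate) >= 2L,
              "need at least two separate fits")
  ss_sep <- sum(vapply(fits_separate, `[[`, numeric(1), "ss_resid"))
  df_sep <- sum(vapply(fits_separate, `[[`, numeric(1), "df"))
  ss_pool <- fit_pooled$ss_resid
  df_pool <- fit_pooled$df
  assert_that(df_pool > df_sep, "pooled model must have more residual df")
  if (ss_sep <= 0 && ss_pool > 0)
    return(list(F = Inf, p = 0, df1 = df_pool - df_sep, df2 = df_sep,
                degenerate = TRUE))
  num <- max(ss_pool - ss_sep, 0) / (df_pool - df_sep)
  den <- ss_sep / df_sep
  Fst <- if (den > 0) num / den else 0
  list(F = Fst, p = stats::pf(Fst, df_pool - df_sep, df_sep, lower.tail = FALSE),
       df1 = df_pool - df_sep, df2 = df_sep, degenerate = FALSE)
}

#' Two-tailed paired t-test
#'
#' Thin wrapper around the standard paired t-test with explicit handling of
#' the degenerate zero-variance case: identical pairs give `t = 0, p = 1`;
#' constant non-zero differences are flagged degenerate with `p = 0`.
#'
#' @param a,b paired per-heart values (equal length >= 2).
#' @return list with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  assert_that(length(a) == length(b) && length(a) >= 2L,
              "a and b must be paired vectors of length >= 2")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1L,
                mean_diff = mean(d), degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = unname(ht$estimate),
       degenerate = FALSE)
}

#' Benjamini-Hochberg step-up correction
#'
#' Sorts the p values ascending, finds the largest i with
#' `p_(i) <= (i / m) * q`, and rejects hypotheses 1..i. Also returns the
#' monotone BH-adjusted p values (`stats::p.adjust` method `"BH"`); a
#' hypothesis is rejected exactly when its adjusted p is at most `q`.
#'
#' @param p_values vector of p values in \[0, 1\].
#' @param q target false discovery rate (0.20 in the reference protocol).
#' @return list with logical `reject`, numeric `p_adjusted`, and `q`.
#' @export
bh_adjust <- function(p_values, q = 0.20) {
  assert_that(q > 0 && q < 1, "q must be in (0, 1)")
  if (!length(p_values))
    return(list(reject = logical(0), p_adjusted = numeric(0), q = q))
  assert_that(all(is.finite(p_values)) && all(p_values >= 0 & p_values <= 1),
              "p values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  ok <- which(p_values[o] <= seq_len(m) / m * q)
  reject <- rep(FALSE, m)
  if (length(ok)) reject[o[seq_len(max(ok))]] <- TRUE
  list(reject = reject, p_adjusted = stats::p.adjust(p_values, "BH"), q = q)
}

# Ten-parameter panel -----------------------------------------------------------

#' Build a ten-parameter panel (TPP)
#'
#' For each heart, computes the percent change of every parameter in the
#' treatment condition relative to the reference condition at the target
#' BCL, then summarizes across hearts as mean +/- SEM, runs two-tailed
#' paired t-tests (treated vs reference raw values), and applies the
#' Benjamini-Hochberg correction at FDR `q` across the panel's parameters.
#'
#' @param params data.frame with columns `heart_id`, `condition`, `bcl_ms`
#'   and the parameter columns (as produced by [analyze_manifest()] or
#'   [simulate_panel_parameters()]).
#' @param treatment,reference condition labels to compare.
#' @param at_bcl_ms BCL at which panel values are taken (150 ms, the
#'   "normal" ex vivo rate of 400 bpm).
#' @param parameters parameter columns to include.
#' @param q false discovery rate for the BH correction.
#' @return a `tpp_table`: data.frame (one row per parameter) with
#'   `mean_pct`, `sem_pct`, `p_raw`, `p_bh`, `significant`, `n`; per-heart
#'   percent changes in `attr(, "per_heart")`.
#' @export
build_tpp <- function(params, treatment, reference, at_bcl_ms = 150,
                      parameters = intersect(.param_names, names(params)),
                      q = 0.20) {
  need <- c("heart_id", "condition", "bcl_ms")
  assert_that(all(need %in% names(params)),
              "params must have heart_id, condition, bcl_ms columns")
  assert_that(length(parameters) >= 1L, "no parameter columns found")
  df <- params[params$bcl_ms == at_bcl_ms, , drop = FALSE]
  if (!any(df$condition == reference))
    abort_trimap(sprintf("reference condition '%s' absent at BCL %g",
                         reference, at_bcl_ms), "trimap_usage_error")
  if (!any(df$condition == treatment))
    abort_trimap(sprintf("treatment condition '%s' absent at BCL %g",
                         treatment, at_bcl_ms), "trimap_usage_error")
  ref <- df[df$condition == reference, , drop = FALSE]
  trt <- df[df$condition == treatment, , drop = FALSE]
  hearts <- intersect(ref$heart_id, trt$heart_id)
  dropped <- setdiff(union(ref$heart_id, trt$heart_id), hearts)
  if (length(dropped))
    warning("dropping unpaired heart(s): ", paste(dropped, collapse = ", "))
  assert_that(length(hearts) >= 2L, "need >= 2 hearts with paired conditions")
  ref <- ref[match(hearts, ref$heart_id), , drop = FALSE]
  trt <- trt[match(hearts, trt$heart_id), , drop = FALSE]

  pct <- matrix(NA_real_, length(hearts), length(parameters),
                dimnames = list(hearts, parameters))
  rows <- lapply(parameters, function(pm) {
    a <- trt[[pm]]; b <- ref[[pm]]
    ok <- is.finite(a) & is.finite(b) & b != 0
    pc <- rep(NA_real_, length(hearts))
    pc[ok] <- 100 * (a[ok] - b[ok]) / b[ok]
    pct[, pm] <<- pc
    if (sum(ok) >= 2L) {
      tt <- paired_t_test(a[ok], b[ok])
      data.frame(parameter = pm, mean_pct = mean(pc[ok]),
                 sem_pct = stats::sd(pc[ok]) / sqrt(sum(ok)),
                 p_raw = tt$p, n = sum(ok),
                 flagged = if (all(b[ok] != 0)) NA_character_ else "zero reference")
    } else {
      data.frame(parameter = pm, mean_pct = NA_real_, sem_pct = NA_real_,
                 p_raw = NA_real_, n = sum(ok),
                 flagged = "insufficient pairs")
    }
  })
  tab <- do.call(rbind, rows)
  testable <- is.finite(tab$p_raw)
  tab$p_bh <- NA_real_
  tab$significant <- FALSE
  if (any(testable)) {
    bh <- bh_adjust(tab$p_raw[testable], q = q)
    tab$p_bh[testable] <- bh$p_adjusted
    tab$significant[testable] <- bh$reject
  }
  structure(tab, per_heart = pct, treatment = treatment,
            reference = reference, at_bcl_ms = at_bcl_ms, q = q,
            class = c("tpp_table", "data.frame"))
}

#' @export
print.tpp_table <- function(x, ...) {
  cat(sprintf("Ten-parameter panel: %s vs %s at BCL %g ms (BH q = %.2f)\n",
              attr(x, "treatment"), attr(x, "reference"),
              attr(x, "at_bcl_ms"), attr(x, "q")))
  df <- as.data.frame(x)
  df$mean_pct <- sprintf("%+.1f%%", df$mean_pct)
  df$sem_pct <- sprintf("%.1f", df$sem_pct)
  df$p_raw <- signif(df$p_raw, 3)
  df$p_bh <- signif(df$p_bh, 3)
  print(df[, c("parameter", "mean_pct", "sem_pct", "p_raw", "p_bh",
               "significant", "n")], row.names = FALSE)
  invisible(x)
}

#' Shapiro-Wilk normality check
#'
#' @param values numeric sample, 3 <= n <= 50.
#' @return list with `W` and `p`.
#' @export
normality_check <- function(values) {
  assert_that(length(values) >= 3L && length(values) <= 50L,
              "normality check requires 3 <= n <= 50")
  if (stats::sd(values) == 0)
    abort_trimap("constant sample: normality undefined",
                 "trimap_degenerate_error")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}
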