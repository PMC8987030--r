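# Shared fixtures built in code.

# Small structured image stack (gradient + blobs) for IO / registration tests.
make_pattern_stack <- function(h = 24, w = 24, frames = 6, channel = "vm",
                               integer_values = TRUE) {
  r <- matrix(seq_len(h), h, w)
  c_ <- matrix(seq_len(w), h, w, byrow = TRUE)
  img <- 400 + 20 * r + 10 * c_ +
    300 * exp(-((r - h / 3)^2 + (c_ - w / 3)^2) / 8) +
    200 * exp(-((r - 2 * h / 3)^2 + (c_ - 2 * w / 3)^2) / 18)
  data <- array(0, c(frames, h, w))
  for (k in seq_len(frames)) data[k, , ] <- img + 5 * (k - 1)
  if (integer_values) data <- round(data)
  movie_stack(data, dt_ms = 1, pixel_mm = 0.1, channel = channel,
              meta = list(heart_id = "h1"))
}

# Translate stack content: out[i, j] = stack[i - dr, j - dc] (edge-padded),
# i.e. the moving image is the reference displaced by (dr, dc).
shift_stack_content <- function(stack, dr, dc) {
  d <- dim(stack$data)
  out <- stack$data
  for (k in seq_len(d[1])) {
    m <- matrix(stack$data[k, , ], d[2], d[3])
    src_r <- pmin(pmax(seq_len(d[2]) - dr, 1), d[2])
    src_c <- pmin(pmax(seq_len(d[3]) - dc, 1), d[3])
    out[k, , ] <- m[src_r, src_c]
  }
  movie_stack(out, stack$dt_ms, stack$pixel_mm, stack$channel, stack$meta)
}

# Sample a template train at 1 kHz: `nbeats` beats at `bcl_ms`, activation
# anchored `lead_ms` into each cycle. Returns the per-beat windows directly.
template_beats <- function(tmpl_fun, bcl_ms = 200, nbeats = 6, lead_ms = 30,
                           dt = 1, noise = 0, seed = 1) {
  u <- seq(-lead_ms, bcl_ms - lead_ms - dt, by = dt)
  v <- tmpl_fun(u)
  withr::with_seed(seed, {
    lapply(seq_len(nbeats), function(k)
      beat_window(v + rnorm(length(v), 0, noise), dt_ms = dt, t0_ms = -lead_ms))
  })
}

# Ensemble-average of noisy template beats -> one beat window (the package's
# standard measurement procedure at low SNR).
averaged_template_beat <- function(tmpl_fun, bcl_ms = 200, nbeats = 8,
                                   lead_ms = 30, dt = 1, noise = 0, seed = 1) {
  beats <- template_beats(tmpl_fun, bcl_ms, nbeats, lead_ms, dt, noise, seed)
  vals <- rowMeans(vapply(beats, `[[`, numeric(length(beats[[1]]$values)),
                          "values"))
  beat_window(vals, dt_ms = dt, t0_ms = -lead_ms)
}

# One small rendered triple recording, cached per option set across tests.
.render_cache <- new.env(parent = emptyenv())
cached_recording <- function(..., key = NULL) {
  args <- list(...)
  key <- if (is.null(key)) paste(deparse(args), collapse = "") else key
  if (is.null(.render_cache[[key]])) {
    cfg <- do.call(sim_config, args)
    .render_cache[[key]] <- list(cfg = cfg, rec = render_recording(cfg))
  }
  .render_cache[[key]]
}
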