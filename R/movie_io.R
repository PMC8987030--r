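# Movie-stack container and file formats -------------------------------------

#' Create a movie stack
#'
#' A movie stack is the in-memory container for one optical-mapping channel:
#' a frames x height x width intensity array plus the acquisition metadata
#' needed downstream (frame interval, pixel size, channel identity). Frame
#' index 1 is t = 0 ms, row 1 is the image top, and all coordinates are
#' (row, col).
#'
#' @param data numeric array, frames x height x width. All values must be
#'   finite.
#' @param dt_ms sampling interval in ms (1 ms for a 1 kHz acquisition).
#' @param pixel_mm pixel edge length in mm (0.1 mm for a 10 mm sensor at
#'   100 px and 1x magnification).
#' @param channel one of `"vm"`, `"ca"`, `"nadh"`.
#' @param meta named list of free-form provenance (source file, heart id,
#'   condition, BCL, stimulus site).
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(data, dt_ms, pixel_mm, channel = c("vm", "ca", "nadh"),
                        meta = list()) {
  channel <- match.arg(channel)
  assert_that(is.array(data) && length(dim(data)) == 3L,
              "data must be a frames x height x width array")
  d <- dim(data)
  assert_that(d[1] >= 2L, "a movie stack needs at least 2 frames")
  assert_that(d[2] >= 8L && d[3] >= 8L, "height and width must be >= 8 px")
  assert_that(is.numeric(dt_ms) && length(dt_ms) == 1L && dt_ms > 0,
              "dt_ms must be a positive scalar")
  assert_that(is.numeric(pixel_mm) && length(pixel_mm) == 1L && pixel_mm > 0,
              "pixel_mm must be a positive scalar")
  assert_that(all(is.finite(data)), "all intensities must be finite",
              class = "trimap_data_error")
  structure(
    list(data = data, dt_ms = dt_ms, pixel_mm = pixel_mm, channel = channel,
         meta = meta),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<movie_stack> channel=%s  %d frames x %d x %d px  dt=%g ms  pixel=%g mm\n",
    x$channel, d[1], d[2], d[3], x$dt_ms, x$pixel_mm))
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

.stack_duration_ms <- function(stack) dim(stack$data)[1] * stack$dt_ms

# Sidecar header (INI-style, one key=value per line) --------------------------

.header_path <- function(path, format) {
  if (format == "raw") paste0(path, ".hdr") else paste0(path, ".meta")
}

.write_header <- function(stack, path, dtype, format) {
  d <- dim(stack$data)
  lines <- c(
    "[movie]",
    paste0("frames=", d[1]),
    paste0("height=", d[2]),
    paste0("width=", d[3]),
    paste0("dtype=", dtype),
    paste0("dt_ms=", format(stack$dt_ms, digits = 17)),
    paste0("pixel_mm=", format(stack$pixel_mm, digits = 17)),
    paste0("channel=", stack$channel)
  )
  m <- stack$meta
  if (length(m)) {
    keep <- vapply(m, function(v) is.atomic(v) && length(v) == 1L, logical(1))
    lines <- c(lines, paste0("meta_", names(m)[keep], "=",
                             vapply(m[keep], as.character, character(1))))
  }
  writeLines(lines, .header_path(path, format))
}

.read_header <- function(path, format) {
  hp <- .header_path(path, format)
  if (!file.exists(hp))
    abort_trimap(sprintf("missing sidecar header '%s'", hp),
                 "trimap_format_error")
  lines <- readLines(hp, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "[") & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    abort_trimap("corrupt header: lines must be key=value", "trimap_format_error")
  vals <- vapply(kv, `[`, character(1), 2L)
  names(vals) <- vapply(kv, `[`, character(1), 1L)
  need <- c("frames", "height", "width", "dtype", "dt_ms", "pixel_mm", "channel")
  miss <- setdiff(need, names(vals))
  if (length(miss))
    abort_trimap(paste0("corrupt header: missing key(s) ",
                        paste(miss, collapse = ", ")), "trimap_format_error")
  num <- suppressWarnings(as.numeric(vals[c("frames", "height", "width",
                                            "dt_ms", "pixel_mm")]))
  if (any(!is.finite(num)) || any(num <= 0))
    abort_trimap("corrupt header: non-numeric or non-positive dimension/scale",
                 "trimap_format_error")
  meta_keys <- grep("^meta_", names(vals), value = TRUE)
  meta <- as.list(vals[meta_keys])
  names(meta) <- sub("^meta_", "", meta_keys)
  list(frames = as.integer(num[1]), height = as.integer(num[2]),
       width = as.integer(num[3]), dtype = unname(vals["dtype"]),
       dt_ms = num[4], pixel_mm = num[5], channel = unname(vals["channel"]),
       meta = meta)
}

.dtype_size <- function(dtype) {
  switch(dtype,
         uint16  = 2L,
         float32 = 4L,
         float64 = 8L,
         abort_trimap(sprintf("unsupported dtype '%s'", dtype),
                      "trimap_format_error"))
}

.guess_format <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "raw"
}

.guess_dtype <- function(data) {
  if (all(data >= 0) && all(data <= 65535) && all(data == round(data)))
    "uint16" else "float64"
}

# Read / write ----------------------------------------------------------------

#' Read a movie stack from disk
#'
#' Two on-disk formats are supported: multi-page grayscale TIFF (one page per
#' frame) and raw little-endian binary. Both carry acquisition metadata in a
#' plain-text INI-style sidecar (`<path>.hdr` for raw, `<path>.meta` for
#' TIFF) with keys `frames, height, width, dtype, dt_ms, pixel_mm, channel`,
#' inspectable without tooling. Integer (`uint16`) data round-trips
#' bit-exactly through both formats.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tiff"`, or `"raw"`.
#' @return a [movie_stack()].
#' @seealso [write_movie()]
#' @export
read_movie <- function(path, format = c("auto", "tiff", "raw")) {
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  assert_that(file.exists(path), sprintf("file '%s' does not exist", path),
              class = "trimap_io_error")
  hdr <- .read_header(path, format)
  n <- hdr$frames * hdr$height * hdr$width
  if (format == "raw") {
    size <- .dtype_size(hdr$dtype)
    payload_bytes <- file.info(path)$size
    if (payload_bytes != n * size)
      abort_trimap(sprintf(
        "payload has %d values but header declares %d (frames=%d, %dx%d)",
        payload_bytes %/% size, n, hdr$frames, hdr$height, hdr$width),
        "trimap_integrity_error")
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- switch(hdr$dtype,
      uint16  = readBin(con, "integer", n, size = 2L, signed = FALSE,
                        endian = "little"),
      float32 = readBin(con, "double", n, size = 4L, endian = "little"),
      float64 = readBin(con, "double", n, size = 8L, endian = "little"))
    data <- array(as.numeric(vals), dim = c(hdr$frames, hdr$height, hdr$width))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = (hdr$dtype == "uint16"))
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != hdr$frames)
      abort_trimap(sprintf("TIFF has %d pages but header declares %d frames",
                           length(pages), hdr$frames), "trimap_integrity_error")
    if (nrow(pages[[1]]) != hdr$height || ncol(pages[[1]]) != hdr$width)
      abort_trimap("TIFF page dimensions disagree with header",
                   "trimap_integrity_error")
    data <- array(0, dim = c(hdr$frames, hdr$height, hdr$width))
    for (k in seq_along(pages)) data[k, , ] <- pages[[k]]
    if (hdr$dtype != "uint16") {
      off <- if (!is.null(hdr$meta$tiff_offset))
        as.numeric(hdr$meta$tiff_offset) else 0
      sc <- if (!is.null(hdr$meta$tiff_scale))
        as.numeric(hdr$meta$tiff_scale) else 1
      data <- data * sc + off
      hdr$meta$tiff_offset <- NULL
      hdr$meta$tiff_scale <- NULL
    }
  }
  movie_stack(data, dt_ms = hdr$dt_ms, pixel_mm = hdr$pixel_mm,
              channel = hdr$channel,
              meta = c(hdr$meta, list(source = path, dtype = hdr$dtype)))
}

#' Write a movie stack to disk
#'
#' @param stack a [movie_stack()].
#' @param path destination file path.
#' @param format `"auto"`, `"tiff"`, or `"raw"` (see [read_movie()]).
#' @param dtype `"auto"` (uint16 when all values are integers in
#'   0..65535, else float64), `"uint16"`, `"float32"`, or `"float64"`.
#'   TIFF supports uint16 and float32.
#' @return `path`, invisibly.
#' @export
write_movie <- function(stack, path, format = c("auto", "tiff", "raw"),
                        dtype = "auto") {
  assert_that(inherits(stack, "movie_stack"), "stack must be a movie_stack")
  if (length(format) == 1L && !format %in% c("auto", "tiff", "raw"))
    abort_trimap(sprintf("unknown format '%s'", format), "trimap_usage_error")
  format <- match.arg(format)
  if (format == "auto") format <- .guess_format(path)
  if (dtype == "auto") dtype <- .guess_dtype(stack$data)
  if (!dtype %in% c("uint16", "float32", "float64"))
    abort_trimap(sprintf("unsupported dtype '%s'", dtype), "trimap_format_error")
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    abort_trimap(sprintf("cannot write to '%s'", dir), "trimap_io_error")
  d <- dim(stack$data)
  if (format == "raw") {
    con <- file(path, "wb")
    vals <- as.vector(stack$data)
    switch(dtype,
      uint16  = writeBin(as.integer(vals), con, size = 2L, endian = "little"),
      float32 = writeBin(as.numeric(vals), con, size = 4L, endian = "little"),
      float64 = writeBin(as.numeric(vals), con, size = 8L, endian = "little"))
    close(con)
  } else {
    if (dtype == "float64") dtype <- "float32"
    # TIFF samples live in [0, 1]; floats are affinely packed and the
    # (offset, scale) pair recorded in the sidecar so reads invert exactly.
    tiff_offset <- 0; tiff_scale <- 65535
    if (dtype == "float32") {
      tiff_offset <- min(stack$data)
      tiff_scale <- max(stack$data) - tiff_offset
      if (tiff_scale <= 0) tiff_scale <- 1
    }
    pages <- lapply(seq_len(d[1]), function(k) {
      page <- matrix(stack$data[k, , ], d[2], d[3])
      (page - tiff_offset) / tiff_scale
    })
    bits <- if (dtype == "uint16") 16L else 32L
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
    stack$meta$tiff_offset <- tiff_offset
    stack$meta$tiff_scale <- tiff_scale
  }
  .write_header(stack, path, dtype, format)
  invisible(path)
}

# Recording manifest ----------------------------------------------------------

.manifest_cols <- c("heart_id", "condition", "bcl_ms", "vm_path", "ca_path",
                    "nadh_path", "stim_row", "stim_col", "fiber_axis_deg")

#' Read or write a recording manifest
#'
#' The manifest is a CSV grouping the three channel files of each recording
#' with its experimental design: columns `heart_id, condition, bcl_ms,
#' vm_path, ca_path, nadh_path, stim_row, stim_col, fiber_axis_deg`. Exactly
#' one entry per (heart, condition, BCL) triple is allowed.
#'
#' @param path CSV file path.
#' @param manifest a data.frame with the manifest columns.
#' @return `read_manifest()`: a validated data.frame; `write_manifest()`:
#'   `path`, invisibly.
#' @export
read_manifest <- function(path) {
  assert_that(file.exists(path), sprintf("manifest '%s' does not exist", path),
              class = "trimap_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(df)
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_manifest
#' @export
validate_manifest <- function(manifest) {
  miss <- setdiff(.manifest_cols, names(manifest))
  if (length(miss))
    abort_trimap(paste0("manifest is missing column(s): ",
                        paste(miss, collapse = ", ")), "trimap_format_error")
  assert_that(all(manifest$bcl_ms > 0), "bcl_ms must be positive",
              class = "trimap_format_error")
  key <- paste(manifest$heart_id, manifest$condition, manifest$bcl_ms)
  if (anyDuplicated(key))
    abort_trimap("duplicate (heart, condition, BCL) entries in manifest",
                 "trimap_format_error")
  manifest
}

# Channel co-registration -----------------------------------------------------

# Time-averaged, edge-enhanced view of a stack (gradient magnitude of the
# mean frame); this is what gets cross-correlated between channels.
.edge_image <- function(stack) {
  img <- apply(stack$data, c(2, 3), mean)
  h <- nrow(img); w <- ncol(img)
  gx <- img[, c(2:w, w)] - img[, c(1, 1:(w - 1))]
  gy <- img[c(2:h, h), ] - img[c(1, 1:(h - 1)), ]
  sqrt(gx^2 + gy^2)
}

.shifted_cor <- function(ref, mov, dr, dc) {
  # correlation of ref[i, j] with mov[i + dr, j + dc]: maximal at the true
  # displacement when mov[i, j] ~ ref[i - dr, j - dc]
  h <- nrow(ref); w <- ncol(ref)
  r1 <- max(1, 1 - dr); r2 <- min(h, h - dr)
  c1 <- max(1, 1 - dc); c2 <- min(w, w - dc)
  if (r2 - r1 < 4 || c2 - c1 < 4) return(NA_real_)
  a <- ref[r1:r2, c1:c2]
  b <- mov[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(as.vector(a), as.vector(b))
}

#' Co-register two channels by translation
#'
#' Estimates the (row, col) translation of `moving` relative to `reference`
#' by exhaustive integer-shift search maximizing the spatial cross-correlation
#' of the time-averaged, edge-enhanced frames, with optional sub-pixel
#' refinement by parabolic interpolation of the correlation surface. The
#' convention is `moving[i, j] ~ reference[i - dr, j - dc]`, so applying the
#' negated shift to `moving` aligns it onto the reference.
#'
#' Translation-only correction mirrors first-order mirror-tilt misalignment
#' between cameras sharing a tandem lens; residual rotation/scale error is
#' assumed negligible (see the package vignette).
#'
#' @param reference,moving [movie_stack()] objects with identical raster
#'   shape and frame count.
#' @param max_shift_px maximum absolute shift searched, in px.
#' @param subpixel refine the integer optimum by parabolic interpolation.
#' @return a `channel_alignment`: list with `shift_rc` (length-2 numeric) and
#'   `score` (peak correlation clipped to \[0, 1\]).
#' @export
coregister <- function(reference, moving, max_shift_px = 10L, subpixel = TRUE) {
  assert_that(inherits(reference, "movie_stack") && inherits(moving, "movie_stack"),
              "reference and moving must be movie_stack objects")
  assert_that(identical(dim(reference$data), dim(moving$data)),
              "stacks must share frame count and raster shape")
  h <- dim(reference$data)[2]; w <- dim(reference$data)[3]
  if (max_shift_px > floor(min(h, w) / 2))
    abort_trimap("max_shift_px exceeds half the raster size", "trimap_usage_error")
  ref <- .edge_image(reference)
  mov <- .edge_image(moving)
  if (stats::sd(ref) == 0 || stats::sd(mov) == 0)
    abort_trimap("flat (zero-variance) image: cannot co-register",
                 "trimap_degenerate_error")
  shifts <- -max_shift_px:max_shift_px
  cc <- matrix(NA_real_, length(shifts), length(shifts),
               dimnames = list(shifts, shifts))
  for (i in seq_along(shifts)) for (j in seq_along(shifts))
    cc[i, j] <- .shifted_cor(ref, mov, shifts[i], shifts[j])
  best <- which(cc == max(cc, na.rm = TRUE), arr.ind = TRUE)[1, ]
  dr <- shifts[best[1]]; dc <- shifts[best[2]]
  sr <- as.numeric(dr); sc <- as.numeric(dc)
  if (subpixel) {
    refine <- function(m1, m0, p1) {
      den <- m1 - 2 * m0 + p1
      if (is.finite(den) && den < 0) 0.5 * (m1 - p1) / den else 0
    }
    if (best[1] > 1 && best[1] < nrow(cc) &&
        all(is.finite(cc[best[1] + c(-1, 1), best[2]])))
      sr <- sr + refine(cc[best[1] - 1, best[2]], cc[best[1], best[2]],
                        cc[best[1] + 1, best[2]])
    if (best[2] > 1 && best[2] < ncol(cc) &&
        all(is.finite(cc[best[1], best[2] + c(-1, 1)])))
      sc <- sc + refine(cc[best[1], best[2] - 1], cc[best[1], best[2]],
                        cc[best[1], best[2] + 1])
  }
  structure(list(shift_rc = c(sr, sc),
                 score = max(0, min(1, max(cc, na.rm = TRUE)))),
            class = "channel_alignment")
}

#' Apply an integer translation to a movie stack
#'
#' Shifts every frame so that the content displaced by `shift_rc` (as
#' estimated by [coregister()]) is brought back into register with the
#' reference. Vacated pixels are filled with `fill`.
#'
#' @param stack a [movie_stack()].
#' @param shift_rc length-2 (row, col) shift from [coregister()]; rounded to
#'   integers.
#' @param fill value for vacated border pixels.
#' @return a shifted [movie_stack()].
#' @export
apply_shift <- function(stack, shift_rc, fill = 0) {
  dr <- as.integer(round(shift_rc[1])); dc <- as.integer(round(shift_rc[2]))
  d <- dim(stack$data)
  out <- array(fill, d)
  rows <- seq_len(d[2]); cols <- seq_len(d[3])
  src_r <- rows + dr; src_c <- cols + dc
  ok_r <- src_r >= 1L & src_r <= d[2]
  ok_c <- src_c >= 1L & src_c <= d[3]
  out[, rows[ok_r], cols[ok_c]] <- stack$data[, src_r[ok_r], src_c[ok_c]]
  movie_stack(out, stack$dt_ms, stack$pixel_mm, stack$channel, stack$meta)
}
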