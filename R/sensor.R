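#' Sensor configuration for the downward-beam visual system
#'
#' The sensor models a nadir-pointing "beam" that sees a square ground patch
#' with no perspective distortion. A raw `window_px` crop is rotated to the
#' travel heading, contrast-equalized, block-mean downsampled to
#' `out_res` x `out_res`, quantized to `gray_levels` gray levels, and finally
#' restricted to a circular field of view.
#'
#' @param window_px Side of the raw crop, pixels (default 640).
#' @param out_res Downsampled sensor side, pixels (typical 10, 20, 40, 50, 80).
#' @param gray_levels Pixel depth: number of gray levels, at least 2
#'   (2 = black/white).
#' @param equalize Apply per-scene histogram equalization before downsampling.
#' @param rotation_increment_deg Rotation step used by [ridf()] (default 1).
#' @param equalize_after_downsample If `TRUE`, equalization is applied to the
#'   downsampled matrix instead of the high-resolution crop.
#' @return An object of class `scenefam_sensor`.
#' @export
sensor_config <- function(window_px = 640, out_res = 50, gray_levels = 10,
                          equalize = TRUE, rotation_increment_deg = 1,
                          equalize_after_downsample = FALSE) {
  window_px <- as.integer(window_px)
  out_res <- as.integer(out_res)
  gray_levels <- as.integer(gray_levels)
  if (out_res < 2L || out_res > window_px)
    stop("`out_res` must lie in [2, window_px]")
  if (gray_levels < 2L) stop("`gray_levels` must be at least 2")
  if (rotation_increment_deg <= 0) stop("rotation increment must be positive")
  structure(
    list(window_px = window_px, out_res = out_res, gray_levels = gray_levels,
         equalize = isTRUE(equalize),
         rotation_increment_deg = rotation_increment_deg,
         equalize_after_downsample = isTRUE(equalize_after_downsample)),
    class = "scenefam_sensor")
}

#' @export
print.scenefam_sensor <- function(x, ...) {
  cat(sprintf("<scenefam_sensor> window %d px -> %d x %d, %d gray levels, equalize %s\n",
              x$window_px, x$out_res, x$out_res, x$gray_levels,
              if (x$equalize) "on" else "off"))
  invisible(x)
}

#' Per-scene histogram equalization
#'
#' Rank-based contrast enhancement: each value is remapped to
#' `255 * cdf(x)` where `cdf` is the empirical distribution of the scene's
#' own values (ties share their maximal rank). The output approximates a
#' uniform histogram over \[0, 255\], is a monotone function of the input, and
#' maps a constant raster to a constant. `NA` cells (e.g. rotation-invalid
#' corners) are ignored and preserved.
#'
#' @param raster Numeric matrix of gray values.
#' @return Matrix of the same shape with values in \[0, 255\].
#' @export
equalize_raster <- function(raster) {
  if (length(raster) == 0L) stop("empty raster")
  n_ok <- sum(!is.na(raster))
  if (n_ok == 0L) stop("raster has no defined cells")
  r <- rank(raster, na.last = "keep", ties.method = "max")
  out <- 255 * r / n_ok
  dim(out) <- dim(raster)
  out
}

#' Block-mean downsampling
#'
#' Each output cell is the mean of its source block. When the input side is an
#' exact multiple of `out_res` the blocks are exact `b` x `b` tiles; otherwise
#' source pixels are binned to output cells by `floor(index * out_res / side)`,
#' an area-style pooling. `NA` source cells are excluded from their block mean.
#'
#' @param raster Square numeric matrix.
#' @param out_res Output side, at most the input side.
#' @return `out_res` x `out_res` numeric matrix.
#' @export
downsample_raster <- function(raster, out_res) {
  s <- nrow(raster)
  if (ncol(raster) != s) stop("downsampling requires a square raster")
  out_res <- as.integer(out_res)
  if (out_res > s) stop("`out_res` exceeds the raster side")
  if (out_res == s) return(raster)
  idx <- floor((seq_len(s) - 1) * out_res / s) + 1L
  ok <- !is.na(raster)
  x0 <- raster
  x0[!ok] <- 0
  sums <- t(rowsum(t(rowsum(x0, idx)), idx))
  cnts <- t(rowsum(t(rowsum(ok + 0, idx)), idx))
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  # rowsum orders groups by sorted unique labels = 1..out_res already
  dimnames(out) <- NULL
  out
}

#' Uniform gray-level quantization
#'
#' Bins \[0, 255\] into `gray_levels` equal-width bins:
#' `level = min(floor(x * g / 256), g - 1)`, so levels run 0 to `g - 1` and
#' the black/white mode (`g = 2`) thresholds at 128.
#'
#' @param raster Numeric matrix with values in \[0, 255\].
#' @param gray_levels Number of levels, at least 2.
#' @return Matrix of integer levels in `{0, ..., gray_levels - 1}`.
#' @export
quantize_raster <- function(raster, gray_levels) {
  g <- as.integer(gray_levels)
  if (g < 2L) stop("`gray_levels` must be at least 2")
  pmin(floor(raster * g / 256), g - 1L)
}

#' Circular field-of-view mask
#'
#' Cell `(i, j)` is kept iff its center lies strictly inside the circle of
#' radius `n/2` centered at the matrix center. Corner cropping removes about
#' 21% of the square (the kept fraction tends to pi/4 as `n` grows) and makes
#' views rotation-comparable.
#'
#' @param n Sensor side, at least 1.
#' @return `n` x `n` logical matrix.
#' @export
circular_mask <- function(n) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be at least 1")
  c0 <- (n + 1) / 2
  d <- (seq_len(n) - c0)^2
  outer(d, d, `+`) < (n / 2)^2
}

# per-session mask cache (the mask is recomputed thousands of times in scans)
.scenefam_cache <- new.env(parent = emptyenv())

cached_mask <- function(n) {
  key <- as.character(n)
  m <- .scenefam_cache[[key]]
  if (is.null(m)) {
    m <- circular_mask(n)
    .scenefam_cache[[key]] <- m
  }
  m
}

#' Rotate a square scene about its center
#'
#' Positive angles bring the world bearing `angle_deg` to the top of the view
#' (the scene content rotates accordingly). Multiples of 90 degrees are exact
#' index permutations; other angles use bilinear interpolation. Cells whose
#' pre-image falls outside the source are `NA` (they are discarded by the
#' circular mask downstream).
#'
#' @param raster Square numeric matrix.
#' @param angle_deg Rotation angle, degrees.
#' @return Rotated matrix of the same shape.
#' @export
rotate_scene <- function(raster, angle_deg) {
  n <- nrow(raster)
  if (ncol(raster) != n) stop("rotation requires a square raster")
  a <- angle_deg %% 360
  if (isTRUE(all.equal(a %% 90, 0)) || isTRUE(all.equal(a %% 90, 90))) {
    k <- round(a / 90) %% 4
    return(switch(as.character(k),
                  "0" = raster,
                  "1" = t(raster[, n:1, drop = FALSE]),
                  "2" = raster[n:1, n:1, drop = FALSE],
                  "3" = t(raster[n:1, , drop = FALSE])))
  }
  cpp_rotate_bilinear(raster, a)
}

#' Process a full sensor view
#'
#' Runs the whole visual pipeline at a landscape position:
#' crop -> rotate to `heading_deg` -> equalize -> downsample -> quantize ->
#' circular mask. The resulting view stores its quantized levels, the mask,
#' the heading its "up" direction corresponds to, and its center.
#'
#' @param land A [landscape()] object.
#' @param center Scene center ([position()]).
#' @param heading_deg World bearing mapped to the view's "up" (north = 0,
#'   clockwise).
#' @param cfg A [sensor_config()].
#' @return An object of class `scenefam_view`: `values` (n x n levels, `NA`
#'   outside the mask), `mask`, `v` (masked values as a vector), `heading_deg`,
#'   `center`, `cfg`.
#' @export
process_view <- function(land, center, heading_deg, cfg) {
  stopifnot(inherits(cfg, "scenefam_sensor"))
  x <- crop_window(land, center, cfg$window_px)
  x <- rotate_scene(x, heading_deg)
  if (cfg$equalize && !cfg$equalize_after_downsample) x <- equalize_raster(x)
  x <- downsample_raster(x, cfg$out_res)
  if (cfg$equalize && cfg$equalize_after_downsample) x <- equalize_raster(x)
  x <- quantize_raster(x, cfg$gray_levels)
  mask <- cached_mask(cfg$out_res)
  x[!mask] <- NA_real_
  structure(
    list(values = x, mask = mask, v = x[mask],
         heading_deg = heading_deg %% 360,
         center = c(row = as.numeric(center[1]), col = as.numeric(center[2])),
         cfg = cfg),
    class = "scenefam_view")
}

#' @export
print.scenefam_view <- function(x, ...) {
  cat(sprintf("<scenefam_view> %d x %d, %d levels, heading %.1f deg at (%.1f, %.1f)\n",
              x$cfg$out_res, x$cfg$out_res, x$cfg$gray_levels,
              x$heading_deg, x$center[1], x$center[2]))
  invisible(x)
}

#' Angular width of the downward beam
#'
#' A nadir sensor at `altitude_m` seeing a `ground_span_m` patch subtends
#' `2 * atan((ground_span / 2) / altitude)` degrees: a 100 m patch from 250 m
#' is a 22.6 degree beam.
#'
#' @param ground_span_m Ground span of the viewed patch, meters.
#' @param altitude_m Sensor altitude, meters.
#' @return Beam width in degrees.
#' @export
beam_width_deg <- function(ground_span_m, altitude_m) {
  if (ground_span_m < 0 || altitude_m <= 0)
    stop("ground span must be non-negative and altitude positive")
  2 * atan((ground_span_m / 2) / altitude_m) * 180 / pi
}
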