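#' Specification of a synthetic landscape
#'
#' Seeded generators emulate three information regimes of real aerial
#' imagery: `"low"` — near-featureless open water (a faint smooth swell);
#' `"medium"` — smooth sandy ground dotted with sparse high-contrast
#' vegetated hummocks; `"high"` — dense multi-scale urban texture (blocks and
#' fine structure). The same spec always generates a bit-identical raster.
#'
#' @param regime One of `"low"`, `"medium"`, `"high"`.
#' @param size_px Square landscape side, pixels (default 600).
#' @param meters_per_pixel Ground scale (default 1).
#' @param seed Integer seed; all randomness derives from it.
#' @param noise_amplitude Gray-level standard deviation of the smooth
#'   component (regime-specific default).
#' @param blob_density Blobs per megapixel for the medium regime; the default
#'   puts a hummock every 25-30 px so every sensor window sees several.
#' @param blob_radius_px Range of blob radii, pixels.
#' @param block_density Rectangular blocks per megapixel for the high regime.
#' @param texture_contrast Gray-level scale of the high-regime texture.
#' @return Object of class `scenefam_terrain`.
#' @export
terrain_spec <- function(regime = c("low", "medium", "high"), size_px = 600,
                         meters_per_pixel = 1, seed = 1,
                         noise_amplitude = NULL,
                         blob_density = 1000, blob_radius_px = c(4, 12),
                         block_density = 500, texture_contrast = 55) {
  regime <- match.arg(regime)
  if (is.null(noise_amplitude))
    noise_amplitude <- switch(regime, low = 3, medium = 6, high = 25)
  structure(
    list(regime = regime, size_px = as.integer(size_px),
         meters_per_pixel = meters_per_pixel, seed = as.integer(seed),
         noise_amplitude = noise_amplitude, blob_density = blob_density,
         blob_radius_px = blob_radius_px, block_density = block_density,
         texture_contrast = texture_contrast),
    class = "scenefam_terrain")
}

# periodic gaussian smoothing by FFT; returns a zero-mean unit-sd field
smooth_noise_field <- function(n, sigma) {
  z <- matrix(stats::rnorm(n * n), n, n)
  d <- pmin(0:(n - 1), n - (0:(n - 1)))
  g <- exp(-d^2 / (2 * sigma^2))
  K <- outer(g, g)
  s <- Re(stats::fft(stats::fft(z) * stats::fft(K / sum(K)), inverse = TRUE)) / n^2
  (s - mean(s)) / stats::sd(s)
}

stamp_disc <- function(raster, row, col, radius, amount) {
  n <- nrow(raster)
  r0 <- max(1, floor(row - 2 * radius)); r1 <- min(n, ceiling(row + 2 * radius))
  c0 <- max(1, floor(col - 2 * radius)); c1 <- min(n, ceiling(col + 2 * radius))
  dr <- (r0:r1) - row
  dc <- (c0:c1) - col
  d2 <- outer(dr^2, dc^2, `+`)
  raster[r0:r1, c0:c1] <- raster[r0:r1, c0:c1] +
    amount * exp(-d2 / (2 * (radius / 1.6)^2))
  raster
}

#' Generate a synthetic landscape
#'
#' @param spec A [terrain_spec()].
#' @return A [landscape()] object, bit-identical for identical specs.
#' @export
make_landscape <- function(spec) {
  stopifnot(inherits(spec, "scenefam_terrain"))
  n <- spec$size_px
  withr::with_seed(spec$seed, {
    x <- switch(
      spec$regime,
      low = 120 + spec$noise_amplitude * smooth_noise_field(n, n / 24),
      medium = {
        # bright, low-contrast sandy ground: raw intensities sit in a narrow
        # band well above mid-gray, so fixed quantization bins crush the
        # structure unless contrast is equalized first
        bg <- 205 + spec$noise_amplitude * smooth_noise_field(n, n / 15)
        n_blobs <- max(1L, round(spec$blob_density * n^2 / 1e6))
        rows <- stats::runif(n_blobs, 1, n)
        cols <- stats::runif(n_blobs, 1, n)
        radii <- stats::runif(n_blobs, spec$blob_radius_px[1],
                              spec$blob_radius_px[2])
        amps <- -stats::runif(n_blobs, 40, 70)
        for (i in seq_len(n_blobs)) {
          bg <- stamp_disc(bg, rows[i], cols[i], radii[i], amps[i])
        }
        bg
      },
      high = {
        tex <- 128 + spec$texture_contrast *
          (0.5 * smooth_noise_field(n, 2) +
           0.35 * smooth_noise_field(n, 8) +
           0.25 * smooth_noise_field(n, 24))
        n_blk <- max(1L, round(spec$block_density * n^2 / 1e6))
        r0 <- stats::runif(n_blk, 1, n)
        c0 <- stats::runif(n_blk, 1, n)
        w <- stats::runif(n_blk, 8, 40)
        h <- stats::runif(n_blk, 8, 40)
        lev <- stats::runif(n_blk, -110, 110)
        for (i in seq_len(n_blk)) {
          rr <- max(1, round(r0[i])):min(n, round(r0[i] + h[i]))
          cc <- max(1, round(c0[i])):min(n, round(c0[i] + w[i]))
          tex[rr, cc] <- tex[rr, cc] + lev[i]
        }
        tex
      })
    landscape(round(pmin(pmax(x, 0), 255)), spec$meters_per_pixel)
  })
}

#' Deterministic training-route waypoints on a landscape
#'
#' Routes are laid out inside the croppable region (window margins plus an
#' `edge_pad_px` allowance for arc overshoot). Shapes: `"straight"` — a single
#' west-to-east segment; `"s_curve"` — a sinusoidal S across the landscape;
#' `"spiral"` — an expanding square spiral with right-angle corners; `"loop"` —
#' a route whose tail crosses its own first segment exactly once.
#'
#' @param shape One of `"s_curve"`, `"spiral"`, `"loop"`, `"straight"`.
#' @param land A [landscape()] object.
#' @param window_px Sensor window side used to reserve margins.
#' @param edge_pad_px Extra margin beyond the window inset, pixels.
#' @param n_waypoints Waypoints used to trace the s-curve.
#' @return A [waypoints()] object.
#' @export
make_route <- function(shape = c("s_curve", "spiral", "loop", "straight"),
                       land, window_px = 80, edge_pad_px = 30,
                       n_waypoints = 9) {
  shape <- match.arg(shape)
  stopifnot(inherits(land, "scenefam_landscape"))
  m <- ceiling(window_px / 2) + edge_pad_px
  h <- land$height_px; w <- land$width_px
  if (h - 2 * m < 40 || w - 2 * m < 40)
    stop("landscape too small for a ", shape, " route with ", window_px,
         "px windows")
  u <- function(fr, fc) c(m + fr * (h - 2 * m), m + fc * (w - 2 * m))
  wp <- switch(
    shape,
    straight = rbind(u(0.5, 0), u(0.5, 1)),
    s_curve = {
      t <- seq(0, 1, length.out = n_waypoints)
      cbind(m + (0.5 + 0.3 * sin(2 * pi * t)) * (h - 2 * m),
            m + t * (w - 2 * m))
    },
    spiral = {
      ctr <- u(0.5, 0.5)
      d <- min(h, w, 600) / 12
      pts <- ctr
      dirs <- rbind(c(0, 1), c(1, 0), c(0, -1), c(-1, 0))  # E, S, W, N
      p <- ctr
      for (leg in 1:7) {
        len <- ceiling(leg / 2) * d
        p <- p + dirs[(leg - 1) %% 4 + 1, ] * len
        pts <- rbind(pts, p)
      }
      pts
    },
    loop = rbind(u(0.6, 0.1), u(0.6, 0.8), u(0.25, 0.8), u(0.25, 0.5),
                 u(0.9, 0.5)))
  wp <- waypoints(wp)
  ok <- vapply(seq_len(nrow(wp)), function(i) {
    is_croppable(land, wp[i, ], window_px)
  }, logical(1))
  if (!all(ok)) stop("route does not fit the croppable region")
  wp
}
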