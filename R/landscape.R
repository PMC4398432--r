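#' Construct a landscape from a raster matrix
#'
#' A landscape is a large 2-D grayscale raster with a ground scale. Intensities
#' are gray values in \[0, 255\]; positions on it are 1-based `(row, col)` pixel
#' coordinates with row increasing downward and column increasing rightward.
#'
#' @param raster Numeric or integer matrix with values in \[0, 255\].
#' @param meters_per_pixel Positive ground scale in meters per pixel.
#' @return An object of class `scenefam_landscape` with fields `raster`,
#'   `meters_per_pixel`, `height_px`, `width_px`.
#' @export
landscape <- function(raster, meters_per_pixel) {
  if (!is.matrix(raster) || length(raster) == 0L)
    stop("`raster` must be a non-empty matrix")
  rng <- range(raster, na.rm = TRUE)
  if (anyNA(raster) || rng[1] < 0 || rng[2] > 255)
    stop("raster values must lie in [0, 255] with no missing cells")
  if (!is.numeric(meters_per_pixel) || length(meters_per_pixel) != 1L ||
      !is.finite(meters_per_pixel) || meters_per_pixel <= 0)
    stop("`meters_per_pixel` must be a single positive number")
  structure(
    list(raster = raster,
         meters_per_pixel = meters_per_pixel,
         height_px = nrow(raster),
         width_px = ncol(raster)),
    class = "scenefam_landscape")
}

#' @export
print.scenefam_landscape <- function(x, ...) {
  cat(sprintf("<scenefam_landscape> %d x %d px @ %g m/px (%g x %g m)\n",
              x$height_px, x$width_px, x$meters_per_pixel,
              x$height_px * x$meters_per_pixel,
              x$width_px * x$meters_per_pixel))
  invisible(x)
}

#' Load a landscape raster from a PNG file
#'
#' Color images are converted to grayscale with the standard Rec. 601 luminance
#' weights (0.299 R + 0.587 G + 0.114 B); an alpha channel, if present, is
#' ignored. Intensities are scaled to \[0, 255\].
#'
#' @param path Path to an 8-bit grayscale or RGB(A) PNG file.
#' @inheritParams landscape
#' @return A [landscape()] object.
#' @export
load_landscape <- function(path, meters_per_pixel) {
  if (!file.exists(path)) stop("cannot read landscape image: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  landscape(round(img * 255), meters_per_pixel)
}

#' Write a landscape to an 8-bit grayscale PNG file
#'
#' @param land A [landscape()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landscape_png <- function(land, path) {
  stopifnot(inherits(land, "scenefam_landscape"))
  png::writePNG(land$raster / 255, target = path)
  invisible(path)
}

#' Create a position
#'
#' Positions are 1-based `(row, col)` pixel coordinates (row grows downward).
#' Fractional coordinates are allowed; window crops snap to the
#' nearest-integer top-left corner.
#'
#' @param row,col Coordinates in pixels.
#' @return Named numeric vector `c(row, col)`.
#' @export
position <- function(row, col) {
  p <- c(row = as.numeric(row), col = as.numeric(col))
  if (any(!is.finite(p))) stop("positions must be finite")
  p
}

window_corner <- function(center, window_px) {
  # nearest-integer top-left corner of the window centered at `center`
  floor(center - (window_px - 1) / 2 + 0.5)
}

#' Test whether a full sensor window fits at a position
#'
#' @param land A [landscape()] object.
#' @param center Position of the window center (see [position()]).
#' @param window_px Side of the square window, pixels.
#' @return Logical.
#' @export
is_croppable <- function(land, center, window_px) {
  tl <- window_corner(center, window_px)
  all(tl >= 1) && tl[1] + window_px - 1 <= land$height_px &&
    tl[2] + window_px - 1 <= land$width_px
}

#' Extract a raw square scene from a landscape
#'
#' The window must lie fully inside the raster; a window overrunning the
#' boundary is an error (a navigating agent treats this as running off the
#' mapped area).
#'
#' @inheritParams is_croppable
#' @return `window_px` x `window_px` numeric matrix, values copied unchanged.
#' @export
crop_window <- function(land, center, window_px) {
  stopifnot(inherits(land, "scenefam_landscape"))
  window_px <- as.integer(window_px)
  if (window_px < 1L) stop("`window_px` must be positive")
  tl <- window_corner(center, window_px)
  if (any(tl < 1) || tl[1] + window_px - 1L > land$height_px ||
      tl[2] + window_px - 1L > land$width_px)
    stop("window overruns the landscape boundary at (",
         center[1], ", ", center[2], ")")
  land$raster[tl[1]:(tl[1] + window_px - 1L),
              tl[2]:(tl[2] + window_px - 1L), drop = FALSE]
}

#' Equally spaced grid of croppable scene centers
#'
#' Centers are inset from the raster edge so that every window is fully
#' croppable; within that margin the `rows` x `cols` centers are equally
#' spaced and returned in row-major order.
#'
#' @inheritParams is_croppable
#' @param rows,cols Grid dimensions (each at least 2).
#' @return An object of class `scenefam_grid`: `positions` (n x 2 matrix of
#'   row, col), `rows`, `cols`, `spacing_px` (named vector, row and col
#'   spacing), `window_px`.
#' @export
sample_grid <- function(land, rows, cols, window_px) {
  stopifnot(inherits(land, "scenefam_landscape"))
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 2L || cols < 2L) stop("grid needs at least 2 rows and 2 columns")
  lo <- ceiling(window_px / 2)
  hi_r <- land$height_px - floor(window_px / 2)
  hi_c <- land$width_px - floor(window_px / 2)
  if (hi_r <= lo || hi_c <= lo)
    stop("landscape too small for a ", rows, "x", cols,
         " grid of ", window_px, "px windows")
  rs <- seq(lo, hi_r, length.out = rows)
  cs <- seq(lo, hi_c, length.out = cols)
  pos <- cbind(row = rep(rs, each = cols), col = rep(cs, times = rows))
  structure(
    list(positions = pos, rows = rows, cols = cols,
         spacing_px = c(row = (hi_r - lo) / (rows - 1),
                        col = (hi_c - lo) / (cols - 1)),
         window_px = window_px),
    class = "scenefam_grid")
}

#' @export
print.scenefam_grid <- function(x, ...) {
  cat(sprintf("<scenefam_grid> %d x %d centers, spacing %.2f x %.2f px, window %d px\n",
              x$rows, x$cols, x$spacing_px["row"], x$spacing_px["col"],
              x$window_px))
  invisible(x)
}

#' @export
as.data.frame.scenefam_grid <- function(x, ...) {
  as.data.frame(x$positions)
}

#' Linear overlap fraction between adjacent sensor windows
#'
#' For windows spanning `window_m` meters of ground sampled at centers
#' `spacing_m` apart, the linear overlap fraction is
#' `(window_m - spacing_m) / window_m`; 100 m windows at 5 m spacing overlap
#' by 95%.
#'
#' @param window_m Ground span of one window, meters.
#' @param spacing_m Distance between adjacent window centers, meters.
#' @return Overlap fraction in \[0, 1\] (0 when spacing exceeds the window).
#' @export
linear_overlap <- function(window_m, spacing_m) {
  if (window_m <= 0 || spacing_m < 0) stop("invalid window or spacing")
  max(0, (window_m - spacing_m) / window_m)
}
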