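#' Image difference score between two views
#'
#' The scene-to-scene difference score: the sum over circularly masked cells
#' of the absolute difference between quantized levels. It is symmetric, zero
#' iff the masked cells are identical, bounded by
#' `n_pixels * (gray_levels - 1)`, and satisfies the triangle inequality.
#' Low values mean high familiarity.
#'
#' @param a,b Views from [process_view()] with identical sensor settings
#'   (`out_res`, `gray_levels`).
#' @return Single non-negative number.
#' @export
image_difference <- function(a, b) {
  stopifnot(inherits(a, "scenefam_view"), inherits(b, "scenefam_view"))
  if (a$cfg$out_res != b$cfg$out_res || a$cfg$gray_levels != b$cfg$gray_levels)
    stop("views were processed with different sensor configurations")
  sum(abs(a$v - b$v))
}

#' Image-difference topography of a landscape
#'
#' Every grid scene (processed at heading 0) is compared to every other grid
#' scene and its difference scores are summed. High values mark scenes that
#' are distinct within the environment; low values mark aliasing-prone,
#' self-similar regions.
#'
#' @param land A [landscape()] object.
#' @param grid A [sample_grid()] over `land`.
#' @param cfg A [sensor_config()] (its `window_px` should match the grid's).
#' @return Object of class `scenefam_diffmap`: `grid` (rows x cols matrix of
#'   summed difference scores), `grid_spec`.
#' @export
difference_topography <- function(land, grid, cfg) {
  stopifnot(inherits(grid, "scenefam_grid"))
  V <- views_matrix(land, grid$positions, cfg)
  totals <- cpp_pairwise_diff_totals(V)
  structure(
    list(grid = matrix(totals, nrow = grid$rows, ncol = grid$cols,
                       byrow = TRUE),
         grid_spec = grid),
    class = "scenefam_diffmap")
}

# stack processed views (heading 0) as an n_positions x n_masked_pixels matrix
views_matrix <- function(land, positions, cfg) {
  mask <- circular_mask(cfg$out_res)
  V <- matrix(0, nrow = nrow(positions), ncol = sum(mask))
  for (i in seq_len(nrow(positions))) {
    V[i, ] <- process_view(land, positions[i, ], 0, cfg)$v
  }
  V
}

#' @export
print.scenefam_diffmap <- function(x, ...) {
  cat(sprintf("<scenefam_diffmap> %d x %d, score range [%g, %g]\n",
              nrow(x$grid), ncol(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Familiarity volcano around a focal scene
#'
#' Image differences between a fixed focal view and the views at the
#' surrounding `(2k+1)` x `(2k+1)` grid of positions, all at heading 0. The
#' surface's central pit is zero (focal vs itself); its depth and slope
#' measure how localizable the focal view is — the catchment within which a
#' gradient descent on image difference homes to the focal point.
#'
#' @param land A [landscape()] object.
#' @param focal Focal scene center ([position()]).
#' @param k Surround half-width in grid steps.
#' @param cfg A [sensor_config()].
#' @param spacing_px Distance between surround centers, pixels.
#' @param out_of_bounds `"error"` to fail on surround positions whose window
#'   leaves the raster, `"trim"` to record them as `NA` with a warning.
#' @return Object of class `scenefam_volcano`: `surface` ((2k+1) x (2k+1)
#'   matrix), `focal`, `k`, `spacing_px`, `spacing_m`.
#' @export
volcano <- function(land, focal, k, cfg, spacing_px,
                    out_of_bounds = c("error", "trim")) {
  out_of_bounds <- match.arg(out_of_bounds)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be at least 1")
  focal_view <- process_view(land, focal, 0, cfg)
  side <- 2L * k + 1L
  surf <- matrix(NA_real_, side, side)
  n_dropped <- 0L
  for (di in -k:k) {
    for (dj in -k:k) {
      p <- c(focal[1] + di * spacing_px, focal[2] + dj * spacing_px)
      if (!is_croppable(land, p, cfg$window_px)) {
        if (out_of_bounds == "error")
          stop("surround window leaves the landscape at offset (",
               di, ", ", dj, ")")
        n_dropped <- n_dropped + 1L
        next
      }
      surf[di + k + 1L, dj + k + 1L] <-
        image_difference(focal_view, process_view(land, p, 0, cfg))
    }
  }
  if (n_dropped > 0L)
    warning(n_dropped, " surround scene(s) trimmed at the landscape boundary")
  structure(
    list(surface = surf, focal = focal, k = k, spacing_px = spacing_px,
         spacing_m = spacing_px * land$meters_per_pixel),
    class = "scenefam_volcano")
}

#' @export
print.scenefam_volcano <- function(x, ...) {
  cat(sprintf("<scenefam_volcano> %d x %d surround @ %.2f m spacing, max %g\n",
              nrow(x$surface), ncol(x$surface), x$spacing_m,
              max(x$surface, na.rm = TRUE)))
  invisible(x)
}

#' Rotational image difference function (RIDF)
#'
#' The view at `at` is processed at each rotation (0 to 360 degrees in
#' `cfg$rotation_increment_deg` steps) and scored against a stored view. The
#' rotation minimizing the difference recovers the stored view's bearing — a
#' "visual compass". Ties break to the smallest angle.
#'
#' @param land A [landscape()] object.
#' @param at Position of the current view.
#' @param stored A stored [process_view()] view.
#' @param cfg A [sensor_config()].
#' @return Object of class `scenefam_ridf`: `angles_deg`, `scores`,
#'   `best_angle_deg`, `best_score`.
#' @export
ridf <- function(land, at, stored, cfg) {
  stopifnot(inherits(stored, "scenefam_view"))
  angles <- seq(0, 360 - cfg$rotation_increment_deg,
                by = cfg$rotation_increment_deg)
  if (cfg$equalize_after_downsample) {
    scores <- vapply(angles, function(th) {
      image_difference(stored, process_view(land, at, th, cfg))
    }, numeric(1))
  } else {
    if (stored$cfg$out_res != cfg$out_res ||
        stored$cfg$gray_levels != cfg$gray_levels)
      stop("stored view and sensor configuration do not match")
    crop <- crop_window(land, at, cfg$window_px)
    scores <- cpp_scan_rotations(crop, angles, matrix(stored$v, nrow = 1),
                                 cached_mask(cfg$out_res), cfg$out_res,
                                 cfg$gray_levels, cfg$equalize)$min_score
  }
  i <- which.min(scores)
  structure(
    list(angles_deg = angles, scores = scores,
         best_angle_deg = angles[i], best_score = scores[i]),
    class = "scenefam_ridf")
}

#' @export
print.scenefam_ridf <- function(x, ...) {
  cat(sprintf("<scenefam_ridf> %d rotations, best %.0f deg (score %g)\n",
              length(x$angles_deg), x$best_angle_deg, x$best_score))
  invisible(x)
}

#' p50 catchment summary of a volcano surface
#'
#' The four cardinal half-slices (N, S, E, W from the center) are averaged
#' into one difference-vs-distance curve; the p50 point is where that curve
#' first reaches 50% of its maximum, located by linear interpolation between
#' samples. Reported as the difference value and the ground distance in
#' meters. A flat (all-zero) surface carries no information and yields the
#' `no_information` sentinel instead of an error.
#'
#' @param volc A [volcano()] object (or any list with `surface` and
#'   `spacing_m`), with odd side of at least 3.
#' @return Object of class `scenefam_p50`: `p50_difference`, `p50_distance_m`,
#'   `curve`, `distances_m`, `no_information`.
#' @export
p50_summary <- function(volc) {
  surf <- volc$surface
  side <- nrow(surf)
  if (side < 3L || side %% 2L == 0L || ncol(surf) != side)
    stop("volcano surface must be square with odd side of at least 3")
  k <- (side - 1L) %/% 2L
  ctr <- k + 1L
  slices <- rbind(surf[ctr - (0:k), ctr],   # north
                  surf[ctr + (0:k), ctr],   # south
                  surf[ctr, ctr + (0:k)],   # east
                  surf[ctr, ctr - (0:k)])   # west
  curve <- colMeans(slices, na.rm = TRUE)
  dists <- (0:k) * volc$spacing_m
  m <- max(curve, na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    return(structure(
      list(p50_difference = NA_real_, p50_distance_m = NA_real_,
           curve = curve, distances_m = dists, no_information = TRUE),
      class = "scenefam_p50"))
  }
  half <- m / 2
  i <- which(curve >= half)[1]
  if (i == 1L) {
    d50 <- dists[1]
  } else {
    c0 <- curve[i - 1L]; c1 <- curve[i]
    d50 <- dists[i - 1L] + (half - c0) / (c1 - c0) * (dists[i] - dists[i - 1L])
  }
  structure(
    list(p50_difference = half, p50_distance_m = d50,
         curve = curve, distances_m = dists, no_information = FALSE),
    class = "scenefam_p50")
}

#' @export
print.scenefam_p50 <- function(x, ...) {
  if (x$no_information) {
    cat("<scenefam_p50> flat surface: no information\n")
  } else {
    cat(sprintf("<scenefam_p50> difference %.1f at %.2f m\n",
                x$p50_difference, x$p50_distance_m))
  }
  invisible(x)
}

#' Region-averaged volcano, RIDF and p50 statistics
#'
#' Computes volcano surfaces and RIDF curves at several evenly spaced focal
#' scenes of a landscape-wide sample grid (by default the five at grid
#' fractions (1/4, 1/4), (1/4, 3/4), (1/2, 1/2), (3/4, 1/4), (3/4, 3/4)),
#' averages them element-wise, and summarizes the averaged volcano by its p50
#' point. This is the landscape-information comparator used to rank
#' environments and sensor designs.
#'
#' @param land A [landscape()] object.
#' @param cfg A [sensor_config()].
#' @param grid_rows,grid_cols Dimensions of the landscape-wide sample grid.
#' @param k Volcano surround half-width in grid steps.
#' @param focal_fracs Two-column matrix of (row, col) grid fractions for the
#'   focal scenes.
#' @return List with `volcano` (averaged `scenefam_volcano`), `ridf`
#'   (averaged `scenefam_ridf`), `p50` ([p50_summary()] of the average),
#'   `focal_positions`.
#' @export
averaged_region_stats <- function(land, cfg, grid_rows = 100,
                                  grid_cols = grid_rows, k = 10,
                                  focal_fracs = cbind(
                                    c(0.25, 0.25, 0.50, 0.75, 0.75),
                                    c(0.25, 0.75, 0.50, 0.25, 0.75))) {
  grid <- sample_grid(land, grid_rows, grid_cols, cfg$window_px)
  spacing <- mean(grid$spacing_px)
  idx_r <- pmax(1L, pmin(grid_rows, round(focal_fracs[, 1] * grid_rows)))
  idx_c <- pmax(1L, pmin(grid_cols, round(focal_fracs[, 2] * grid_cols)))
  focals <- t(vapply(seq_len(nrow(focal_fracs)), function(i) {
    grid$positions[(idx_r[i] - 1L) * grid_cols + idx_c[i], ]
  }, numeric(2)))
  surfs <- NULL
  curves <- NULL
  for (i in seq_len(nrow(focals))) {
    focal <- focals[i, ]
    vol <- volcano(land, focal, k, cfg, spacing)
    rid <- ridf(land, focal, process_view(land, focal, 0, cfg), cfg)
    if (is.null(surfs)) {
      surfs <- vol$surface
      curves <- rid$scores
      angles <- rid$angles_deg
    } else {
      surfs <- surfs + vol$surface
      curves <- curves + rid$scores
    }
  }
  n <- nrow(focals)
  avg_vol <- structure(
    list(surface = surfs / n, focal = NA, k = as.integer(k),
         spacing_px = spacing, spacing_m = spacing * land$meters_per_pixel),
    class = "scenefam_volcano")
  j <- which.min(curves)
  avg_ridf <- structure(
    list(angles_deg = angles, scores = curves / n,
         best_angle_deg = angles[j], best_score = curves[j] / n),
    class = "scenefam_ridf")
  list(volcano = avg_vol, ridf = avg_ridf, p50 = p50_summary(avg_vol),
       focal_positions = focals)
}
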