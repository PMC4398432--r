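#' @export
plot.scenefam_landscape <- function(x, ...) {
  op <- graphics::par(mar = c(2, 2, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(t(x$raster)[, x$height_px:1], col = grDevices::gray.colors(256, 0, 1),
                  zlim = c(0, 255), axes = FALSE, asp = 1, ...)
}

#' @export
plot.scenefam_diffmap <- function(x, ...) {
  graphics::image(t(x$grid)[, nrow(x$grid):1],
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, asp = 1,
                  main = "image-difference topography", ...)
}

#' @export
plot.scenefam_volcano <- function(x, ...) {
  graphics::image(t(x$surface)[, nrow(x$surface):1],
                  col = grDevices::hcl.colors(64, "inferno"),
                  axes = FALSE, asp = 1, main = "familiarity volcano", ...)
}

#' @export
plot.scenefam_ridf <- function(x, ...) {
  graphics::plot(x$angles_deg, x$scores, type = "l",
                 xlab = "rotation (deg)", ylab = "image difference",
                 main = "RIDF", ...)
  graphics::abline(v = x$best_angle_deg, lty = 2)
}

#' Overlay a retraced path on its training route
#'
#' @param x A [recapitulate()] result.
#' @param route The training route.
#' @param land Optional landscape drawn underneath.
#' @param ... Passed to the underlying plot.
#' @export
plot.scenefam_recap <- function(x, route = NULL, land = NULL, ...) {
  if (!is.null(land)) {
    plot(land, ...)
    sc <- function(p) cbind((p[, 2] - 1) / (land$width_px - 1),
                            1 - (p[, 1] - 1) / (land$height_px - 1))
    if (!is.null(route))
      graphics::lines(sc(route$path_points), col = "yellow", lwd = 2)
    graphics::lines(sc(x$path), col = "red", lwd = 2)
  } else {
    graphics::plot(x$path[, 2], -x$path[, 1], type = "l", col = "red",
                   asp = 1, xlab = "col", ylab = "-row", ...)
    if (!is.null(route))
      graphics::lines(route$path_points[, 2], -route$path_points[, 1],
                      col = "goldenrod")
  }
  invisible(x)
}

#' Export a matrix-valued result as CSV
#'
#' Writes [difference_topography()] grids, [volcano()] surfaces, or
#' [ridf()] curves (as angle,score columns) to a plain CSV file.
#'
#' @param x A `scenefam_diffmap`, `scenefam_volcano` or `scenefam_ridf`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  if (inherits(x, "scenefam_diffmap")) {
    utils::write.table(x$grid, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (inherits(x, "scenefam_volcano")) {
    utils::write.table(x$surface, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (inherits(x, "scenefam_ridf")) {
    utils::write.csv(data.frame(angle_deg = x$angles_deg, score = x$scores),
                     path, row.names = FALSE)
  } else {
    stop("no CSV writer for this object")
  }
  invisible(path)
}
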