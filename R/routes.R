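#' Compass bearing between two positions
#'
#' Bearings use a 360-degree compass with north = 0, increasing clockwise.
#' In raster coordinates north is decreasing row and east is increasing
#' column, so the bearing of a displacement `(drow, dcol)` is
#' `atan2(dcol, -drow)` converted to degrees in \[0, 360).
#'
#' @param p_from,p_to Distinct positions ([position()]).
#' @return Bearing in degrees.
#' @export
bearing <- function(p_from, p_to) {
  dr <- unname(p_to[1] - p_from[1])
  dc <- unname(p_to[2] - p_from[2])
  if (dr == 0 && dc == 0) stop("bearing is undefined for identical points")
  (atan2(dc, -dr) * 180 / pi) %% 360
}

# unit displacement (drow, dcol) of a bearing in degrees
bearing_step <- function(bearing_deg) {
  th <- bearing_deg * pi / 180
  c(-cos(th), sin(th))
}

#' Training waypoints
#'
#' An ordered list of user-selected route points. At least two points are
#' required and consecutive points must be distinct.
#'
#' @param x Two-column matrix or data frame of (row, col) pixel coordinates.
#' @return Object of class `scenefam_waypoints` (an n x 2 matrix).
#' @export
waypoints <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2L || nrow(x) < 2L)
    stop("waypoints must be an n x 2 matrix with at least 2 points")
  if (any(!is.finite(x))) stop("waypoints must be finite")
  d <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE])^2))
  if (any(d == 0)) stop("consecutive waypoints must be distinct")
  colnames(x) <- c("row", "col")
  structure(x, class = c("scenefam_waypoints", "matrix", "array"))
}

#' Read waypoints from a CSV file with columns row,col
#'
#' @param path CSV file path.
#' @return A [waypoints()] object.
#' @export
read_waypoints_csv <- function(path) {
  waypoints(utils::read.csv(path)[, c("row", "col")])
}

#' Interpolate a dense training path through waypoints
#'
#' Points are placed at `spacing_px` intervals along each straight segment
#' (the segment start included; the final waypoint closes the path). Each
#' point carries its segment's compass bearing; a corner waypoint takes the
#' outgoing segment's bearing, the view an agent faces when departing the
#' corner.
#'
#' @param wp A [waypoints()] object.
#' @param spacing_px Spacing between successive path points, pixels.
#' @return Object of class `scenefam_route`: `path_points` (m x 2 matrix),
#'   `bearings_deg`, `spacing_px`, `waypoints`; corridor fields are `NULL`
#'   until [widen_corridor()] is applied.
#' @export
interpolate_path <- function(wp, spacing_px) {
  stopifnot(inherits(wp, "scenefam_waypoints"))
  if (spacing_px <= 0) stop("`spacing_px` must be positive")
  pts <- NULL
  brg <- NULL
  n_seg <- nrow(wp) - 1L
  for (s in seq_len(n_seg)) {
    a <- wp[s, ]; b <- wp[s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    beta <- bearing(a, b)
    t_along <- seq(0, len - 1e-9, by = spacing_px)
    seg <- cbind(a[1] + t_along / len * (b[1] - a[1]),
                 a[2] + t_along / len * (b[2] - a[2]))
    pts <- rbind(pts, seg)
    brg <- c(brg, rep(beta, nrow(seg)))
  }
  pts <- rbind(pts, wp[nrow(wp), , drop = FALSE])
  brg <- c(brg, brg[length(brg)])
  colnames(pts) <- c("row", "col")
  rownames(pts) <- NULL
  structure(
    list(path_points = pts, bearings_deg = brg, spacing_px = spacing_px,
         waypoints = wp, corridor_points = NULL, corridor_bearings = NULL),
    class = "scenefam_route")
}

#' @export
print.scenefam_route <- function(x, ...) {
  cat(sprintf("<scenefam_route> %d path points @ %.1f px%s\n",
              nrow(x$path_points), x$spacing_px,
              if (is.null(x$corridor_points)) ""
              else sprintf(", corridor of %d points",
                           nrow(x$corridor_points))))
  invisible(x)
}

#' Widen a training route into a corridor
#'
#' For each path point, two additional points are added one scene spacing to
#' each side, perpendicular to the point's travel bearing, carrying the same
#' bearing. If a landscape is supplied, offset points whose sensor window
#' would overrun the raster are dropped with a message.
#'
#' @param route A [interpolate_path()] route.
#' @param spacing_px Lateral offset, pixels (default: the route's own path
#'   spacing).
#' @param land Optional [landscape()] used to drop non-croppable offsets.
#' @param window_px Window side used for the croppability check.
#' @return The route with `corridor_points` and `corridor_bearings` filled;
#'   corridor order is (center, left, right) per path point.
#' @export
widen_corridor <- function(route, spacing_px = route$spacing_px,
                           land = NULL, window_px = NULL) {
  stopifnot(inherits(route, "scenefam_route"))
  n <- nrow(route$path_points)
  pts <- matrix(NA_real_, 3L * n, 2L)
  brg <- numeric(3L * n)
  for (i in seq_len(n)) {
    p <- route$path_points[i, ]
    beta <- route$bearings_deg[i]
    perp <- bearing_step(beta + 90) * spacing_px
    pts[3L * i - 2L, ] <- p
    pts[3L * i - 1L, ] <- p - perp
    pts[3L * i, ] <- p + perp
    brg[(3L * i - 2L):(3L * i)] <- beta
  }
  if (!is.null(land)) {
    if (is.null(window_px)) stop("`window_px` is required with a landscape")
    keep <- vapply(seq_len(nrow(pts)), function(i) {
      is_croppable(land, pts[i, ], window_px)
    }, logical(1))
    if (any(!keep))
      message(sum(!keep), " corridor point(s) dropped at the landscape boundary")
    pts <- pts[keep, , drop = FALSE]
    brg <- brg[keep]
  }
  colnames(pts) <- c("row", "col")
  route$corridor_points <- pts
  route$corridor_bearings <- brg
  route
}

#' Build the memory bank of a training route
#'
#' Simulates what the agent sees along the route: each corridor point's scene
#' is processed at that point's travel bearing and stored, in order. During
#' recapitulation the bank is addressed only by familiarity — no sequence or
#' position information is ever read back.
#'
#' @param land A [landscape()] object.
#' @param route A route; if it has no corridor, the path points are used.
#' @param cfg A [sensor_config()].
#' @return Object of class `scenefam_memory`: `views` (list of views), `V`
#'   (n_views x n_masked_pixels matrix), `positions`, `bearings_deg`, `cfg`,
#'   `goal` (last path point), `spacing_m`, `route_length_m`.
#' @export
build_memory <- function(land, route, cfg) {
  stopifnot(inherits(route, "scenefam_route"), inherits(cfg, "scenefam_sensor"))
  pts <- if (is.null(route$corridor_points)) route$path_points else
    route$corridor_points
  brg <- if (is.null(route$corridor_points)) route$bearings_deg else
    route$corridor_bearings
  views <- vector("list", nrow(pts))
  mask <- circular_mask(cfg$out_res)
  V <- matrix(0, nrow(pts), sum(mask))
  for (i in seq_len(nrow(pts))) {
    views[[i]] <- process_view(land, pts[i, ], brg[i], cfg)
    V[i, ] <- views[[i]]$v
  }
  seg <- diff(route$path_points)
  structure(
    list(views = views, V = V, positions = pts, bearings_deg = brg,
         cfg = cfg, goal = route$path_points[nrow(route$path_points), ],
         spacing_m = route$spacing_px * land$meters_per_pixel,
         route_length_m = sum(sqrt(rowSums(seg^2))) * land$meters_per_pixel),
    class = "scenefam_memory")
}

#' @export
print.scenefam_memory <- function(x, ...) {
  cat(sprintf("<scenefam_memory> %d stored views (%d px each), route %.0f m\n",
              nrow(x$V), ncol(x$V), x$route_length_m))
  invisible(x)
}

#' Persist or restore a memory bank
#'
#' Training and recapitulation can run as separate invocations; the bank is
#' stored as a single RDS file.
#'
#' @param memory A [build_memory()] bank.
#' @param path File path.
#' @return `save_memory` returns `path` invisibly; `load_memory` the bank.
#' @export
save_memory <- function(memory, path) {
  stopifnot(inherits(memory, "scenefam_memory"))
  saveRDS(memory, path)
  invisible(path)
}

#' @rdname save_memory
#' @export
load_memory <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "scenefam_memory")) stop("not a scenefam memory bank")
  m
}
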