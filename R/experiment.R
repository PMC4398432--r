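#' Specification of a sensor-sweep navigation experiment
#'
#' Crosses sensor resolutions, pixel depths, landscape regimes and seeds, and
#' runs one train-and-recapitulate cycle per cell.
#'
#' @param resolutions Sensor sides to sweep (default 10, 20, 40, 80).
#' @param gray_depths Pixel depths to sweep (default 2, 10, 100).
#' @param regimes Landscape regimes (default all three).
#' @param seeds Integer seeds; one landscape/route per regime x seed.
#' @param route_shape Shape passed to [make_route()].
#' @param size_px,meters_per_pixel Landscape geometry.
#' @param window_px Raw sensor window, pixels.
#' @param equalize Histogram equalization on or off.
#' @param mem_spacing_px Training path spacing, pixels.
#' @param agent An [agent_config()].
#' @param max_cells Safety cap on the size of the cartesian product.
#' @return Object of class `scenefam_experiment`.
#' @export
experiment_spec <- function(resolutions = c(10, 20, 40, 80),
                            gray_depths = c(2, 10, 100),
                            regimes = c("low", "medium", "high"),
                            seeds = 1L, route_shape = "s_curve",
                            size_px = 600, meters_per_pixel = 1,
                            window_px = 80, equalize = TRUE,
                            mem_spacing_px = 5,
                            agent = agent_config(max_steps = 60),
                            max_cells = 500) {
  if (!length(resolutions) || !length(gray_depths) || !length(regimes) ||
      !length(seeds))
    stop("all sweep lists must be non-empty")
  n_cells <- length(resolutions) * length(gray_depths) * length(regimes) *
    length(seeds)
  if (n_cells > max_cells)
    stop(n_cells, " cells exceed `max_cells` = ", max_cells)
  structure(
    list(resolutions = resolutions, gray_depths = gray_depths,
         regimes = regimes, seeds = as.integer(seeds),
         route_shape = route_shape, size_px = size_px,
         meters_per_pixel = meters_per_pixel, window_px = window_px,
         equalize = isTRUE(equalize), mem_spacing_px = mem_spacing_px,
         agent = agent),
    class = "scenefam_experiment")
}

#' Run a sensor-sweep navigation experiment
#'
#' For every (regime, seed) a landscape and training route are generated; for
#' every (resolution, depth) a memory bank is trained and the route is
#' recapitulated from its start. Each cell yields one result row; a cell that
#' errors is recorded as a row with outcome `"error"` rather than aborting
#' the sweep.
#'
#' @param spec An [experiment_spec()].
#' @return Data frame with one row per cell: regime, seed, resolution,
#'   gray_levels, equalize, outcome, steps, departure_m,
#'   departure_per_step_m, samples_evaluated, success.
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "scenefam_experiment"))
  rows <- list()
  for (regime in spec$regimes) {
    for (seed in spec$seeds) {
      land <- make_landscape(terrain_spec(
        regime, size_px = spec$size_px,
        meters_per_pixel = spec$meters_per_pixel, seed = seed))
      wp <- make_route(spec$route_shape, land, window_px = spec$window_px)
      route <- interpolate_path(wp, spec$mem_spacing_px)
      route <- widen_corridor(route, land = land, window_px = spec$window_px)
      for (res in spec$resolutions) {
        for (g in spec$gray_depths) {
          row <- tryCatch({
            cfg <- sensor_config(window_px = spec$window_px, out_res = res,
                                 gray_levels = g, equalize = spec$equalize)
            memory <- build_memory(land, route, cfg)
            rec <- recapitulate(land, route$path_points[1, ], memory,
                                spec$agent)
            n_steps <- nrow(rec$steps)
            dep <- if (n_steps > 0)
              departure_metric(rec, route, spec$meters_per_pixel) else 0
            dps <- if (n_steps > 0) dep / n_steps else 0
            data.frame(
              regime = regime, seed = seed, resolution = res,
              gray_levels = g, equalize = spec$equalize,
              outcome = rec$outcome, steps = n_steps, departure_m = dep,
              departure_per_step_m = dps,
              samples_evaluated = sum(rec$steps$n_samples),
              success = rec$outcome == "reached_goal")
          }, error = function(e) {
            data.frame(
              regime = regime, seed = seed, resolution = res,
              gray_levels = g, equalize = spec$equalize,
              outcome = "error", steps = NA_integer_,
              departure_m = NA_real_, departure_per_step_m = NA_real_,
              samples_evaluated = NA_integer_, success = FALSE)
          })
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Success matrix of an experiment table
#'
#' @param results A [run_experiment()] table.
#' @return Data frame of success rates by regime, resolution and depth.
#' @export
summarize_experiment <- function(results) {
  agg <- stats::aggregate(success ~ regime + resolution + gray_levels,
                          data = results, FUN = mean)
  names(agg)[names(agg) == "success"] <- "success_rate"
  agg[order(agg$regime, agg$resolution, agg$gray_levels), ]
}
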