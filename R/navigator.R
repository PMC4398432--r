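#' Agent configuration for route recapitulation
#'
#' The agent advances by scanning an arc of candidate positions ahead of its
#' current heading, matching each candidate's view against the whole memory
#' bank over all rotations, and moving to the first candidate familiar enough
#' (or the most familiar one if none meets the threshold).
#'
#' @param arc_span_m Ground span of the scan arc, meters (default 40).
#' @param arc_radius_m Step length = arc radius, meters (default
#'   `arc_span_m / 2`).
#' @param arc_angle_step_deg Angular spacing of arc samples (default 10).
#' @param arc_half_extent_deg Maximum deviation from the current heading
#'   (default 90).
#' @param rotation_increment_deg Rotation step while matching (default 10; use
#'   1 for full fidelity at ~10x the cost).
#' @param threshold_frac Familiarity threshold as a fraction of the mean of
#'   all rotation-by-memory difference values at a sample point
#'   (default 0.20). A sample meets the threshold when its best score is at
#'   most `threshold_frac * mean`.
#' @param goal_radius_m Distance to the training path's end that counts as
#'   arrival (default: one arc radius, i.e. one step length — the agent
#'   advances in `arc_radius_m` jumps, so a tighter disc could be stepped
#'   over even on a perfect retrace).
#' @param max_steps Hard cap on steps (default: 10 x route length /
#'   arc radius, resolved at run time).
#' @return Object of class `scenefam_agent`.
#' @export
agent_config <- function(arc_span_m = 40, arc_radius_m = arc_span_m / 2,
                         arc_angle_step_deg = 10, arc_half_extent_deg = 90,
                         rotation_increment_deg = 10, threshold_frac = 0.20,
                         goal_radius_m = NULL, max_steps = NULL) {
  if (arc_span_m <= 0 || arc_radius_m <= 0 || arc_angle_step_deg <= 0 ||
      arc_half_extent_deg <= 0 || rotation_increment_deg <= 0)
    stop("arc and rotation parameters must be positive")
  if (threshold_frac <= 0 || threshold_frac > 1)
    stop("`threshold_frac` must lie in (0, 1]")
  structure(
    list(arc_span_m = arc_span_m, arc_radius_m = arc_radius_m,
         arc_angle_step_deg = arc_angle_step_deg,
         arc_half_extent_deg = arc_half_extent_deg,
         rotation_increment_deg = rotation_increment_deg,
         threshold_frac = threshold_frac,
         goal_radius_m = goal_radius_m, max_steps = max_steps),
    class = "scenefam_agent")
}

#' Match the view at a position against the whole memory bank
#'
#' The current scene is processed at every rotation (0 to 360 degrees in
#' `rotation_increment_deg` steps) and each rotation is scored against every
#' stored memory view. The minimum over rotations x memories gives the best
#' score, heading and memory index; ties break to the smaller angle, then the
#' earlier memory index. The mean over all comparisons supports the
#' familiarity threshold.
#'
#' @param land A [landscape()] object.
#' @param at Position to evaluate.
#' @param memory A [build_memory()] bank.
#' @param agent_cfg An [agent_config()].
#' @return Object of class `scenefam_scan`: `position`, `best_score`,
#'   `best_heading_deg`, `best_memory_index`, `mean_score`, `n_comparisons`,
#'   `threshold`, `met_threshold`.
#' @export
match_against_memory <- function(land, at, memory, agent_cfg = agent_config()) {
  stopifnot(inherits(memory, "scenefam_memory"))
  if (nrow(memory$V) == 0L) stop("memory bank is empty")
  cfg <- memory$cfg
  angles <- seq(0, 360 - agent_cfg$rotation_increment_deg,
                by = agent_cfg$rotation_increment_deg)
  if (cfg$equalize_after_downsample) {
    # general (slower) path through the R pipeline
    best <- Inf; best_angle <- 0; best_index <- 1L; total <- 0
    for (th in angles) {
      v <- process_view(land, at, th, cfg)$v
      sc <- cpp_absdiff_rowsums(memory$V, v)
      total <- total + sum(sc)
      i <- which.min(sc)
      if (sc[i] < best) {
        best <- sc[i]; best_angle <- th; best_index <- i
      }
    }
  } else {
    crop <- crop_window(land, at, cfg$window_px)
    res <- cpp_scan_rotations(crop, angles, memory$V, cached_mask(cfg$out_res),
                              cfg$out_res, cfg$gray_levels, cfg$equalize)
    i <- which.min(res$min_score)
    best <- res$min_score[i]
    best_angle <- angles[i]
    best_index <- res$min_index[i]
    total <- res$total
  }
  n_cmp <- length(angles) * nrow(memory$V)
  thr <- agent_cfg$threshold_frac * total / n_cmp
  structure(
    list(position = c(row = as.numeric(at[1]), col = as.numeric(at[2])),
         best_score = best, best_heading_deg = best_angle,
         best_memory_index = best_index, mean_score = total / n_cmp,
         n_comparisons = n_cmp, threshold = thr,
         met_threshold = best <= thr),
    class = "scenefam_scan")
}

#' @export
print.scenefam_scan <- function(x, ...) {
  cat(sprintf("<scenefam_scan> best %g @ %.0f deg (memory %d), threshold %g%s\n",
              x$best_score, x$best_heading_deg, x$best_memory_index,
              x$threshold, if (x$met_threshold) " [met]" else ""))
  invisible(x)
}

#' Familiarity threshold at a position
#'
#' `threshold_frac` times the mean of all rotation-by-memory difference
#' values at the position; a sample is familiar enough when its best score
#' does not exceed this.
#'
#' @inheritParams match_against_memory
#' @return Single number.
#' @export
familiarity_threshold <- function(land, at, memory,
                                  agent_cfg = agent_config()) {
  match_against_memory(land, at, memory, agent_cfg)$threshold
}

#' Heading of the most familiar scene at the start position
#'
#' @inheritParams match_against_memory
#' @param start Release position.
#' @return Bearing in degrees.
#' @export
initial_heading <- function(land, start, memory, agent_cfg = agent_config()) {
  match_against_memory(land, start, memory, agent_cfg)$best_heading_deg
}

arc_offsets <- function(step_deg, half_extent_deg) {
  ks <- seq_len(floor(half_extent_deg / step_deg))
  c(0, as.vector(rbind(ks * step_deg, -ks * step_deg)))
}

#' One arc scan: choose the agent's next position
#'
#' Candidate positions lie on an arc of radius `arc_radius_m` ahead of the
#' current heading, sampled at offsets 0, +s, -s, +2s, -2s, ... up to the
#' half-extent. Each candidate is matched against the full memory bank; the
#' first candidate meeting its familiarity threshold is taken immediately and
#' no further arc points are sampled. If none meets it, the candidate with
#' the globally smallest best score is taken. Candidates whose sensor window
#' leaves the landscape are skipped; if every candidate is off the landscape
#' the scan fails.
#'
#' @inheritParams match_against_memory
#' @param current Current position.
#' @param heading_deg Current travel heading (degrees, north = 0).
#' @return List: `position` (chosen next position or `NULL`), `sample` (its
#'   `scenefam_scan`), `chosen_offset_deg`, `n_samples` evaluated,
#'   `met_threshold`, `offsets_evaluated`, `off_landscape`.
#' @export
arc_scan <- function(land, current, heading_deg, memory,
                     agent_cfg = agent_config()) {
  offs <- arc_offsets(agent_cfg$arc_angle_step_deg,
                      agent_cfg$arc_half_extent_deg)
  radius_px <- agent_cfg$arc_radius_m / land$meters_per_pixel
  best_sample <- NULL
  best_pos <- NULL
  best_off <- NA_real_
  evaluated <- numeric(0)
  for (off in offs) {
    p <- current + bearing_step(heading_deg + off) * radius_px
    if (!is_croppable(land, p, memory$cfg$window_px)) next
    smp <- match_against_memory(land, p, memory, agent_cfg)
    evaluated <- c(evaluated, off)
    if (smp$met_threshold) {
      return(list(position = p, sample = smp, chosen_offset_deg = off,
                  n_samples = length(evaluated), met_threshold = TRUE,
                  offsets_evaluated = evaluated, off_landscape = FALSE))
    }
    if (is.null(best_sample) || smp$best_score < best_sample$best_score) {
      best_sample <- smp
      best_pos <- p
      best_off <- off
    }
  }
  if (is.null(best_sample)) {
    return(list(position = NULL, sample = NULL, chosen_offset_deg = NA_real_,
                n_samples = 0L, met_threshold = FALSE,
                offsets_evaluated = evaluated, off_landscape = TRUE))
  }
  list(position = best_pos, sample = best_sample, chosen_offset_deg = best_off,
       n_samples = length(evaluated), met_threshold = FALSE,
       offsets_evaluated = evaluated, off_landscape = FALSE)
}

#' Recapitulate a learned route by scene familiarity
#'
#' From a release position near the route start, the agent takes its first
#' scan direction from the most familiar scene there, then repeatedly arc-scans
#' and moves. Each new scan is cast along the forward extension of the
#' previous chosen chord, giving the agent forward momentum across crossing
#' paths. The run ends when the agent comes within `goal_radius_m` of the
#' training path's end (`reached_goal`), every arc candidate leaves the
#' landscape (`off_landscape`), or `max_steps` is exhausted (`max_steps`).
#'
#' @inheritParams match_against_memory
#' @param start Release position.
#' @return Object of class `scenefam_recap`: `steps` (data frame with step,
#'   row, col, heading_deg, best_score, n_samples, met_threshold), `outcome`,
#'   `path` (positions including the start), `start`, `goal`.
#' @export
recapitulate <- function(land, start, memory, agent_cfg = agent_config()) {
  stopifnot(inherits(memory, "scenefam_memory"))
  goal_radius <- agent_cfg$goal_radius_m
  if (is.null(goal_radius)) goal_radius <- agent_cfg$arc_radius_m
  max_steps <- agent_cfg$max_steps
  if (is.null(max_steps))
    max_steps <- ceiling(10 * memory$route_length_m / agent_cfg$arc_radius_m)
  mpp <- land$meters_per_pixel
  dist_to_goal <- function(p) sqrt(sum((p - memory$goal)^2)) * mpp

  steps <- list()
  current <- c(row = as.numeric(start[1]), col = as.numeric(start[2]))
  path <- matrix(current, 1L, 2L, dimnames = list(NULL, c("row", "col")))
  outcome <- "max_steps"
  if (dist_to_goal(current) <= goal_radius) {
    outcome <- "reached_goal"
    max_steps <- 0L
  } else {
    heading <- initial_heading(land, current, memory, agent_cfg)
  }
  step <- 0L
  while (step < max_steps) {
    step <- step + 1L
    scan <- arc_scan(land, current, heading, memory, agent_cfg)
    if (scan$off_landscape) {
      outcome <- "off_landscape"
      break
    }
    heading <- bearing(current, scan$position)
    current <- c(row = unname(scan$position[1]),
                 col = unname(scan$position[2]))
    path <- rbind(path, current, deparse.level = 0)
    steps[[step]] <- data.frame(
      step = step, row = current[1], col = current[2],
      heading_deg = heading, best_score = scan$sample$best_score,
      n_samples = scan$n_samples, met_threshold = scan$met_threshold)
    if (dist_to_goal(current) <= goal_radius) {
      outcome <- "reached_goal"
      break
    }
  }
  structure(
    list(steps = if (length(steps)) do.call(rbind, steps) else
           data.frame(step = integer(), row = numeric(), col = numeric(),
                      heading_deg = numeric(), best_score = numeric(),
                      n_samples = integer(), met_threshold = logical()),
         outcome = outcome, path = path,
         start = c(row = as.numeric(start[1]), col = as.numeric(start[2])),
         goal = memory$goal),
    class = "scenefam_recap")
}

#' @export
print.scenefam_recap <- function(x, ...) {
  cat(sprintf("<scenefam_recap> %s after %d step(s)\n",
              x$outcome, nrow(x$steps)))
  invisible(x)
}

# point at arc-length fraction f along a polyline (m x 2 matrix)
polyline_point <- function(pts, f) {
  seg <- diff(pts)
  lens <- sqrt(rowSums(seg^2))
  total <- sum(lens)
  if (total == 0) return(pts[1, ])
  target <- f * total
  cum <- c(0, cumsum(lens))
  i <- findInterval(target, cum, rightmost.closed = TRUE)
  i <- max(1L, min(i, nrow(seg)))
  t_in <- (target - cum[i]) / lens[i]
  pts[i, ] + t_in * seg[i, ]
}

#' Cumulative departure of a retraced path from its training route
#'
#' Each chosen step point is paired with the training-path point at the same
#' arc-length fraction (a monotone, in-sequence mapping); the geometric
#' distances of all pairs are summed and reported in meters.
#'
#' @param result A [recapitulate()] result with at least one step.
#' @param route The training [interpolate_path()] route.
#' @param meters_per_pixel Ground scale of the landscape the paths live on.
#' @return Summed departure in meters.
#' @export
departure_metric <- function(result, route, meters_per_pixel) {
  stopifnot(inherits(result, "scenefam_recap"),
            inherits(route, "scenefam_route"))
  n <- nrow(result$steps)
  if (n == 0L) stop("recapitulation result has no steps")
  if (nrow(route$path_points) < 2L) stop("route has no extent")
  retraced <- result$path
  seg <- diff(retraced)
  cum <- c(0, cumsum(sqrt(rowSums(seg^2))))
  total <- cum[length(cum)]
  fracs <- if (total == 0) rep(1, n) else cum[-1] / total
  sum(vapply(seq_len(n), function(i) {
    ref <- polyline_point(route$path_points, fracs[i])
    sqrt(sum((retraced[i + 1L, ] - ref)^2))
  }, numeric(1))) * meters_per_pixel
}
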