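test_that("memory matching finds the stored view and obeys tie rules", {
  fx <- small_memory()
  land <- fx$land; mem <- fx$memory; route <- fx$route
  acfg <- agent_config(rotation_increment_deg = 10)

  # standing exactly on a stored point whose bearing the increment divides:
  # perfect match with that bearing and index
  i <- 10
  expect_equal(mem$bearings_deg[i] %% 10, 0)  # straight east route
  s <- match_against_memory(land, mem$positions[i, ], mem, acfg)
  expect_equal(s$best_score, 0)
  expect_equal(s$best_heading_deg, mem$bearings_deg[i])
  expect_equal(s$best_memory_index, i)
  expect_true(s$met_threshold)

  # constant landscape: every comparison ties; smallest angle, first index win
  flat <- landscape(matrix(77, 150, 150), 1)
  wp <- waypoints(rbind(c(75, 40), c(75, 110)))
  route_f <- interpolate_path(wp, 10)
  mem_f <- build_memory(flat, route_f, fx$cfg)
  sf <- match_against_memory(flat, position(75, 75), mem_f, acfg)
  expect_equal(sf$best_heading_deg, 0)
  expect_equal(sf$best_memory_index, 1)
  expect_equal(sf$best_score, 0)
  expect_true(sf$met_threshold)  # zero mean -> zero threshold, met by zero

  # brute-force triple-loop oracle over rotations x memory views
  acfg_coarse <- agent_config(rotation_increment_deg = 45)
  set.seed(12)
  for (trial in 1:10) {
    at <- position(runif(1, 100, 200), runif(1, 100, 200))
    s <- match_against_memory(land, at, mem, acfg_coarse)
    best <- Inf; ba <- NA; bi <- NA; tot <- 0
    for (th in seq(0, 315, by = 45)) {
      v <- process_view(land, at, th, fx$cfg)
      for (m in seq_len(nrow(mem$V))) {
        d <- sum(abs(v$v - mem$V[m, ]))
        tot <- tot + d
        if (d < best) { best <- d; ba <- th; bi <- m }
      }
    }
    expect_equal(s$best_score, best)
    expect_equal(s$best_heading_deg, ba)
    expect_equal(s$best_memory_index, bi)
    expect_equal(s$mean_score, tot / (8 * nrow(mem$V)))
  }
})

test_that("the familiarity threshold is a fraction of the mean comparison score", {
  fx <- small_memory()
  acfg <- agent_config(rotation_increment_deg = 30, threshold_frac = 0.2)
  at <- position(170, 170)
  thr <- familiarity_threshold(fx$land, at, fx$memory, acfg)
  # independent accumulation pass
  tot <- 0; n <- 0
  for (th in seq(0, 330, by = 30)) {
    v <- process_view(fx$land, at, th, fx$cfg)
    for (m in seq_len(nrow(fx$memory$V))) {
      tot <- tot + sum(abs(v$v - fx$memory$V[m, ]))
      n <- n + 1
    }
  }
  expect_equal(thr, 0.2 * tot / n)
  expect_error(match_against_memory(fx$land, at,
                                    structure(list(V = matrix(0, 0, 3)),
                                              class = "scenefam_memory"),
                                    acfg),
               "empty")
})

test_that("the first scan heading points along the route at its start", {
  fx <- small_memory()
  h <- initial_heading(fx$land, fx$route$path_points[1, ], fx$memory,
                       agent_config(rotation_increment_deg = 10))
  expect_equal(h, fx$route$bearings_deg[1])
})

test_that("arc sampling alternates left and right and stops early", {
  fx <- small_memory()
  land <- fx$land; mem <- fx$memory

  # threshold_frac = 1: the first (straight-ahead) sample always meets it
  sc <- arc_scan(land, position(150, 100), 90, mem,
                 agent_config(threshold_frac = 1,
                              rotation_increment_deg = 30))
  expect_equal(sc$n_samples, 1)
  expect_equal(sc$chosen_offset_deg, 0)
  expect_true(sc$met_threshold)

  # a nearly unreachable threshold forces the full alternating sweep
  acfg <- agent_config(threshold_frac = 1e-9, rotation_increment_deg = 90,
                       arc_angle_step_deg = 15, arc_half_extent_deg = 60)
  sc2 <- arc_scan(land, position(157.3, 101.2), 90, mem, acfg)
  expect_equal(sc2$offsets_evaluated,
               c(0, 15, -15, 30, -30, 45, -45, 60, -60))
  expect_false(sc2$met_threshold)
  expect_equal(sc2$n_samples, 9)

  # off-landscape candidates are skipped; all-off yields the failure flag
  near_edge <- position(25, 150)  # arc at 20 px radius heading north leaves
  sc3 <- arc_scan(land, near_edge, 0, mem,
                  agent_config(threshold_frac = 1e-9))
  expect_true(all(abs(sc3$offsets_evaluated) >= 60))
  corner <- position(21, 21)
  sc4 <- arc_scan(land, corner, 315, mem, agent_config())
  expect_true(sc4$off_landscape)
})

test_that("recapitulation retraces a straight route and terminates properly", {
  fx <- small_memory()
  land <- fx$land; mem <- fx$memory; route <- fx$route
  acfg <- agent_config(max_steps = 30)

  rec <- recapitulate(land, route$path_points[1, ], mem, acfg)
  expect_equal(rec$outcome, "reached_goal")
  # 180 px route at 20 px steps: about 9 steps, allow detours up to 2x
  expect_lte(nrow(rec$steps), 18)
  expect_lt(departure_metric(rec, route, 1) / nrow(rec$steps),
            acfg$arc_radius_m)
  # consecutive headings never reverse more than the arc half-extent
  dh <- abs(((diff(rec$steps$heading_deg) + 180) %% 360) - 180)
  expect_true(all(dh <= 90 + 1e-9))
  # consecutive positions are one arc radius apart
  hops <- sqrt(rowSums(diff(rec$path)^2))
  expect_equal(hops, rep(20, length(hops)), tolerance = 1e-6)

  # releasing the agent at the goal ends immediately
  rec0 <- recapitulate(land, mem$goal, mem, acfg)
  expect_equal(rec0$outcome, "reached_goal")
  expect_equal(nrow(rec0$steps), 0)
})

test_that("memory trained on different terrain does not guide navigation", {
  # negative control: the bank comes from an independently seeded landscape
  fx <- small_memory()
  other <- make_landscape(terrain_spec("high", size_px = 300, seed = 99))
  acfg <- agent_config(max_steps = 12)
  fails <- 0
  for (s in 1:3) {
    start <- fx$route$path_points[1, ] + c(s, -s)
    rec <- recapitulate(other, start, fx$memory, acfg)
    ok <- rec$outcome == "reached_goal" &&
      departure_metric(rec, fx$route, 1) / nrow(rec$steps) < acfg$arc_radius_m
    if (!ok) fails <- fails + 1
  }
  expect_gte(fails, 2)
})

test_that("departure pairs step points with in-sequence training points", {
  fx <- small_memory()
  route <- fx$route

  # a synthetic result tracing the whole training path exactly departs by zero
  n_route <- nrow(route$path_points)
  pts <- route$path_points[seq(1, n_route, length.out = 5), ]
  mk_result <- function(path) {
    structure(list(
      steps = data.frame(step = seq_len(nrow(path) - 1)),
      path = path, outcome = "reached_goal"),
      class = "scenefam_recap")
  }
  expect_equal(departure_metric(mk_result(pts), route, 1), 0)

  # a uniform 5 px lateral offset on an equal-length straight retrace
  # departs by 5 m per step
  off <- cbind(pts[, 1] + 5, pts[, 2])
  expect_equal(departure_metric(mk_result(off), route, 1), 5 * 4)

  # brute-force arc-length-fraction pairing oracle on random retraces
  set.seed(13)
  for (trial in 1:20) {
    n_steps <- sample(3:8, 1)
    path <- cbind(150 + cumsum(stats::rnorm(n_steps + 1, 0, 4)),
                  seq(60, 240, length.out = n_steps + 1))
    got <- departure_metric(mk_result(path), route, 2)
    seg <- diff(path)
    cum <- c(0, cumsum(sqrt(rowSums(seg^2))))
    fr <- cum[-1] / max(cum)
    tr_seg <- diff(route$path_points)
    tr_cum <- c(0, cumsum(sqrt(rowSums(tr_seg^2))))
    oracle <- 0
    for (i in seq_len(n_steps)) {
      target <- fr[i] * max(tr_cum)
      j <- max(which(tr_cum <= target + 1e-12))
      j <- min(j, nrow(tr_seg))
      tloc <- (target - tr_cum[j]) / sqrt(sum(tr_seg[j, ]^2))
      ref <- route$path_points[j, ] + tloc * tr_seg[j, ]
      oracle <- oracle + sqrt(sum((path[i + 1, ] - ref)^2))
    }
    expect_equal(got, oracle * 2, tolerance = 1e-9)
  }
  expect_error(departure_metric(mk_result(route$path_points[1:2, ])[
    c("path", "outcome")], route, 1))
})

test_that("forward momentum carries the agent across its own crossing path", {
  land <- regime_landscape("high", 400, seed = 7)
  wp <- make_route("loop", land, window_px = 40)
  route <- widen_corridor(interpolate_path(wp, 5), land = land,
                          window_px = 40)
  cfg <- sensor_config(window_px = 40, out_res = 20, gray_levels = 10)
  mem <- build_memory(land, route, cfg)
  rec <- recapitulate(land, route$path_points[1, ], mem,
                      agent_config(max_steps = 80))
  # scan directions extend the previous chord, so consecutive headings can
  # never reverse by more than the arc half-extent, even at the crossing
  dh <- abs(((diff(rec$steps$heading_deg) + 180) %% 360) - 180)
  expect_true(all(dh <= 90 + 1e-9))
  expect_equal(rec$outcome, "reached_goal")
})

test_that("a stricter familiarity threshold never hurts on mixed terrain", {
  # half high-information texture, half near-featureless water
  mixed_land <- function(seed) {
    hi <- make_landscape(terrain_spec("high", size_px = 400, seed = seed))
    lo <- make_landscape(terrain_spec("low", size_px = 400,
                                      seed = seed + 1000))
    r <- hi$raster
    r[, 201:400] <- lo$raster[, 201:400]
    landscape(r, 1)
  }
  cfg <- sensor_config(window_px = 40, out_res = 20, gray_levels = 10)
  success <- function(seed, frac) {
    land <- mixed_land(seed)
    wp <- make_route("straight", land, window_px = 40)
    route <- widen_corridor(interpolate_path(wp, 5), land = land,
                            window_px = 40)
    mem <- build_memory(land, route, cfg)
    acfg <- agent_config(threshold_frac = frac, max_steps = 40)
    rec <- recapitulate(land, route$path_points[1, ], mem, acfg)
    rec$outcome == "reached_goal" &&
      departure_metric(rec, route, 1) / nrow(rec$steps) < acfg$arc_radius_m
  }
  seeds <- 1:6
  strict <- sum(sapply(seeds, success, frac = 0.1))
  lax <- sum(sapply(seeds, success, frac = 0.3))
  expect_gte(strict, lax)
  expect_gt(strict, 0)
})
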