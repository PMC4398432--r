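test_that("image difference is a metric-like score on masked cells", {
  set.seed(5)
  pair <- random_view_pair(10, 8)
  expect_equal(image_difference(pair$a, pair$a), 0)
  expect_equal(image_difference(pair$a, pair$b),
               image_difference(pair$b, pair$a))

  # loop oracle over masked cells, 100 random pairs
  for (trial in 1:100) {
    p <- random_view_pair(8, 10)
    oracle <- 0
    for (i in 1:8) for (j in 1:8) {
      if (p$a$mask[i, j])
        oracle <- oracle + abs(p$a$values[i, j] - p$b$values[i, j])
    }
    expect_equal(image_difference(p$a, p$b), oracle)
  }

  # triangle inequality
  for (trial in 1:20) {
    p1 <- random_view_pair(9, 6)
    p2 <- random_view_pair(9, 6)
    expect_lte(image_difference(p1$a, p2$b),
               image_difference(p1$a, p1$b) + image_difference(p1$b, p2$b))
  }

  # extreme views: all level 0 vs all level g-1 over an n=50 mask
  g <- 10
  mask <- circular_mask(50)
  mk <- function(level) {
    vals <- matrix(level, 50, 50)
    vals[!mask] <- NA_real_
    structure(list(values = vals, mask = mask, v = vals[mask],
                   heading_deg = 0, center = c(row = 1, col = 1),
                   cfg = sensor_config(window_px = 50, out_res = 50,
                                       gray_levels = g)),
              class = "scenefam_view")
  }
  expect_equal(image_difference(mk(0), mk(g - 1)), sum(mask) * (g - 1))

  # mismatched sensor configurations are rejected
  v1 <- random_view_pair(10, 8)$a
  v2 <- random_view_pair(12, 8)$a
  expect_error(image_difference(v1, v2), "different sensor")
})

test_that("difference topography sums each scene's differences to all others", {
  cfg <- sensor_config(window_px = 20, out_res = 10, gray_levels = 10)

  flat <- landscape(matrix(50, 100, 100), 1)
  g <- sample_grid(flat, 3, 3, 20)
  expect_true(all(difference_topography(flat, g, cfg)$grid == 0))

  land <- regime_landscape("high", 300, seed = 11)
  g2 <- sample_grid(land, 2, 2, 20)
  dm <- difference_topography(land, g2, cfg)
  views <- lapply(seq_len(4), function(i) {
    process_view(land, g2$positions[i, ], 0, cfg)
  })
  # enumeration oracle: cell i = sum of its 3 pairwise scores (row-major)
  oracle <- sapply(1:4, function(i) {
    sum(sapply(setdiff(1:4, i), function(j) {
      image_difference(views[[i]], views[[j]])
    }))
  })
  expect_equal(as.vector(t(dm$grid)), oracle)
  # double-counting identity: total = 2 * sum over unordered pairs
  pair_sum <- sum(sapply(1:3, function(i) {
    sum(sapply((i + 1):4, function(j) image_difference(views[[i]], views[[j]])))
  }))
  expect_equal(sum(dm$grid), 2 * pair_sum)
})

test_that("volcano surfaces are zero at the focal scene and grow along a gradient", {
  cfg <- sensor_config(window_px = 20, out_res = 10, gray_levels = 100,
                       equalize = FALSE)
  land <- gradient_landscape(200)
  vol <- volcano(land, position(100, 100), 3, cfg, spacing_px = 10)
  expect_equal(vol$surface[4, 4], 0)
  expect_equal(vol$spacing_m, 10)
  # along the gradient axis the difference grows monotonically with distance
  east <- vol$surface[4, 4:7]
  expect_true(all(diff(east) > 0))

  flat <- landscape(matrix(50, 100, 100), 1)
  expect_true(all(volcano(flat, position(50, 50), 2, cfg, 5)$surface == 0))

  # out-of-bounds surrounds: error by default, NA + warning when trimmed
  expect_error(volcano(land, position(15, 100), 3, cfg, 10), "leaves")
  expect_warning(
    vtrim <- volcano(land, position(15, 100), 3, cfg, 10,
                     out_of_bounds = "trim"),
    "trimmed")
  expect_true(anyNA(vtrim$surface))
})

test_that("RIDF recovers a stored view's heading on textured ground", {
  land <- regime_landscape("high", 300, seed = 11)
  cfg <- sensor_config(window_px = 40, out_res = 20, gray_levels = 10,
                       rotation_increment_deg = 1)
  at <- position(160, 140)

  stored0 <- process_view(land, at, 0, cfg)
  r0 <- ridf(land, at, stored0, cfg)
  expect_equal(r0$best_angle_deg, 0)
  expect_equal(r0$best_score, 0)
  expect_equal(r0$best_score, min(r0$scores))
  expect_equal(length(r0$angles_deg), 360)

  set.seed(6)
  for (beta in runif(5, 0, 360)) {
    st <- process_view(land, at, beta, cfg)
    r <- ridf(land, at, st, cfg)
    delta <- abs(((r$best_angle_deg - beta + 180) %% 360) - 180)
    expect_lte(delta, 1)
  }

  # rotationally symmetric input: flat curve, argmin tie-breaks to angle 0
  flat <- landscape(matrix(99, 120, 120), 1)
  stf <- process_view(flat, position(60, 60), 0, cfg)
  rf <- ridf(flat, position(60, 60), stf, cfg)
  expect_equal(length(unique(rf$scores)), 1)
  expect_equal(rf$best_angle_deg, 0)
})

test_that("p50 finds the half-maximum crossing of the averaged cardinal slices", {
  # synthetic cone: difference rises linearly from 0 to M over D meters
  k <- 10
  cone <- outer(-k:k, -k:k, function(i, j) pmax(abs(i), abs(j)))
  # cardinal slices see value = distance * slope
  M <- 80
  surf <- cone / k * M
  vol <- structure(list(surface = surf, spacing_m = 2), class = "scenefam_volcano")
  p <- p50_summary(vol)
  expect_false(p$no_information)
  expect_equal(p$p50_difference, M / 2)
  expect_equal(p$p50_distance_m, (k * 2) / 2)

  # flat surface: no-information sentinel, not an error
  pz <- p50_summary(structure(list(surface = matrix(0, 5, 5), spacing_m = 1),
                              class = "scenefam_volcano"))
  expect_true(pz$no_information)
  expect_true(is.na(pz$p50_distance_m))

  # random surfaces match a brute-force scan of the averaged curve
  set.seed(7)
  for (trial in 1:100) {
    kk <- sample(3:8, 1)
    s <- matrix(runif((2 * kk + 1)^2, 0, 100), 2 * kk + 1)
    s[kk + 1, kk + 1] <- 0
    sp <- runif(1, 1, 10)
    p <- p50_summary(structure(list(surface = s, spacing_m = sp),
                               class = "scenefam_volcano"))
    ctr <- kk + 1
    curve <- (s[ctr:(ctr - kk), ctr] + s[ctr:(ctr + kk), ctr] +
              s[ctr, ctr:(ctr + kk)] + s[ctr, ctr:(ctr - kk)]) / 4
    half <- max(curve) / 2
    i <- which(curve >= half)[1]
    d50 <- if (i == 1) 0 else
      (i - 2 + (half - curve[i - 1]) / (curve[i] - curve[i - 1])) * sp
    expect_equal(p$p50_difference, half)
    expect_equal(p$p50_distance_m, d50)
  }
})

test_that("region averaging is the mean of the per-focal surfaces and curves", {
  land <- regime_landscape("medium", 400, seed = 7)
  cfg <- sensor_config(window_px = 40, out_res = 10, gray_levels = 10,
                       rotation_increment_deg = 30)
  st <- averaged_region_stats(land, cfg, grid_rows = 20, k = 3)
  expect_equal(dim(st$volcano$surface), c(7, 7))
  expect_equal(nrow(st$focal_positions), 5)

  grid <- sample_grid(land, 20, 20, 40)
  spacing <- mean(grid$spacing_px)
  surfs <- curves <- vector("list", 5)
  for (i in 1:5) {
    f <- st$focal_positions[i, ]
    surfs[[i]] <- volcano(land, f, 3, cfg, spacing)$surface
    curves[[i]] <- ridf(land, f, process_view(land, f, 0, cfg), cfg)$scores
  }
  expect_equal(st$volcano$surface, Reduce(`+`, surfs) / 5)
  expect_equal(st$ridf$scores, Reduce(`+`, curves) / 5)
  expect_equal(st$p50$p50_difference,
               p50_summary(structure(list(surface = Reduce(`+`, surfs) / 5,
                                          spacing_m = spacing),
                                     class = "scenefam_volcano"))$p50_difference)
})
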