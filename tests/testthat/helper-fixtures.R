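# shared fixtures, built once per test run and cached by argument signature
.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# smooth deterministic gradient: intensity rises along rows and columns
gradient_landscape <- function(n = 200, mpp = 1) {
  fixture(paste0("grad", n, "_", mpp), function() {
    r <- outer(seq_len(n), seq_len(n), function(i, j) (i + j))
    landscape(round(255 * (r - min(r)) / (max(r) - min(r))), mpp)
  })
}

# seeded synthetic terrain, shared across tests
regime_landscape <- function(regime, n = 400, seed = 7) {
  fixture(paste0(regime, n, "_", seed), function() {
    make_landscape(terrain_spec(regime, size_px = n, seed = seed))
  })
}

# random raster in [0, 255] with distinct values (rank ties avoided)
random_raster <- function(n) {
  matrix(sample(seq(0, 255, length.out = n * n)), n, n)
}

# small random quantized view pair sharing one mask/config
random_view_pair <- function(n = 10, g = 8) {
  mask <- circular_mask(n)
  mk <- function() {
    vals <- matrix(sample(0:(g - 1), n * n, replace = TRUE), n, n)
    vals[!mask] <- NA_real_
    structure(list(values = vals, mask = mask, v = vals[mask],
                   heading_deg = 0, center = c(row = 1, col = 1),
                   cfg = sensor_config(window_px = n, out_res = n,
                                       gray_levels = g)),
              class = "scenefam_view")
  }
  list(a = mk(), b = mk())
}

# short straight-route memory bank on a small high-information landscape
small_memory <- function(res = 20, g = 10, window = 40, regime = "high") {
  fixture(paste0("mem", res, "_", g, "_", window, "_", regime), function() {
    land <- regime_landscape(regime, 300, seed = 11)
    wp <- waypoints(rbind(c(150, 60), c(150, 240)))
    route <- widen_corridor(interpolate_path(wp, 5), land = land,
                            window_px = window)
    cfg <- sensor_config(window_px = window, out_res = res, gray_levels = g)
    list(land = land, route = route, memory = build_memory(land, route, cfg),
         cfg = cfg)
  })
}
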