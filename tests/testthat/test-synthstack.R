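test_that("sample_death_times handles empty, fixed, and parametric draws", {
  expect_identical(sample_death_times(0, list(name = "exponential", mean = 40)),
                   numeric(0))
  expect_equal(
    sample_death_times(3, list(name = "fixed", times = c(10, 20, 30))),
    c(10, 20, 30))
  # law of large numbers against the closed-form mean
  x <- sample_death_times(10000, list(name = "exponential", mean = 40),
                          seed = 11)
  expect_true(mean(x) > 39 && mean(x) < 41)
  expect_true(all(x >= 0))
  w <- sample_death_times(5000, list(name = "weibull", shape = 2, scale = 30),
                          seed = 12)
  expect_equal(mean(w), 30 * gamma(1.5), tolerance = 0.02)
  # reproducibility
  expect_identical(
    sample_death_times(50, list(name = "exponential", mean = 40), seed = 4),
    sample_death_times(50, list(name = "exponential", mean = 40), seed = 4))
})

test_that("sample_death_times rejects bad distributions", {
  expect_error(sample_death_times(3, list(name = "gompertz", a = 1)),
               "unknown")
  expect_error(sample_death_times(3, list(name = "exponential", mean = -4)),
               "positive")
  expect_error(sample_death_times(3, list(name = "weibull", shape = 0,
                                          scale = 2)))
})

test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(occupancy_probs = c(0.5, 0.5, 0.1, 0, 0)), "sum")
  expect_error(sim_config(frame_interval = 0), "frame_interval")
  expect_error(sim_config(worm_level = 220, background_level = 200), "darker")
  expect_error(sim_config(n_arenas = 0), "n_arenas")
})

test_that("render_arena_frame draws worm-like blobs of the target area", {
  # no objects, no noise: constant background
  img <- render_arena_frame(list(), c(60, 120), background_level = 180)
  expect_true(all(img == 180))

  set.seed(21)
  for (k in 1:5) {
    off <- worm_posture(1000, max_extent = 45)
    img <- render_arena_frame(
      list(list(offsets = off, centroid = c(60, 100), level = 60)),
      c(126, 200), background_level = 200)
    mask <- img < 130
    st <- oracle_component_stats(mask)
    expect_equal(nrow(st), 1)                      # one connected component
    expect_lt(abs(st$area - 1000), 100)            # area within 10%
    expect_lt(abs(st$centroid_row - 60), 1)        # placed at the centroid
    expect_lt(abs(st$centroid_col - 100), 1)
  }

  # determinism of the noise draw
  off <- worm_posture(600, max_extent = 40)
  st <- list(list(offsets = off, centroid = c(30, 30), level = 60))
  a <- render_arena_frame(st, c(64, 64), noise_sd = 3, seed = 9)
  b <- render_arena_frame(st, c(64, 64), noise_sd = 3, seed = 9)
  expect_identical(a, b)
})

test_that("render_arena_frame warns when a blob is clipped", {
  off <- worm_posture(400, max_extent = 30)
  expect_warning(
    render_arena_frame(list(list(offsets = off, centroid = c(2, 2),
                                 level = 60)), c(64, 64)),
    "clipped")
})

test_that("postures vary but respect the area target and extent bound", {
  set.seed(31)
  areas <- numeric(20); exts <- numeric(20); widths <- numeric(20)
  for (i in 1:20) {
    off <- worm_posture(1000, max_extent = 45)
    areas[i] <- nrow(off)
    exts[i] <- max(abs(off))
    widths[i] <- diff(range(off[, 2])) + 1
  }
  expect_true(all(abs(areas - 1000) <= 100))
  expect_true(all(exts <= 55))
  expect_gt(length(unique(widths)), 3)  # bounding boxes vary with posture
})

test_that("generated experiments respect occupancy and conserve animals", {
  cfg <- sim_config(n_arenas = 8, frames = 12, arena_px = c(126, 456),
                    occupancy_probs = c(0, 1, 0, 0, 0),
                    survival_dist = list(name = "fixed", times = 100),
                    debris_rate = 0, bubble_rate = 0, seed = 5)
  sim <- generate_experiment(cfg)
  expect_equal(sim$truth$arenas$occupancy, rep(1, 8))
  expect_equal(nrow(sim$truth$animals), sum(sim$truth$arenas$occupancy))
  expect_true(all(sim$truth$animals$alive_at_end))

  cfg2 <- sim_config(n_arenas = 12, frames = 12,
                     occupancy_probs = c(0.3, 0.3, 0.2, 0.1, 0.1),
                     debris_rate = 0.5, bubble_rate = 0.2, seed = 6)
  sim2 <- generate_experiment(cfg2)
  expect_equal(nrow(sim2$truth$animals), sum(sim2$truth$arenas$occupancy))
  # death times inside the observed range or alive-at-end
  d <- sim2$truth$animals
  expect_true(all(is.na(d$death_time_h[d$alive_at_end])))
  expect_true(all(d$death_time_h[!d$alive_at_end] >= 0 &
                  d$death_time_h[!d$alive_at_end] <= 11))
})

test_that("generation is bit-identical for a fixed seed", {
  cfg <- sim_config(n_arenas = 4, frames = 6, debris_rate = 0.3, seed = 17)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(a$series$frames, b$series$frames)
  expect_identical(a$truth, b$truth)
})

test_that("a worm's rendered centroid moves while alive and freezes at death", {
  cfg <- sim_config(n_arenas = 1, frames = 10, arena_px = c(126, 456),
                    occupancy_probs = c(0, 1, 0, 0, 0),
                    survival_dist = list(name = "fixed", times = 5),
                    movement_px = c(mean = 12, sd = 0),
                    debris_rate = 0, bubble_rate = 0, noise_sd = 0, seed = 2)
  sim <- generate_experiment(cfg)
  cents <- t(vapply(sim$series$frames, function(f)
    oracle_centroid(f < 130), numeric(2)))
  disp <- sqrt(rowSums(diff(cents)^2))  # pair i = frames i -> i+1
  expect_true(all(disp[1:5] > 7))       # alive through the pair starting at 4 h
  expect_true(all(disp[6:9] == 0))      # frozen once t >= death
})

test_that("global shift events translate static content exactly", {
  cfg <- sim_config(n_arenas = 1, frames = 5, arena_px = c(126, 456),
                    occupancy_probs = c(1, 0, 0, 0, 0),
                    debris_rate = 3, bubble_rate = 0, noise_sd = 0,
                    global_shift_events = data.frame(frame = 4, drow = 10,
                                                     dcol = 0),
                    seed = 8)
  sim <- generate_experiment(cfg)
  expect_gt(nrow(sim$truth$artifacts), 0)
  cents <- t(vapply(sim$series$frames, function(f)
    oracle_centroid(f < 130), numeric(2)))
  expect_equal(unname(cents[4, ] - cents[3, ]), c(10, 0))  # the shift pair
  expect_equal(unname(cents[2, ] - cents[1, ]), c(0, 0))   # static otherwise
  expect_equal(unname(cents[5, ] - cents[4, ]), c(0, 0))   # shift persists
  expect_equal(sim$truth$shifts$drow, c(0, 0, 0, 10, 10))
})

test_that("fading after death lowers worm contrast over time", {
  cfg <- sim_config(n_arenas = 1, frames = 12, arena_px = c(126, 456),
                    occupancy_probs = c(0, 1, 0, 0, 0),
                    survival_dist = list(name = "fixed", times = 2),
                    fade_after_death = 0.3, debris_rate = 0, bubble_rate = 0,
                    noise_sd = 0, seed = 13)
  sim <- generate_experiment(cfg)
  mins <- vapply(sim$series$frames, min, numeric(1))
  expect_equal(mins[1], 60)             # full contrast while alive
  expect_true(all(diff(mins[3:12]) > 0))  # contrast decays after death
  expect_gt(mins[12], 150)              # nearly vanished into background
})

test_that("simulations round-trip through TIFF + JSON manifest", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_arenas = 2, frames = 4, arena_px = c(64, 128),
                    worm_area_px = 400,
                    occupancy_probs = c(0, 1, 0, 0, 0),
                    survival_dist = list(name = "fixed", times = 2),
                    debris_rate = 0, bubble_rate = 0, seed = 14)
  sim <- generate_experiment(cfg)
  write_simulation(sim, dir)
  back <- load_simulation(dir)
  expect_equal(length(back$series), 4)
  expect_equal(back$series$times, sim$series$times)
  # 8-bit quantisation: within half a gray level
  expect_lt(max(abs(back$series$frames[[1]] - sim$series$frames[[1]])), 0.51)
  expect_equal(back$truth$arenas$occupancy, sim$truth$arenas$occupancy)
  expect_equal(back$truth$animals$death_time_h, sim$truth$animals$death_time_h)
  expect_equal(back$config$seed, 14)
})
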