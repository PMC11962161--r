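test_that("background-only movie is exactly the background level", {
  cal <- movie_calibration(frame_count = 3, roi = c(32, 32))
  sim <- simulate_movie(cal, NULL, emitter_model(), noiseless(100), seed = 1)
  expect_true(all(sim$movie == 100))
  expect_equal(nrow(sim$truth), 0)
})

test_that("non-physical simulation parameters are rejected", {
  expect_error(movie_calibration(pixel_size = -1), "pixel_size")
  expect_error(emitter_model(brightness_b = 0), "brightness_b")
  expect_error(emitter_model(maturation_fraction = 1.5), "maturation_fraction")
  expect_error(noise_model(background_level = -5), "background_level")
  cal <- movie_calibration(frame_count = 3, roi = c(32, 32))
  expect_error(simulate_movie(cal, data.frame(S = 0, D = 0.1),
                              emitter_model(), noiseless(), seed = 1),
               "parameter error")
})

test_that("immobile unbleached assembly integrates to S x b per frame", {
  cal <- movie_calibration(frame_count = 4, roi = c(32, 32))
  sim <- simulate_movie(cal, data.frame(S = 4, D = 0, x0 = 0.8, y0 = 0.8),
                        narrow_emitter(brightness_b = 110), noiseless(100),
                        seed = 1)
  ctr <- rep(floor(0.8 / 0.053) + 1, 2)
  for (f in 1:4) {
    expect_equal(measure_intensity(sim$movie[, , f], ctr), 440,
                 tolerance = 0.01)  # PSF-truncation tolerance
  }
  expect_true(all(sim$truth$expected_intensity == 440))
})

test_that("simulated walk matches Brownian per-step displacement variance", {
  cal <- movie_calibration(frame_count = 2000, roi = c(4000, 4000))
  sim <- simulate_movie(cal, data.frame(S = 1, D = 0.5, x0 = 100, y0 = 100),
                        emitter_model(bleach_rate = 0), noiseless(),
                        seed = 2, render = FALSE)
  vx <- stats::var(diff(sim$truth$x_um))
  vy <- stats::var(diff(sim$truth$y_um))
  expect_equal(vx, 2 * 0.5 * 0.0125, tolerance = 0.1)
  expect_equal(vy, 2 * 0.5 * 0.0125, tolerance = 0.1)
})

test_that("photon conservation: counts above background equal live emission", {
  cal <- movie_calibration(frame_count = 6, roi = c(48, 48))
  set.seed(3)
  asm <- data.frame(S = c(4, 8), D = 0.05,
                    x0 = c(0.9, 1.7), y0 = c(0.9, 1.7))
  emit <- emitter_model(bleach_rate = 0.05, brightness_cv = 0.1)
  sim <- simulate_movie(cal, asm, emit, noiseless(100), seed = 3)
  for (f in seq_len(6)) {
    total <- sum(sim$movie[, , f]) - 100 * 48 * 48
    expected <- sum(sim$truth$expected_intensity[sim$truth$frame == f])
    expect_equal(total, expected, tolerance = 0.01)
  }
})

test_that("same seed reproduces movie bit-identically; truth is noise-independent", {
  cal <- movie_calibration(frame_count = 5, roi = c(32, 32))
  asm <- data.frame(S = 4, D = 0.2)
  a <- simulate_movie(cal, asm, emitter_model(), fixture_noise(), seed = 9)
  b <- simulate_movie(cal, asm, emitter_model(), fixture_noise(), seed = 9)
  expect_identical(a$movie, b$movie)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_movie(cal, asm, emitter_model(), fixture_noise(), seed = 9,
                       noise_seed = 77)
  expect_identical(a$truth, c2$truth)   # same latent trajectories
  expect_false(identical(a$movie, c2$movie))  # different photon noise
})

test_that("expected per-assembly intensity is non-increasing in frame", {
  cal <- movie_calibration(frame_count = 50, roi = c(64, 64))
  sim <- simulate_movie(cal, data.frame(S = 12, D = 0, x0 = 1.5, y0 = 1.5),
                        emitter_model(bleach_rate = 0.05), noiseless(),
                        seed = 4)
  expect_true(all(diff(sim$truth$expected_intensity) <= 0))
})

test_that("bleach trace examples: single and triple fluorophore, noiseless", {
  emit <- emitter_model(brightness_cv = 0, bleach_rate = 0.05,
                        brightness_b = 110)
  tr1 <- simulate_bleach_trace(1, emit, noise_sd = 0, seed = 5)
  expect_setequal(unique(tr1$trace), c(110, 0))
  expect_length(tr1$step_frames, 1)
  expect_true(all(diff(tr1$trace) <= 0))

  tr3 <- simulate_bleach_trace(3, emit, noise_sd = 0, seed = 3)
  expect_true(all(unique(tr3$trace) %in% c(330, 220, 110, 0)))
  expect_true(all(diff(tr3$trace) <= 0))
  expect_error(simulate_bleach_trace(0, emit), "n_fluor")
})

test_that("bleach trace ensemble mean follows the exponential decay law", {
  emit <- emitter_model(brightness_cv = 0, bleach_rate = 0.03,
                        brightness_b = 100)
  n_fluor <- 3
  traces <- sapply(1:400, function(i)
    simulate_bleach_trace(n_fluor, emit, noise_sd = 0, seed = i,
                          n_frames = 100)$trace)
  emp <- rowMeans(traces)
  t0 <- 0:99
  expect_lt(max(abs(emp - n_fluor * 100 * exp(-0.03 * t0))) /
              (n_fluor * 100), 0.05)
})

test_that("confocal phantom: truth volumes, channel counts, overlap", {
  obj <- data.frame(x = 1.4, y = 1.4, z = 1.8,
                    rx = 0.175, ry = 0.175, rz = 0.175, peak = 200)
  cfg <- phantom3d_config(shape = c(48, 48, 14), objects_ch1 = obj)
  ph <- simulate_confocal_stack(cfg)
  expect_equal(sum(ph$truth$channel == 1), 1)
  expect_equal(sum(ph$truth$channel == 2), 0)
  # analytic sphere volume 4/3 pi r^3
  cfg2 <- phantom3d_config(shape = c(48, 48, 14),
                           objects_ch1 = transform(obj, rx = 0.3, ry = 0.3,
                                                   rz = 0.3))
  ph2 <- simulate_confocal_stack(cfg2)
  expect_equal(ph2$truth$volume_analytic[1], 4 / 3 * pi * 0.3^3,
               tolerance = 1e-12)
  # identical object lists, zero shift -> overlap fraction 1 for every pair
  cfg3 <- phantom3d_config(shape = c(48, 48, 14), objects_ch1 = obj,
                           objects_ch2 = obj, channel_shift = c(0, 0))
  ph3 <- simulate_confocal_stack(cfg3)
  expect_true(all(ph3$truth$overlap_fraction == 1))
})

test_that("movies round-trip through 16-bit TIFF at count resolution", {
  cal <- movie_calibration(frame_count = 3, roi = c(24, 24))
  sim <- simulate_movie(cal, data.frame(S = 4, D = 0.1), emitter_model(),
                        fixture_noise(), seed = 6)
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d, "mv")
  back <- read_tiff_stack(file.path(d, "mv.tif"))
  expect_equal(back, pmin(pmax(round(sim$movie), 0), 65535), tolerance = 1e-9)
  cfgy <- yaml::read_yaml(file.path(d, "mv_config.yaml"))
  expect_equal(cfgy$seed, 6)
})
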