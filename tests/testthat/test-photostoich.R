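test_that("bleach correction flattens a global exponential decay", {
  set.seed(1)
  Tn <- 60
  base <- matrix(200, 32, 32)
  movie <- array(0, c(32, 32, Tn))
  for (f in seq_len(Tn)) movie[, , f] <- base * exp(-0.01 * (f - 1)) + 20
  bc <- bleach_correct(movie)
  expect_true(bc$corrected)
  means <- apply(bc$movie, 3, mean)
  expect_lt((max(means) - min(means)) / mean(means), 0.01)
  expect_equal(unname(bc$params["k"]), 0.01, tolerance = 0.05)
})

test_that("constant movies pass through bleach correction unchanged", {
  movie <- array(150, c(16, 16, 12))
  expect_warning(bc <- bleach_correct(movie), "identity")
  expect_identical(bc$movie, movie)
  expect_false(bc$corrected)
  expect_error(bleach_correct(array(1, c(4, 4, 5))), "10 frames")
})

test_that("Chung-Kennedy preserves noiseless steps and smooths noise", {
  x <- c(440, 440, 330, 330)
  expect_equal(chung_kennedy(x, window = 2), x, tolerance = 1e-9)
  set.seed(2)
  y <- 100 + rnorm(200, 0, 10)
  expect_lt(stats::var(chung_kennedy(y, 10)), stats::var(y))
  expect_error(chung_kennedy(y, window = 1), "window")
  expect_error(chung_kennedy(rnorm(5), window = 10), "longer")
})

test_that("Chung-Kennedy matches an independently coded direct implementation", {
  # naive loop implementation of the same forward/backward predictor
  # equations, written without any vectorized shortcuts
  ck_direct <- function(y, W, p) {
    n <- length(y)
    eps <- .Machine$double.eps
    mu_f <- rep(NA_real_, n); mu_b <- rep(NA_real_, n)
    for (i in 1:n) {
      if (i > 1) mu_f[i] <- mean(y[max(1, i - W):(i - 1)])
      if (i < n) mu_b[i] <- mean(y[(i + 1):min(n, i + W)])
    }
    out <- y
    for (i in 1:n) {
      if (is.na(mu_f[i]) || is.na(mu_b[i])) next
      sf <- 0
      for (j in max(1, i - W + 1):i) if (!is.na(mu_f[j]))
        sf <- sf + (y[j] - mu_f[j])^2
      sb <- 0
      for (j in i:min(n, i + W - 1)) if (!is.na(mu_b[j]))
        sb <- sb + (y[j] - mu_b[j])^2
      wf <- (sf + eps)^(-p); wb <- (sb + eps)^(-p)
      out[i] <- (wf * mu_f[i] + wb * mu_b[i]) / (wf + wb)
    }
    out
  }
  set.seed(3)
  y <- c(rep(440, 40), rep(330, 30), rep(110, 30)) + rnorm(100, 0, 8)
  for (W in c(5, 10)) for (p in c(1, 4)) {
    expect_equal(chung_kennedy(y, W, p), ck_direct(y, W, p),
                 tolerance = 1e-9)
  }
})

test_that("brightness calibration: exact steps, Monte-Carlo recovery, failure", {
  # all steps exactly 110 -> modal brightness exactly 110
  tr0 <- rep(c(440, 330, 220, 110, 0), each = 20)
  cal0 <- calibrate_brightness(lapply(1:5, function(i) tr0),
                               late_stage_fraction = 1)
  expect_equal(cal0$b_modal, 110)
  # steps ~ Normal(110, 15): modal step within 110 +- 5
  emit <- emitter_model(brightness_b = 110, brightness_cv = 15 / 110,
                        bleach_rate = 0.02)
  traces <- lapply(1:200, function(i)
    simulate_bleach_trace(((i - 1) %% 4) + 1, emit, noise_sd = 10,
                          seed = i, n_frames = 150)$trace)
  cal <- calibrate_brightness(traces)
  expect_gte(cal$n_steps_used, 10)
  expect_lt(abs(cal$b_modal - 110), 5.5)
  # empty / stepless input signals calibration failure
  expect_error(calibrate_brightness(list()), class = "calibration_error")
  flat <- lapply(1:5, function(i) rep(500, 50))
  expect_error(calibrate_brightness(flat), class = "calibration_error")
})

test_that("calibration is invariant to adding tracks with zero steps", {
  emit <- emitter_model(brightness_b = 110, brightness_cv = 15 / 110,
                        bleach_rate = 0.02)
  traces <- lapply(1:100, function(i)
    simulate_bleach_trace(((i - 1) %% 4) + 1, emit, noise_sd = 10,
                          seed = i, n_frames = 150)$trace)
  cal1 <- calibrate_brightness(traces)
  flat <- lapply(1:20, function(i) rep(5000, 150))
  cal2 <- calibrate_brightness(c(traces, flat))
  expect_equal(cal2$b_modal, cal1$b_modal)
  expect_equal(cal2$n_steps_used, cal1$n_steps_used)
})

test_that("stoichiometry extrapolation: linear fit to the first frame", {
  tr <- data.frame(frame = 1:5, intensity = c(440, 436, 432, 428, 424))
  s <- stoichiometry(tr, 110)
  expect_equal(s$initial_intensity, 440, tolerance = 1e-9)
  expect_equal(s$S, 4, tolerance = 1e-9)
  # 2-frame track
  tr2 <- data.frame(frame = 1:2, intensity = c(220, 220))
  expect_equal(stoichiometry(tr2, 110)$S, 2, tolerance = 1e-9)
  # longer tracks use only the first 5 points
  tr3 <- data.frame(frame = 1:10,
                    intensity = c(440, 436, 432, 428, 424, 0, 0, 0, 0, 0))
  expect_equal(stoichiometry(tr3, 110)$S, 4, tolerance = 1e-9)
  # extrapolation is to the track's own first frame, not movie frame 0
  tr4 <- data.frame(frame = 11:15, intensity = c(440, 436, 432, 428, 424))
  expect_equal(stoichiometry(tr4, 110)$S, 4, tolerance = 1e-9)
  # non-positive initial intensity -> rejected with a reason code
  bad <- stoichiometry(data.frame(frame = 1:3, intensity = c(-5, -6, -7)),
                       110)
  expect_false(bad$accepted)
  expect_equal(bad$reason, "nonpositive_initial")
  expect_error(stoichiometry(tr[1, , drop = FALSE], 110), ">= 2")
})

test_that("stoichiometry is scale-consistent", {
  tr <- data.frame(frame = 1:5, intensity = c(880, 860, 840, 820, 800))
  s1 <- stoichiometry(tr, 110)$S
  tr2 <- transform(tr, intensity = intensity * 3.7)
  s2 <- stoichiometry(tr2, 110 * 3.7)$S
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("stoichiometry recovery across the oligomer ladder", {
  # tracks built from simulated assembly intensities at fixture noise
  emit <- emitter_model(brightness_b = 110, brightness_cv = 15 / 110,
                        bleach_rate = 0.01)
  set.seed(10)
  svals <- seq(4, 56, by = 4)
  est <- lapply(svals, function(S) {
    replicate(40, {
      tr <- simulate_bleach_trace(S, emit, noise_sd = 10,
                                  seed = sample.int(1e6, 1), n_frames = 30)
      st <- stoichiometry(data.frame(frame = 1:5,
                                     intensity = tr$trace[1:5]), 110)
      if (st$accepted) st$S else NA_real_
    })
  })
  err <- mapply(function(S, e) stats::median(abs(e - S), na.rm = TRUE),
                svals, est)
  expect_true(all(err[svals <= 16] <= 1))
  expect_true(all(err[svals > 16] / svals[svals > 16] <= 0.1))
  # mean for true S = 8 within 8 +- 1
  expect_lt(abs(mean(est[[2]], na.rm = TRUE) - 8), 1)
})
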