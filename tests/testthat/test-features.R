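test_that("uniform resampling preserves uniform input and endpoints", {
  p <- runif(240, 0.5, 2)
  rec <- uniform_rec(p)
  u <- resample_uniform(rec, 120)
  expect_equal(u$pressure, p, tolerance = 1e-12)
  expect_equal(u$rate, 120)

  ramp <- pen_recording(c(0, 1), c(0, 1), c(0, 0), c(0, 1), "R", "spiral")
  expect_equal(resample_uniform(ramp, 4)$pressure,
               c(0, 0.25, 0.5, 0.75, 1))
})

test_that("resampling agrees with a pointwise interpolation oracle", {
  set.seed(5)
  t <- sort(runif(40, 0, 2))
  t <- t - t[1]
  p <- runif(40, 0.5, 3)
  rec <- pen_recording(t, seq_along(t), rep(0, 40), p, "I", "spiral")
  u <- resample_uniform(rec, 50)
  for (k in seq_along(u$t)) {
    tk <- u$t[k]
    j <- max(which(t <= tk + 1e-15))
    expected <- if (j == length(t)) p[j] else
      p[j] + (p[j + 1] - p[j]) * (tk - t[j]) / (t[j + 1] - t[j])
    expect_equal(u$pressure[k], expected, tolerance = 1e-12)
  }
})

test_that("drawing time is the elapsed span and is shift-invariant", {
  rec <- uniform_rec(rep(1, 1141))  # 9.5 s at 120 Hz
  expect_equal(drawing_time(rec), 9.5)
  shifted <- pen_recording(rec$samples$t + 5, rec$samples$x,
                           rec$samples$y, rec$samples$pressure,
                           "S", "spiral")
  expect_equal(drawing_time(shifted), 9.5)
})

test_that("average pressure matches closed forms", {
  expect_equal(average_pressure(uniform_rec(rep(1, 10))), 1.0)
  expect_equal(average_pressure(uniform_rec(c(1, 2, 3))), 2.0)
  ramp <- uniform_rec(seq(0.5, 2.5, length.out = 241))
  expect_equal(average_pressure(ramp), 1.5, tolerance = 1e-12)
})

test_that("sparc equals the brute-force DFT arc-length oracle", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(16:64, 1)
    rate <- sample(c(60, 120), 1)
    s <- 1.5 + 0.4 * sin(seq(0, 3 * pi, length.out = n)) + rnorm(n, 0, 0.2)
    mode <- sample(c("pressure", "pressure_derivative"), 1)
    fn <- sample(c(TRUE, FALSE), 1)
    cfg <- sparc_config(freq_normalized = fn, signal_mode = mode)
    expect_equal(sparc(s, rate, cfg),
                 sparc_oracle(s, rate, freq_normalized = fn, mode = mode),
                 tolerance = 1e-10)
  }
})

test_that("sparc is invariant to positive rescaling", {
  set.seed(7)
  s <- 1.2 + cumsum(rnorm(200, 0, 0.01))
  for (cfg in list(sparc_config(),
                   sparc_config(signal_mode = "pressure"))) {
    expect_lt(abs(sparc(2 * s, 120, cfg) - sparc(s, 120, cfg)), 1e-12)
    expect_lt(abs(sparc(0.3 * s, 120, cfg) - sparc(s, 120, cfg)), 1e-12)
  }
})

test_that("sparc decreases as band-limited noise is amplified", {
  set.seed(11)
  n <- 600
  t <- (0:(n - 1)) / 120
  base <- 1.5 + 0.35 * (t / 5 - 0.5) + 0.2 * sin(2 * pi * t / 5)
  set.seed(12)
  w <- rnorm(n)
  W <- fft(w)
  f <- pmin((0:(n - 1)) * 120 / n, 120 - (0:(n - 1)) * 120 / n)
  W[f < 2 | f > 15] <- 0
  shape <- Re(fft(W, inverse = TRUE)) / n
  shape <- shape / sd(shape)
  amps <- c(0.002, 0.005, 0.01, 0.02, 0.05, 0.1)
  sp <- vapply(amps, function(a) sparc(base + a * shape, 120),
               numeric(1))
  expect_true(all(diff(sp) <= 1e-9))
  # same directionality for an independent 10 Hz contamination
  smooth <- 1.5 + 0.3 * (t / 5) + 0.2 * sin(2 * pi * 0.2 * t)
  noisy <- smooth + 0.05 * sin(2 * pi * 10 * t)
  expect_lt(sparc(noisy, 120), sparc(smooth, 120))
})

test_that("sparc rejects degenerate inputs", {
  expect_error(sparc(c(1, 2, 3), 120), "too short")
  expect_error(sparc(rep(0, 16), 120, sparc_config(signal_mode = "pressure")),
               "zero DC")
  # constant signal: identically zero derivative, maximal smoothness
  expect_equal(sparc(rep(2, 16), 120), 0)
})

test_that("feature extraction assembles DT/AP/SP per recording", {
  co <- simulate_cohort(n_noncm = 3, n_cm = 2, seed = 6)
  f <- extract_features(co)
  expect_equal(nrow(f), length(co$recordings))
  expect_named(f, c("participant_id", "group", "shape", "DT", "AP", "SP"))
  expect_true(all(f$DT > 0))
  expect_true(all(f$AP > 0 & f$AP <= pressure_max()))
  expect_true(all(f$SP < 0))

  # a constant-pressure tracing scores smoother than any noisy variant
  quiet <- simulate_recording(make_spiral(),
                              subject_draw(5, 1.5, pressure_drift_amp = 0,
                                           pressure_trend = 0,
                                           roughness_amp = 0, seed = 1))
  noisy <- lapply(1:3, function(s)
    simulate_recording(make_spiral(),
                       subject_draw(5, 1.5, roughness_amp = 0.02 * s,
                                    seed = s)))
  sp0 <- extract_features(quiet)$SP
  expect_true(all(sp0 > vapply(noisy, function(r) extract_features(r)$SP,
                               numeric(1))))
})
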