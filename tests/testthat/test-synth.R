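test_that("whistle waveforms follow their contour", {
  fs <- 100e3
  # flat tone: spectrogram ridge within one bin of the nominal frequency
  w <- synth_whistle(whistle_spec("flat", 10e3, duration = 0.5), fs)
  sp <- compute_spectrogram(w, spectrogram_params(fs = fs))
  ridge <- sp$f[apply(sp$P, 2, which.max)]
  expect_lt(max(abs(ridge - 10e3)), fs / 1024 + 1e-9)
  # instantaneous frequency (phase derivative) tracks the contour closely
  spec <- whistle_spec("rise", 5e3, 15e3, 1)
  w <- synth_whistle(spec, fs)
  # linear ridge fit of the spectrogram recovers the sweep rate
  sp <- compute_spectrogram(w, spectrogram_params(fs = fs))
  cs <- click_suppress(sp, 4.5e3, 15.5e3)
  fit <- lm(cs$M ~ cs$t)
  expect_equal(unname(coef(fit)[2]), 10e3, tolerance = 0.03)
  expect_length(synth_whistle(whistle_spec(duration = 0)), 0)
  expect_error(synth_whistle(whistle_spec("flat", 60e3), fs), "Nyquist")
})

test_that("whistle RMS pressure matches the source level", {
  w <- synth_whistle(whistle_spec("flat", 10e3, duration = 0.5, SL = 160))
  mid <- 10000:40000   # avoid the tapers
  expect_equal(20 * log10(sqrt(mean(w[mid]^2))), 160, tolerance = 0.05)
})

test_that("click trains have the configured number of impulses", {
  fs <- 100e3
  x <- synth_clicks(10, fs, 1, SL = 170)
  thr <- 0.5 * max(abs(x))
  above <- abs(x) > thr
  onsets <- sum(diff(c(FALSE, above)) == 1)
  # clicks are oscillatory: count bursts, not samples; group within 1 ms
  idx <- which(above)
  bursts <- sum(diff(c(-Inf, idx)) > fs * 1e-3)
  expect_equal(bursts, 10)
})

test_that("boat spectrum has comb lines at engine harmonics", {
  fs <- 100e3
  set.seed(4)
  x <- synth_boat(boat_spec(f0 = 120, n_harmonics = 5,
                            broadband_frac = 0.05, SL = 170), fs, 2)
  X <- Mod(fft(x))[1:(length(x) / 2)]
  f <- (seq_along(X) - 1) * fs / length(x)
  for (k in 1:5) {
    band <- which(abs(f - 120 * k) < 5)
    nearby <- which(abs(f - 120 * k) < 40 & abs(f - 120 * k) > 15)
    expect_gt(max(X[band]), 5 * stats::median(X[nearby]))
  }
})

test_that("ambient noise band level matches the Wenz table entry", {
  set.seed(5)
  x <- synth_ambient(0, 100e3, 5)
  expect_equal(band_level(x, 100e3, 5e3, 15e3), 69, tolerance = 0.5)
  x4 <- synth_ambient(4, 100e3, 2)
  expect_equal(band_level(x4, 100e3, 5e3, 15e3), 88, tolerance = 0.5)
})

test_that("scene rendering is deterministic under a fixed seed", {
  spec <- whistle_spec("rise", 6e3, 12e3, 0.2, SL = 160)
  sc <- scene(list(scene_source("w", "whistle", spec, t0 = 0.05,
                                trajectory = c(800, 0, 1))),
              duration = 0.9, sea_state = 0, seed = 77)
  r1 <- render_scene(sc, list(scene_unit("A")))
  r2 <- render_scene(sc, list(scene_unit("A")))
  expect_identical(r1$A$x, r2$A$x)
})

test_that("rendered TDOAs match the plane-wave model", {
  r <- render_single_whistle(pos = c(1000, 0, 2), seed = 8)
  tr <- r$truth[1, ]
  expect_equal(tr$bearing_deg, 90)
  ts <- event_tdoa_set(r$x, r$fs, tr$arrival_time, tr$arrival_time + 0.5)
  expect_true(ts$valid)
  tru <- unlist(tr[c("t01", "t02", "t03", "t12", "t13", "t23")])
  expect_lt(max(abs(ts$dt - tru)) * r$fs, 2)   # within 2 samples
  # East-aligned geometry: pair (0,2) sees ~L/c, pair (1,3) ~0
  expect_equal(abs(ts$dt[["t02"]]), 5 / 1500 * sin(deg2rad(tr$elevation_deg)),
               tolerance = 2e-5)
  expect_lt(abs(ts$dt[["t13"]]), 2e-5)
})

test_that("sources inside the plane-wave range are flagged", {
  r <- render_single_whistle(pos = c(50, 0, 2), seed = 9)
  expect_match(r$warnings[1], "plane-wave")
})

test_that("equal-range source arrives simultaneously at both units", {
  spec <- whistle_spec("rise", 6e3, 12e3, 0.3, SL = 165)
  sc <- scene(list(scene_source("w", "whistle", spec, t0 = 0.05,
                                trajectory = c(900, 1200, 1))),
              duration = 1.5, sea_state = 0, seed = 10)
  r <- render_scene(sc, list(scene_unit("A", c(0, 0)),
                             scene_unit("B", c(1800, 0))))
  expect_equal(r$A$truth$arrival_time, r$B$truth$arrival_time,
               tolerance = 1e-4)
})

test_that("WAV files round-trip 4-channel data at 100 kHz", {
  set.seed(11)
  x <- matrix(runif(4000, -0.9, 0.9), ncol = 4)
  path <- tempfile(fileext = ".wav")
  write_wav(x, path, 100e3)
  back <- read_wav(path)
  expect_equal(back$fs, 100e3)
  expect_equal(dim(back$x), dim(x))
  expect_lt(max(abs(back$x - x)), 1 / 32767)
})
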