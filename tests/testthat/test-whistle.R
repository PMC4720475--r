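test_that("spectrogram geometry and normalization are correct", {
  fs <- 100e3
  p <- spectrogram_params(fs = fs)
  expect_equal(p$hop, 256L)
  t <- (0:99999) / fs
  x <- sin(2 * pi * 10e3 * t)
  sp <- compute_spectrogram(x, p)
  # ridge at bin round(10000 / df) of the 0-based bin axis
  peak_bin <- apply(sp$P, 2, which.max) - 1
  expect_true(all(peak_bin == round(10e3 / (fs / 1024))))
  # per-frame total power approximates the signal variance (Parseval)
  expect_equal(mean(colSums(sp$P)), 0.5, tolerance = 0.01)
  expect_error(compute_spectrogram(x[1:100], p), "shorter")
  sp0 <- compute_spectrogram(numeric(2048), p)
  expect_true(all(sp0$P == 0))
})

test_that("click suppression keeps the tonal track through clicks", {
  fs <- 100e3
  t <- (0:49999) / fs
  tone <- sin(2 * pi * 9e3 * t)
  clicks <- synth_clicks(20, fs, 0.5, SL = 10)
  clicks <- clicks / max(abs(clicks)) * 8       # strong broadband bursts
  sp <- compute_spectrogram(tone + clicks, spectrogram_params(fs = fs))
  cs <- click_suppress(sp)
  # the maxima track must stay on the tone despite the clicks
  expect_gt(mean(abs(cs$M - 9e3) < 200), 0.95)
  # noise-only input gives a scattered track
  set.seed(21)
  spn <- compute_spectrogram(rnorm(50000), spectrogram_params(fs = fs))
  csn <- click_suppress(spn)
  expect_gt(sd(csn$M), 1000)
  expect_error(click_suppress(sp, 1e3, 60e3), "band")
})

test_that("click suppression reduces to the only nonzero bin", {
  sp <- structure(list(P = matrix(0, 513, 20),
                       f = (0:512) * (100e3 / 1024),
                       t = seq_len(20) * 0.00256,
                       params = spectrogram_params()),
                  class = "spectrogram")
  sp$P[80, ] <- 1    # a single active bin per column
  cs <- click_suppress(sp)
  expect_true(all(cs$bin == 80))
})

test_that("detection function has the closed-form bounds and offsets", {
  P <- 10
  n <- 200
  # constant track: all L = 0, W = 1
  r <- detection_function(rep(8e3, n), seq_len(n) * 0.00256, P = P)
  expect_true(all(r$W == 1))
  # maximally jagged track (third difference large everywhere): W = 0.8^P
  M <- 1000 * (-1)^(1:n) * (1:n)
  r2 <- detection_function(M, seq_len(n) * 0.00256, P = P, threshold = 100)
  expect_true(all(abs(r2$W - 0.8^P) < 1e-12))
  # bounds and constant-offset invariance hold for arbitrary tracks
  set.seed(31)
  M3 <- runif(n, 5e3, 15e3)
  r3 <- detection_function(M3, seq_len(n) * 0.00256, P = P)
  expect_true(all(r3$W >= 0.8^P - 1e-12 & r3$W <= 1 + 1e-12))
  r4 <- detection_function(M3 + 3e3, seq_len(n) * 0.00256, P = P)
  expect_equal(r3$W, r4$W)
  expect_error(detection_function(rep(1, 5), 1:5, P = 10), "shorter")
})

test_that("slope and duration are measured robustly", {
  hop_t <- 0.00256
  n <- 300
  times <- seq_len(n) * hop_t
  # linear chirp 10 kHz/s
  M <- 8e3 + 1e4 * times
  ev <- data.frame(peak_index = 150)
  r <- measure_slope_duration(ev, M, times)
  expect_equal(r$slope, 1e4, tolerance = 0.05)
  # three corrupted samples leave the bisquare slope unchanged
  M2 <- M; M2[c(140, 150, 160)] <- M2[c(140, 150, 160)] + 4e3
  r2 <- measure_slope_duration(ev, M2, times)
  expect_equal(r2$slope, 1e4, tolerance = 0.05)
  # flat tone embedded in scattered noise: duration recovers tone extent
  set.seed(41)
  M3 <- runif(n, 5e3, 15e3)
  M3[100:200] <- 9e3
  r3 <- measure_slope_duration(data.frame(peak_index = 150), M3, times)
  expect_lt(abs(r3$slope), 100)
  expect_lt(abs(r3$duration - 101 * hop_t), 6 * hop_t)
  # truncation flag at the record edge
  r4 <- measure_slope_duration(data.frame(peak_index = 5), M, times)
  expect_true(r4$truncated)
})

test_that("slope/duration gate separates whistles from cable screech", {
  expect_true(false_positive_gate(10e3, 0.4))
  expect_false(false_positive_gate(0, 2.0))
  expect_true(false_positive_gate(0, 0.5))     # short flat whistles pass
  expect_true(false_positive_gate(0, 2.0, gate_config(enabled = FALSE)))
  expect_false(false_positive_gate(NaN, 1))
})

test_that("whistles are detected in ambient noise where present only", {
  set.seed(51)
  fs <- 100e3
  spec <- whistle_spec("rise", 6e3, 13e3, 0.5, SL = 160)
  w <- synth_whistle(spec, fs)
  x <- synth_ambient(0, fs, 3)
  nm <- noise_model()
  # place the whistle at 20 dB band SNR
  NLb <- band_noise_level(noise_spectral_level(nm, 0), 5e3, 15e3)
  w <- w * db_to_pressure(NLb + 20) / db_to_pressure(spec$SL)
  t0 <- 1.2
  idx <- round(t0 * fs) + seq_along(w)
  x[idx] <- x[idx] + w
  d <- detect_whistles(x)
  acc <- d[d$accepted, ]
  expect_gte(nrow(acc), 1)
  expect_true(any(acc$start < t0 + 0.5 & acc$end > t0))
  # nothing accepted far away from the whistle
  expect_false(any(acc$end < t0 - 0.1 | acc$start > t0 + 0.8))
})
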