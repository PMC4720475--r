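Lc0 <- 5 / 1500

test_that("pair TDOAs invert to the documented candidate angles", {
  a <- angles_from_tdoas(Lc0, 0, Lc0)
  expect_equal(a$a20[1], 0)
  expect_true(0 %in% round(a$a31 %% (2 * pi), 10))
  b <- angles_from_tdoas(0, Lc0, Lc0)
  expect_equal(b$a20[1], pi / 2)
  expect_equal(b$a31[1], pi / 2)
  d <- angles_from_tdoas(Lc0 / sqrt(2), Lc0 / sqrt(2), Lc0)
  expect_equal(d$a20[1], pi / 4, tolerance = 1e-12)
  expect_equal(d$a31[1], pi / 4, tolerance = 1e-12)
  # beyond Lc by more than the tolerance: discarded
  expect_null(angles_from_tdoas(Lc0 * 1.2, 0, Lc0))
  # just over: clipped and flagged
  cl <- angles_from_tdoas(Lc0 + 1e-5, 0, Lc0, tol = 2e-5)
  expect_true(cl$clipped)
})

test_that("angular error propagates and diverges at the pair axis", {
  expect_equal(angular_error(0, Lc0, 1e-5), 1e-5 / Lc0)
  expect_equal(angular_error(Lc0 / sqrt(2), Lc0, 1e-5),
               sqrt(2) * 1e-5 / Lc0, tolerance = 1e-12)
  taus <- seq(0, 0.99, by = 0.01) * Lc0
  errs <- sapply(taus, angular_error, Lc = Lc0, dtau = 1e-5)
  expect_true(all(diff(errs) > 0))
  expect_equal(angular_error(Lc0, Lc0, 1e-5), Inf)
})

brute_force_alpha <- function(cand, e20, e31, sigma_factor = 4) {
  grid <- seq(0, 2 * pi, by = deg2rad(0.1))
  f <- rep(1, length(grid))
  if (is.finite(e20))
    f <- f * pair_density(grid, cand$a20, sigma_factor * e20)
  if (is.finite(e31))
    f <- f * pair_density(grid, cand$a31, sigma_factor * e31)
  grid[which.max(f)]
}

test_that("ambiguity resolution matches the brute-force density argmax", {
  set.seed(10)
  for (i in 1:25) {
    alpha <- runif(1, 0, 2 * pi)
    dT20 <- Lc0 * cos(alpha) + rnorm(1, sd = 2e-6)
    dT31 <- Lc0 * sin(alpha) + rnorm(1, sd = 2e-6)
    if (abs(dT20) > Lc0) dT20 <- sign(dT20) * Lc0
    if (abs(dT31) > Lc0) dT31 <- sign(dT31) * Lc0
    cand <- angles_from_tdoas(dT20, dT31, Lc0)
    e20 <- angular_error(dT20, Lc0); e31 <- angular_error(dT31, Lc0)
    r <- resolve_ambiguity(cand, e20, e31)
    expect_true(r$ok)
    bf <- brute_force_alpha(cand, e20, e31)
    expect_lt(rad2deg(abs((r$alpha - bf + pi) %% (2 * pi) - pi)), 0.1)
    # the resolved angle is near the true one, mirrors suppressed
    expect_lt(rad2deg(abs((r$alpha - alpha + pi) %% (2 * pi) - pi)), 3)
    expect_equal(r$dalpha, min(e20, e31))
  }
})

test_that("degenerate pair hands the solution to the other pair", {
  # target on the (H0,H2) axis: tau20 ~ Lc, pair (0,2) error diverges
  cand <- angles_from_tdoas(Lc0, 2e-6, Lc0)
  r <- resolve_ambiguity(cand, angular_error(Lc0 * 0.9999, Lc0),
                         angular_error(2e-6, Lc0))
  expect_true(r$ok)
  expect_lt(rad2deg(abs((r$alpha - 0 + pi) %% (2 * pi) - pi)), 2)
  expect_equal(r$dalpha, angular_error(2e-6, Lc0))
  # coincident mirrors at 90 deg give a unique maximum there
  cand2 <- angles_from_tdoas(0, Lc0, Lc0)
  r2 <- resolve_ambiguity(cand2, angular_error(0, Lc0),
                          angular_error(Lc0 * 0.9999, Lc0))
  expect_equal(rad2deg(r2$alpha), 90, tolerance = 1)
})

test_that("elevation correction follows 1/cos(arctan(h/R))", {
  expect_equal(elevation_correction(1, -20, 150), 1 / cos(atan(20 / 150)))
  expect_equal(elevation_correction(1, -20, 150), 1.009, tolerance = 1e-3)
  expect_equal(elevation_correction(3, 0, 150), 3)
  expect_equal(elevation_correction(1, -20, 1e9), 1, tolerance = 1e-12)
})

test_that("correlogram stream tracks a static boat and gates noise", {
  set.seed(11)
  pos <- c(500 * sin(pi / 4), 500 * cos(pi / 4), 0)
  src <- scene_source("b", "boat", boat_spec(SL = 175), t0 = 0,
                      trajectory = pos, duration = 2.5)
  sc <- scene(list(src), duration = 2.5, sea_state = 0, seed = 14)
  r <- render_scene(sc, list(scene_unit("A")))
  cg <- correlogram_stream(r$A$x, r$A$fs)
  ok <- is.finite(cg$dT20)
  expect_gt(mean(ok), 0.7)
  # constant within a sample for the bulk of windows (the gate passes a few
  # periodic-signal outliers, so use robust dispersion)
  expect_lt(stats::mad(cg$dT20[ok]) * r$A$fs, 1)
  med <- stats::median(cg$dT20[ok])
  expect_gt(mean(abs(cg$dT20[ok] - med) * r$A$fs < 1.5), 0.9)
  # noise-only channels: at least 95% of windows gated out
  amb <- sapply(1:4, function(i) synth_ambient(0, 100e3, 2))
  cgn <- correlogram_stream(amb, 100e3)
  expect_gt(mean(!is.finite(cgn$dT20)), 0.95)
  expect_gt(mean(!is.finite(cgn$dT31)), 0.95)
})

test_that("a circling boat is tracked around the full circle", {
  lap <- 30
  tt <- seq(0, lap, by = 0.1)
  ang <- 2 * pi * tt / lap
  traj <- cbind(tt, 300 * sin(ang), 300 * cos(ang), 0)
  src <- scene_source("b", "boat", boat_spec(SL = 175), t0 = 0,
                      trajectory = traj, duration = lap)
  sc <- scene(list(src), duration = lap, sea_state = 0, seed = 15)
  r <- render_scene(sc, list(scene_unit("A")))
  bs <- boat_bearing_stream(r$A$x, r$A$fs)
  s <- bs[bs$ok, ]
  truth <- (360 * (s$time - 0.2) / lap) %% 360   # 0.2 s acoustic delay
  err <- abs((s$azimuth_deg - truth + 180) %% 360 - 180)
  off_axis <- pmin(truth %% 90, 90 - truth %% 90) >= 5
  expect_gt(nrow(s), 2000)
  expect_lt(sqrt(mean(err[off_axis]^2)), 2)
})

test_that("bearing stream is equivariant under a compass shift", {
  set.seed(16)
  pos <- c(400 * sin(1), 400 * cos(1), 0)
  src <- scene_source("b", "boat", boat_spec(SL = 175), t0 = 0,
                      trajectory = pos, duration = 1)
  mk <- function(compass) {
    sc <- scene(list(src), duration = 1, sea_state = 0, seed = 17)
    un <- scene_unit("A", attitude_fun = function(t)
      attitude(0, 0, compass, time = t))
    r <- render_scene(sc, list(un))
    bs <- boat_bearing_stream(r$A$x, r$A$fs, attitude_log = r$A$attitude)
    stats::median(bs$azimuth_deg[bs$ok])
  }
  expect_equal(mk(25), mk(0), tolerance = 0.2)
  agg <- aggregate_bearing_stream(data.frame(
    time = c(0.1, 0.4, 1.2), azimuth_deg = c(359, 1, 90),
    error_deg = c(1, 1, 1), ok = TRUE))
  expect_lt(abs((agg$azimuth_deg[1] + 180) %% 360 - 180), 1e-6)
})
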