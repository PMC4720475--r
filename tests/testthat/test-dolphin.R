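test_that("linear solve inverts the forward TDOA model exactly", {
  g <- array_geometry()
  n_true <- angles_to_unit(deg2rad(30), deg2rad(100))
  dt <- expected_tdoas(n_true, g)
  r <- solve_linear(dt, g)
  expect_equal(r$n, n_true, tolerance = 1e-10)
  expect_lt(r$norm_residual, 1e-10)
  # wave straight down the z axis
  r2 <- solve_linear(expected_tdoas(c(0, 0, 1), g), g)
  expect_equal(r2$n, c(0, 0, 1), tolerance = 1e-10)
})

test_that("one-sample TDOA noise moves the direction less than 3 degrees", {
  set.seed(6)
  g <- array_geometry()
  errs <- replicate(1000, {
    phi <- runif(1, 0, 2 * pi); theta <- runif(1, deg2rad(60), deg2rad(120))
    n_true <- angles_to_unit(phi, theta)
    dt <- expected_tdoas(n_true, g) + runif(6, -1e-5, 1e-5)
    r <- solve_linear(dt, g)
    rad2deg(acos(min(1, sum(r$n * n_true))))
  })
  expect_lt(max(errs), 3)
})

test_that("grid search minimizes G to the true direction", {
  g <- array_geometry()
  set.seed(7)
  for (i in 1:10) {
    phi <- runif(1, 0, 2 * pi); theta <- runif(1, deg2rad(20), deg2rad(160))
    dt <- expected_tdoas(angles_to_unit(phi, theta), g)
    gs <- grid_search_G(dt, g)
    expect_true(gs$ok)
    sep <- acos(min(1, sum(angles_to_unit(gs$phi, gs$theta) *
                           angles_to_unit(phi, theta))))
    expect_lt(rad2deg(sep), 0.5)
    expect_lt(gs$G, 1e-11)            # residual of the 0.02-deg final grid
    # G vanishes exactly at the true direction
    expect_equal(G_functional(phi, theta, dt, g), 0)
  }
  # degenerate flat surface
  z <- stats::setNames(rep(0, 6), pamtrack:::pair_names())
  expect_false(grid_search_G(z, g)$ok)
})

test_that("grid search and linear solve agree on noiseless TDOAs", {
  g <- array_geometry()
  set.seed(8)
  for (i in 1:10) {
    phi <- runif(1, 0, 2 * pi); theta <- runif(1, deg2rad(30), deg2rad(150))
    dt <- expected_tdoas(angles_to_unit(phi, theta), g)
    a <- solve_linear(dt, g)$n
    gs <- grid_search_G(dt, g)
    b <- angles_to_unit(gs$phi, gs$theta)
    expect_lt(rad2deg(acos(min(1, sum(a * b)))), 1)
  }
})

test_that("G is invariant under joint rotation of array and direction", {
  g <- array_geometry()
  att <- attitude(10, -8, 35)
  R <- attitude_rotation(att)
  g_rot <- g; g_rot$H <- g$H %*% t(R)
  set.seed(9)
  for (i in 1:5) {
    phi <- runif(1, 0, 2 * pi); theta <- runif(1, deg2rad(30), deg2rad(150))
    n0 <- angles_to_unit(phi, theta)
    dt <- expected_tdoas(n0, g)
    n_rot <- drop(R %*% n0)
    a_rot <- unit_to_angles(n_rot)
    expect_equal(G_functional(phi, theta, dt, g),
                 G_functional(a_rot$phi, a_rot$theta,
                              expected_tdoas(n_rot, g_rot, H = g_rot$H), g_rot),
                 tolerance = 1e-18)
  }
})

test_that("wave-to-source mapping applies the half-turn and attitude", {
  # wave travelling along +x at the horizontal: source lies at math
  # azimuth 180 deg, i.e. compass bearing 270 (ENU West)
  b <- wave_to_source_bearing(0, pi / 2, attitude())
  expect_equal(b$azimuth, 270)
  expect_equal(b$elevation, 90, tolerance = 1e-9)
  # adding 30 deg of heading shifts the bearing by +30
  b2 <- wave_to_source_bearing(0, pi / 2, attitude(compass = 30))
  expect_equal(b2$azimuth, 300)
  # missing attitude: body-frame bearing, flagged
  b3 <- wave_to_source_bearing(0, pi / 2, NULL)
  expect_equal(b3$frame, "body")
})

test_that("full event pipeline recovers the bearing on a rendered scene", {
  r <- render_single_whistle(pos = c(-700, 1100, 2), seed = 13)
  det <- detect_whistles(r$x[, 1])
  expect_true(any(det$accepted))
  bs <- dolphin_bearings(r$x, r$fs, det, attitude_log = r$attitude, psi0 = 0)
  expect_gte(length(bs), 1)
  err <- abs((bs[[1]]$azimuth - r$truth$bearing_deg[1] + 180) %% 360 - 180)
  expect_lt(err, 2)
})
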