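test_that("band centroid is the geometric mean", {
  expect_equal(band_centroid(5e3, 15e3), 8660.254, tolerance = 1e-6)
  expect_equal(band_centroid(7e3, 7e3), 7e3)
  expect_equal(band_centroid(1, 100), 10)
  expect_error(band_centroid(-1, 10))
})

test_that("detection threshold follows DT = 10 log10(d/m)", {
  r <- detection_threshold(9, 100e3, 15e3)
  expect_equal(r$DT, 1.3, tolerance = 0.01)
  expect_equal(r$SN0, 1.35)
  expect_equal(detection_threshold(100e3 / 15e3, 100e3, 15e3)$DT, 0)
  expect_equal(detection_threshold(9, 100e3, 30e3)$DT,
               10 * log10(9 * 30e3 / 100e3), tolerance = 1e-12)
  expect_error(detection_threshold(-1, 100e3, 15e3))
})

test_that("transmission loss combines spreading and absorption", {
  expect_equal(transmission_loss(1, 20, 0), 0)
  expect_lt(transmission_loss(1), 1e-3)   # absorption over 1 m is negligible
  expect_equal(transmission_loss(1000, 20, 0.72), 60.72)
  expect_equal(transmission_loss(9200, 20, 0.72), 85.9, tolerance = 0.05)
  expect_error(transmission_loss(0.5), "1 m")
})

test_that("band noise level adds 10 log10(B)", {
  expect_equal(band_noise_level(29, 5e3, 15e3), 69)
  expect_equal(band_noise_level(48, 5e3, 15e3), 88)
  expect_equal(band_noise_level(33, 1000, 1001), 33)
  # shift equivariance
  expect_equal(band_noise_level(29 + 7, 5e3, 15e3),
               band_noise_level(29, 5e3, 15e3) + 7)
  expect_error(band_noise_level(29, 10, 10))
})

test_that("detection range solves the sonar budget", {
  p <- sonar_params()   # SL 160, DT 5, k 20, alpha 0.72
  r0 <- detection_range(p, 69)
  r4 <- detection_range(p, 88)
  expect_equal(r0, 9200, tolerance = 0.02)
  expect_equal(r4, 1900, tolerance = 0.02)
  # inversion: budget closes at the root
  expect_equal(transmission_loss(r0, p$k, p$alpha) + 69 + p$DT, p$SL,
               tolerance = 0.01)
  expect_equal(transmission_loss(r4, p$k, p$alpha) + 88 + p$DT, p$SL,
               tolerance = 0.01)
  # zero budget at the reference distance (absorption off so TL(1) = 0)
  expect_equal(detection_range(sonar_params(SL = 74, DT = 5, alpha = 0), 69), 1)
  und <- detection_range(sonar_params(SL = 60, DT = 5), 69)
  expect_true(is.na(und))
  expect_true(attr(und, "undetectable"))
})

test_that("detection range is monotone in SL, NL and DT", {
  base <- sonar_params()
  ranges_nl <- sapply(c(60, 70, 80, 90), function(nl)
    detection_range(base, nl))
  expect_true(all(diff(ranges_nl) < 0))
  ranges_sl <- sapply(c(150, 155, 160, 165), function(sl)
    detection_range(sonar_params(SL = sl), 69))
  expect_true(all(diff(ranges_sl) > 0))
  ranges_dt <- sapply(c(1, 3, 5, 8), function(dt)
    detection_range(sonar_params(DT = dt), 69))
  expect_true(all(diff(ranges_dt) < 0))
})

test_that("noise model table is validated and applies its offset", {
  nm <- noise_model(c("0" = 29, "2" = 36, "4" = 48), offset = 7)
  expect_equal(noise_spectral_level(nm, 2), 43)
  expect_error(noise_model(c("0" = 48, "4" = 29)), "non-decreasing")
  expect_error(noise_spectral_level(nm, 9), "not in noise table")
  tab <- sonar_budget_table(sonar_params(), noise_model())
  expect_equal(nrow(tab), 2)
  expect_true(all(diff(tab$range_m) < 0))
})

test_that("radio link planning arithmetic matches closed forms", {
  expect_equal(radio_horizon(40), 22.6, tolerance = 0.01)
  expect_equal(radio_horizon(0), 0)
  expect_equal(radio_horizon(10), sqrt(2 * 6371 * 0.01), tolerance = 1e-12)
  expect_equal(fresnel_radius(0.85, 0.85, 5.47), 4.8, tolerance = 0.01)
  expect_equal(fresnel_radius(1.75, 1.75, 5.47), 6.9, tolerance = 0.01)
  expect_equal(fresnel_radius(0, 1.7, 5.47, 1.7), 0)
  expect_error(fresnel_radius(1, 1, 0))
  expect_equal(free_space_loss(1.7, 5470), 111.8, tolerance = 0.01)
  expect_equal(free_space_loss(1, 1), 32.45)
  b <- link_budget(20, Cls = 0, Gtx = 0, Lfs = 0, Grx = 0)
  expect_equal(b$Prx, 20)
  b2 <- link_budget(20, Cls = 1, Gtx = 18, Lfs = 111.8, Grx = 18,
                    sensitivity = -90)
  expect_equal(b2$Prx, 20 - 1 + 18 - 111.8 + 18 - 1)
  expect_equal(b2$margin, b2$Prx + 90)
})

test_that("minimum stream bandwidth is the sample-channel-bit product", {
  expect_equal(min_stream_bandwidth(100e3, 4, 16), 6.4e6)
  expect_equal(min_stream_bandwidth(1, 1, 1), 1)
  expect_equal(min_stream_bandwidth(48e3, 2, 24), 2.304e6)
})
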