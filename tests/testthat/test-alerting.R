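test_that("positions and bearing rays map to the right sectors", {
  g <- sector_grid()
  expect_equal(assign_sector(g, east = 500, north = 500), "3")
  expect_equal(assign_sector(g, east = -2500, north = 500), "1")
  expect_equal(assign_sector(g, east = 0, north = -500), "5")
  expect_equal(assign_sector(g, east = 9000, north = 9000), "outside")
  # a NE ray from the origin crosses sector 3 only
  expect_equal(assign_sector(g, unit_pos = c(100, 100), azimuth_deg = 45,
                             range_m = 4000), "3")
  # a due-East ray at mid-height crosses sectors 3 then 4
  hit <- assign_sector(g, unit_pos = c(100, 500), azimuth_deg = 90,
                       range_m = 4000)
  expect_setequal(hit, c("3", "4"))
  # a Westward ray from the far East crosses 4, 3, 2 within its range
  hit2 <- assign_sector(g, unit_pos = c(3900, 500), azimuth_deg = 270,
                        range_m = 4200)
  expect_setequal(hit2, c("4", "3", "2"))
  expect_equal(assign_sector(g, unit_pos = c(0, -3000), azimuth_deg = 180,
                             range_m = 1000), "outside")
})

test_that("sector colours follow the dolphin/boat precedence", {
  g <- sector_grid()
  expect_true(all(update_state(g, now = 100) == "green"))
  dol <- data.frame(time = 90, sector = "2")
  st <- update_state(g, dolphin_events = dol, now = 100)
  expect_equal(unname(st["2"]), "yellow")
  expect_true(all(st[names(st) != "2"] == "green"))
  boat <- data.frame(time = 95, sector = "2")
  st2 <- update_state(g, dol, boat, now = 100)
  expect_equal(unname(st2["2"]), "red")
  # boat alone does not raise an alarm
  st3 <- update_state(g, boat_events = boat, now = 100)
  expect_true(all(st3 == "green"))
  # hold time expiry returns to green
  st4 <- update_state(g, dol, boat, now = 90 + 601)
  expect_true(all(st4 == "green"))
})

test_that("alarm history logs transitions and replays identically", {
  g <- sector_grid()
  dol <- data.frame(time = c(10, 400), sector = c("2", "3"))
  boat <- data.frame(time = 420, sector = "3")
  h1 <- alarm_history(g, dol, boat)
  h2 <- alarm_history(g, dol, boat)
  expect_identical(h1, h2)
  expect_true(any(h1$sector == "2" & h1$to == "yellow"))
  expect_true(any(h1$sector == "3" & h1$to == "red"))
  expect_true(any(h1$to == "green" & h1$from != "green"))
  expect_equal(nrow(alarm_history(g)), 0)
})

test_that("detection reports carry the four products or mark them absent", {
  ev <- data.frame(start = 1, end = 1.5, peak_time = 1.2, peak_freq = 9e3,
                   peak_W = 1, slope = 5e3, duration = 0.4, accepted = TRUE)
  w <- synth_whistle(whistle_spec("rise", 6e3, 12e3, 0.3, SL = 120))
  sp <- compute_spectrogram(w)
  X <- plane_wave_channels(0.5, 1.5)
  ts <- tdoa_set(X, 100e3)
  b <- bearing(123, 88)
  rep <- detection_report(ev, sp, ts, b)
  expect_equal(rep$tracking$mode, "bearing-only")
  expect_false(identical(rep$spectrogram, "absent"))
  expect_false(identical(rep$cross_correlation, "absent"))
  # degradation: no products still yields a report
  rep2 <- detection_report(ev)
  expect_identical(rep2$spectrogram, "absent")
  expect_identical(rep2$tracking, "absent")
  # written form is valid JSON
  path <- tempfile(fileext = ".json")
  detection_report(ev, path = path)
  expect_silent(jsonlite::fromJSON(path))
})

test_that("configuration round-trips through YAML with overrides", {
  cfg <- default_config()
  expect_equal(cfg$sonar$SL, 160)
  path <- tempfile(fileext = ".yaml")
  writeLines(c("sonar:", "  SL: 155", "tdoa:", "  n_sigma: 5"), path)
  over <- read_config(path)
  expect_equal(over$sonar$SL, 155)
  expect_equal(over$sonar$f_min, 5000)   # untouched default
  expect_equal(over$tdoa$n_sigma, 5)
})
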