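# Simulation studies exercising the full pipeline on synthetic scenes with
# known ground truth: bearing/triangulation recovery, detector hit and
# false-event rates, and calibration recovery. Tests and the acceptance
# script both call these, so the study conditions live in one place.

random_whistle_spec <- function(SL = 160) {
  shape <- sample(whistle_shapes, 1)
  f0 <- stats::runif(1, 6e3, 12e3)
  f1 <- if (shape %in% c("rise")) stats::runif(1, f0 + 2e3, 15e3)
        else if (shape == "fall") stats::runif(1, 5e3, f0 - 1e3)
        else f0
  # natural whistles are never spectrally pure: even "flat" calls wander by
  # a few hundred Hz over their course
  whistle_spec(shape, f0, f1, duration = stats::runif(1, 0.3, 0.8), SL = SL,
               excursion = stats::runif(1, 1e3, 2.5e3),
               wander = stats::runif(1, 150, 400))
}

#' Bearing and triangulation recovery study
#'
#' Renders single-whistle scenes at two units 1.8 km apart (wobbling
#' attitudes, sea-state 0 ambient noise, 160 dB source level), runs the full
#' chain (whistle detection, TDOA measurement, functional minimization,
#' world-frame bearing, two-ray triangulation) and compares against ground
#' truth. Source positions are drawn uniformly in bearing with ranges of
#' 0.5--3 km from both units.
#'
#' @param n number of trials (default 100).
#' @param seed RNG seed.
#' @param SL whistle source level, dB re 1 uPa at 1 m.
#' @param sea_state ambient sea state.
#' @param range_lim allowed range interval to each unit, metres.
#' @param error_deg angular accuracy used for the error square, degrees
#'   (default 2).
#' @return data.frame, one row per trial: truth and estimates per unit,
#'   bearing errors (degrees), fix position and error, error-square side and
#'   \code{in_square}. Trials where a unit missed the whistle have NA
#'   estimates.
#' @export
sim_bearing_study <- function(n = 100, seed = 1, SL = 160, sea_state = 0,
                              range_lim = c(500, 3000), error_deg = 2) {
  set.seed(seed)
  posA <- c(0, 0); posB <- c(1800, 0)
  geom <- array_geometry()
  rows <- vector("list", n)
  for (tr in seq_len(n)) {
    repeat {
      az <- stats::runif(1, 0, 2 * pi)
      r0 <- stats::runif(1, range_lim[1], range_lim[2])
      src_pos <- c(posA[1] + r0 * sin(az), posA[2] + r0 * cos(az))
      rB <- sqrt(sum((src_pos - posB)^2))
      if (rB >= range_lim[1] && rB <= range_lim[2]) break
    }
    spec <- random_whistle_spec(SL)
    t0 <- 0.1
    src <- scene_source("w", "whistle", spec, t0 = t0,
                        trajectory = c(src_pos, 1))
    dur <- t0 + max(r0, rB) / 1500 + spec$duration + 0.25
    sc <- scene(list(src), duration = dur, sea_state = sea_state,
                seed = sample.int(2^31 - 1, 1))
    units <- list(
      scene_unit("A", posA, psi0 = stats::runif(1, -90, 90),
                 attitude_fun = NULL),
      scene_unit("B", posB, psi0 = stats::runif(1, -90, 90)))
    units[[1]]$attitude_fun <- wobble_attitude(
      compass0 = stats::runif(1, 0, 360), psi0 = units[[1]]$psi0)
    units[[2]]$attitude_fun <- wobble_attitude(
      compass0 = stats::runif(1, 0, 360), psi0 = units[[2]]$psi0)
    rend <- render_scene(sc, units, geom)
    est <- lapply(c("A", "B"), function(nm) {
      ru <- rend[[nm]]
      det <- detect_whistles(ru$x[, 1])
      if (!nrow(det) || !any(det$accepted)) return(NULL)
      bs <- dolphin_bearings(ru$x, sc$fs, det, attitude_log = ru$attitude,
                             psi0 = ru$unit$psi0, geom = geom)
      if (!length(bs)) return(NULL)
      list(bearing = bs[[1]], det = det[det$accepted, ][1, ])
    })
    names(est) <- c("A", "B")
    trA <- rend$A$truth[1, ]; trB <- rend$B$truth[1, ]
    errA <- errB <- NA_real_; azA <- azB <- NA_real_
    fixE <- fixN <- fix_err <- side <- NA_real_; in_sq <- NA
    if (!is.null(est$A)) {
      azA <- est$A$bearing$azimuth
      errA <- abs((azA - trA$bearing_deg + 180) %% 360 - 180)
    }
    if (!is.null(est$B)) {
      azB <- est$B$bearing$azimuth
      errB <- abs((azB - trB$bearing_deg + 180) %% 360 - 180)
    }
    if (!is.null(est$A) && !is.null(est$B)) {
      fx <- intersect_bearings(azA, azB, posA, posB)
      if (fx$ok) {
        fixE <- fx$east; fixN <- fx$north
        fix_err <- sqrt((fixE - src_pos[1])^2 + (fixN - src_pos[2])^2)
        side <- error_square(max(trA$range_m, trB$range_m), error_deg)
        in_sq <- abs(fixE - src_pos[1]) <= side / 2 &&
                 abs(fixN - src_pos[2]) <= side / 2
      }
    }
    rows[[tr]] <- data.frame(
      trial = tr, shape = spec$shape, east = src_pos[1], north = src_pos[2],
      range_A = trA$range_m, range_B = trB$range_m,
      true_az_A = trA$bearing_deg, true_az_B = trB$bearing_deg,
      est_az_A = azA, est_az_B = azB, err_A = errA, err_B = errB,
      fix_east = fixE, fix_north = fixN, fix_err = fix_err,
      square_side = side, in_square = in_sq)
  }
  do.call(rbind, rows)
}

#' Detector hit-rate and false-event study
#'
#' Hit rate: single-channel records with one whistle each at a received band
#' SNR drawn from \code{snr_range}, counting records with an accepted
#' detection overlapping the whistle. False events: accepted detections on
#' noise-only records of \code{noise_minutes} total duration.
#'
#' @param n_whistles number of whistle records (default 50).
#' @param seed RNG seed.
#' @param snr_range received band SNR interval, dB (default 15--35: at and
#'   above the operating detection threshold of 5 dB plus 10 dB).
#' @param sea_state ambient sea state.
#' @param noise_minutes noise-only minutes for the false-event rate.
#' @param fs sample rate, Hz.
#' @return list with \code{hits} (logical per whistle), \code{hit_rate},
#'   \code{details} (per-whistle frame), \code{false_events},
#'   \code{false_per_10min}.
#' @export
sim_detector_study <- function(n_whistles = 50, seed = 1,
                               snr_range = c(15, 35), sea_state = 0,
                               noise_minutes = 10, fs = 100e3) {
  set.seed(seed)
  nm <- noise_model()
  NLb <- band_noise_level(noise_spectral_level(nm, sea_state), 5e3, 15e3)
  hits <- logical(n_whistles); det_rows <- vector("list", n_whistles)
  for (i in seq_len(n_whistles)) {
    spec <- random_whistle_spec()
    snr <- stats::runif(1, snr_range[1], snr_range[2])
    w <- synth_whistle(spec, fs)
    # scale so the received band level sits snr dB above the noise band level
    w <- w * db_to_pressure(NLb + snr) / db_to_pressure(spec$SL)
    t0 <- 0.3
    x <- synth_ambient(sea_state, fs, spec$duration + 0.8, nm)
    idx <- round(t0 * fs) + seq_along(w)
    x[idx] <- x[idx] + w
    d <- detect_whistles(x)
    acc <- d[d$accepted, , drop = FALSE]
    hit <- nrow(acc) > 0 &&
      any(acc$start < t0 + spec$duration & acc$end > t0)
    hits[i] <- hit
    det_rows[[i]] <- data.frame(shape = spec$shape, snr = snr, hit = hit)
  }
  false_events <- 0L
  for (m in seq_len(noise_minutes)) {
    x <- synth_ambient(sea_state, fs, 60, nm)
    d <- detect_whistles(x)
    false_events <- false_events + sum(d$accepted)
  }
  list(hits = hits, hit_rate = mean(hits),
       details = do.call(rbind, det_rows),
       false_events = false_events,
       false_per_10min = false_events / noise_minutes * 10)
}

#' Calibration recovery study
#'
#' Forward-simulates circling-boat calibration data (TDOA sinusoids with
#' timing jitter for L/c; noisy tracked-vs-GPS bearings for psi0) and runs
#' the estimators.
#'
#' @param seed RNG seed.
#' @param c_sound true sound speeds to recover, m/s.
#' @param psi0_true injected compass offsets, degrees.
#' @param R lap radius, metres.
#' @param laps number of laps.
#' @param lap_s lap period, seconds.
#' @param jitter TDOA jitter standard deviation, seconds (default half a
#'   sample at 100 kHz).
#' @param bearing_sd tracked-bearing noise, degrees.
#' @return data.frame with one row per recovered quantity: name, true,
#'   estimated, relative or absolute error.
#' @export
sim_calibration_study <- function(seed = 1, c_sound = c(1458, 1445),
                                  psi0_true = c(30, -80), R = 150,
                                  laps = 3, lap_s = 120, jitter = 5e-6,
                                  bearing_sd = 2) {
  set.seed(seed)
  tt <- seq(0, laps * lap_s, by = 1)
  alpha <- 2 * pi * tt / lap_s
  rows <- list()
  for (cs in c_sound) {
    Lc <- 5 / cs
    d20 <- data.frame(time = tt, dT = Lc * cos(atan(20 / R)) * cos(alpha) +
                        stats::rnorm(length(tt), sd = jitter))
    d31 <- data.frame(time = tt, dT = Lc * cos(atan(25 / R)) * sin(alpha) +
                        stats::rnorm(length(tt), sd = jitter))
    est <- estimate_Lc(d20, d31, R = R)
    rows[[length(rows) + 1]] <- data.frame(
      quantity = sprintf("Lc_c%d", cs), true = Lc, est = est$Lc,
      error = abs(est$Lc - Lc) / Lc)
  }
  for (p0 in psi0_true) {
    gps_b <- rad2deg(alpha) %% 360
    gps <- data.frame(time = tt, east = R * sin(deg2rad(gps_b)),
                      north = R * cos(deg2rad(gps_b)))
    tracked <- data.frame(time = tt,
                          azimuth_deg = (gps_b - p0 +
                            stats::rnorm(length(tt), sd = bearing_sd)) %% 360)
    est <- estimate_psi0(tracked, gps)
    rows[[length(rows) + 1]] <- data.frame(
      quantity = sprintf("psi0_%+d", p0), true = p0, est = est$psi0,
      error = abs((est$psi0 - p0 + 180) %% 360 - 180))
  }
  do.call(rbind, rows)
}
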