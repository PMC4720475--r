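# Acoustic scene simulator: renders configured sources to the four channels
# of each acoustic unit under the plane-wave arrival model, with spherical
# spreading + absorption amplitude, fractional-delay interpolation and
# sea-state ambient noise. Ground truth is returned for use as a test oracle.

#' Scene source
#'
#' One source in a simulated scene: a waveform generator plus a world-frame
#' trajectory. The trajectory is piecewise linear: a matrix with columns
#' \code{t, east, north, depth} (depth positive down, metres); a single row
#' means a static source.
#'
#' @param id source identifier string.
#' @param type one of \code{"whistle"}, \code{"clicks"}, \code{"boat"}.
#' @param spec a \code{\link{whistle_spec}} or \code{\link{boat_spec}}; for
#'   clicks a list with \code{rate}, \code{SL}, \code{duration}.
#' @param t0 emission start time in the scene, seconds.
#' @param trajectory matrix with columns \code{t, east, north, depth}.
#' @param duration source duration (defaults to the duration field of the
#'   source specification).
#' @return object of class \code{scene_source}.
#' @export
scene_source <- function(id, type = c("whistle", "clicks", "boat"), spec,
                         t0 = 0, trajectory, duration = NULL) {
  type <- match.arg(type)
  if (is.vector(trajectory)) trajectory <- matrix(trajectory, nrow = 1)
  if (ncol(trajectory) == 3) trajectory <- cbind(0, trajectory)
  colnames(trajectory) <- c("t", "east", "north", "depth")
  if (is.null(duration))
    duration <- if (!is.null(spec$duration)) spec$duration else 1
  structure(list(id = id, type = type, spec = spec, t0 = t0,
                 trajectory = trajectory, duration = duration),
            class = "scene_source")
}

source_position <- function(src, t) {
  tr <- src$trajectory
  if (nrow(tr) == 1) return(tr[1, 2:4])
  c(stats::approx(tr[, 1], tr[, 2], t, rule = 2)$y,
    stats::approx(tr[, 1], tr[, 3], t, rule = 2)$y,
    stats::approx(tr[, 1], tr[, 4], t, rule = 2)$y)
}

#' Simulated acoustic scene
#'
#' @param sources list of \code{\link{scene_source}} objects.
#' @param duration scene duration, seconds.
#' @param fs sample rate, Hz (default 100 kHz).
#' @param sea_state ambient sea state (default 0).
#' @param noise a \code{\link{noise_model}}.
#' @param seed RNG seed; fixing it makes rendering bit-exact reproducible.
#' @return object of class \code{scene}.
#' @export
scene <- function(sources, duration, fs = 100e3, sea_state = 0,
                  noise = noise_model(), seed = NULL) {
  structure(list(sources = sources, duration = duration, fs = fs,
                 sea_state = sea_state, noise = noise, seed = seed),
            class = "scene")
}

#' Scene unit: an acoustic unit placed in the scene
#'
#' @param name unit name.
#' @param pos 2-vector (east, north) of the unit in the local ENU frame,
#'   metres.
#' @param depth array depth, metres (positive down, default 20).
#' @param psi0 compass offset, degrees.
#' @param attitude_fun function(t) returning an \code{\link{attitude}};
#'   default a static zero attitude. Use \code{\link{wobble_attitude}} for a
#'   slowly rocking buoy.
#' @return object of class \code{scene_unit}.
#' @export
scene_unit <- function(name, pos = c(0, 0), depth = 20, psi0 = 0,
                       attitude_fun = NULL) {
  if (is.null(attitude_fun))
    attitude_fun <- function(t) attitude(0, 0, 0, psi0 = psi0, time = t)
  structure(list(name = name, pos = pos, depth = depth, psi0 = psi0,
                 attitude_fun = attitude_fun), class = "scene_unit")
}

#' Slowly wobbling attitude generator
#'
#' Sinusoidal pitch/roll rocking and compass drift emulating a moored spar
#' buoy in mild sea.
#'
#' @param pitch_amp,roll_amp rocking amplitudes, degrees.
#' @param compass0 mean heading, degrees.
#' @param compass_amp heading oscillation amplitude, degrees.
#' @param period rocking period, seconds.
#' @param psi0 compass offset, degrees.
#' @return function(t) returning an \code{\link{attitude}}.
#' @export
wobble_attitude <- function(pitch_amp = 2, roll_amp = 2, compass0 = 0,
                            compass_amp = 5, period = 8, psi0 = 0) {
  function(t) {
    attitude(pitch = pitch_amp * sin(2 * pi * t / period),
             roll = roll_amp * sin(2 * pi * t / period + 1),
             compass = (compass0 + compass_amp * sin(2 * pi * t / (3 * period))) %% 360,
             psi0 = psi0, time = t)
  }
}

# windowed-sinc fractional delay kernel, 64 taps
frac_delay_kernel <- function(mu, taps = 64) {
  k <- seq(-taps / 2 + 1, taps / 2)
  h <- sinc(k - mu) * hann_window(taps, centered = TRUE)
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

hann_window <- function(n, centered = FALSE) {
  if (centered) {
    k <- seq(-n / 2 + 1, n / 2)
    0.5 * (1 + cos(2 * pi * k / n))
  } else {
    0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  }
}

# delay waveform w to fractional sample position 'at'; returns the filtered
# waveform and the integer sample index of its first sample
delayed_waveform <- function(w, at, taps = 64) {
  i0 <- floor(at)
  mu <- at - i0
  h <- frac_delay_kernel(mu, taps)
  nw <- length(w)
  xp <- c(rep(0, taps - 1), w, rep(0, taps - 1))
  wd <- stats::filter(xp, h, method = "convolution", sides = 1)
  list(start = i0 - (taps / 2 - 1),
       w = as.numeric(wd[taps:(2 * (taps - 1) + nw)]))
}

source_waveform <- function(src, fs) {
  switch(src$type,
    whistle = synth_whistle(src$spec, fs),
    clicks = synth_clicks(src$spec$rate, fs, src$duration,
                          SL = if (!is.null(src$spec$SL)) src$spec$SL else 170),
    boat = synth_boat(src$spec, fs, src$duration)
  )
}

source_level_db <- function(src) {
  if (!is.null(src$spec$SL)) src$spec$SL else 170
}

#' Render a scene at a set of acoustic units
#'
#' Each source contributes to each hydrophone as a plane wave arriving from
#' the source direction: per-channel delays are \eqn{(H_i \cdot \hat n)/c}
#' (windowed-sinc fractional-delay interpolation) on top of the common
#' range/c arrival time, and the amplitude is scaled by the spherical
#' spreading + absorption transmission loss. Sea-state ambient noise is added
#' independently per channel. Sources inside 100 m of a unit violate the
#' plane-wave approximation; they are still rendered but a warning is
#' recorded in the output.
#'
#' Moving sources are rendered block-wise (constant direction within a
#' block). Whistle and click events use the geometry at the event mid-time.
#'
#' @param sc a \code{\link{scene}}.
#' @param units list of \code{\link{scene_unit}} objects.
#' @param geom an \code{\link{array_geometry}}.
#' @param c_sound sound speed, m/s.
#' @param k,alpha transmission-loss parameters (see
#'   \code{\link{transmission_loss}}).
#' @param block block length for moving sources, seconds.
#' @param att_rate attitude log rate, Hz (default 5: tilt-compass devices
#'   sample continuously; the log must resolve the buoy rocking period).
#' @return list with one entry per unit: \code{x} (samples x 4 pressure
#'   matrix, uPa), \code{attitude} (data.frame log), \code{truth}
#'   (data.frame of per-source ground truth: time, bearing, elevation, range,
#'   position, expected per-pair TDOAs), \code{warnings} (character).
#' @export
render_scene <- function(sc, units, geom = array_geometry(), c_sound = 1500,
                         k = 20, alpha = 0.72, block = 0.05, att_rate = 5) {
  if (!is.null(sc$seed)) set.seed(sc$seed)
  fs <- sc$fs
  n <- round(sc$duration * fs)
  out <- list()
  for (u in units) {
    X <- matrix(synth_ambient(sc$sea_state, fs, sc$duration, sc$noise),
                n, 4)
    for (ch in 2:4) X[, ch] <- synth_ambient(sc$sea_state, fs, sc$duration,
                                             sc$noise)
    truth <- list(); warns <- character(0)
    for (src in sc$sources) {
      w <- source_waveform(src, fs)
      if (length(w) == 0) next
      blk <- if (src$type == "boat") block else src$duration
      nblk <- max(1, ceiling(src$duration / blk))
      bounds <- round(seq(0, length(w), length.out = nblk + 1))
      for (b in seq_len(nblk)) {
        s0 <- bounds[b] + 1; s1 <- bounds[b + 1]
        if (s1 < s0) next
        t_mid <- src$t0 + (s0 + s1) / 2 / fs
        pos <- source_position(src, t_mid)
        rel <- c(pos[1] - u$pos[1], pos[2] - u$pos[2],
                 -(pos[3] - u$depth))     # ENU, array origin; z up
        r <- sqrt(sum(rel^2))
        # the array orientation that matters is the one at reception time
        att <- u$attitude_fun(t_mid + r / c_sound)
        if (r < 100)
          warns <- c(warns, sprintf(
            "source %s at %.0f m from unit %s: inside plane-wave validity range",
            src$id, r, u$name))
        s_hat <- rel / r                   # unit vector toward source, world
        n_hat <- -s_hat                    # propagation direction, world
        Hw <- geom$H %*% t(attitude_rotation(att))  # hydrophones in world
        amp <- 10^(-transmission_loss(max(r, 1), k, alpha) / 20)
        delays <- (Hw %*% n_hat) / c_sound
        at0 <- (src$t0 + (s0 - 1) / fs + r / c_sound) * fs + 1
        wseg <- amp * w[s0:s1]
        for (ch in 1:4) {
          dw <- delayed_waveform(wseg, at0 + delays[ch] * fs)
          idx <- dw$start + seq_along(dw$w) - 1
          ok <- idx >= 1 & idx <= n
          X[idx[ok], ch] <- X[idx[ok], ch] + dw$w[ok]
        }
        if (src$type != "boat" || b == 1 || b %% 4 == 1) {
          td <- expected_tdoas(n_hat, geom, c_sound, H = Hw)
          truth[[length(truth) + 1]] <- data.frame(
            source = src$id, time = t_mid,
            bearing_deg = enu_bearing(s_hat),
            elevation_deg = rad2deg(acos(max(-1, min(1, s_hat[3])))),
            range_m = r, east = pos[1], north = pos[2], depth = pos[3],
            arrival_time = src$t0 + r / c_sound,
            t(td))
        }
      }
    }
    att_t <- seq(0, sc$duration, by = 1 / att_rate)
    att_log <- do.call(rbind, lapply(att_t, function(ti) {
      a <- u$attitude_fun(ti)
      data.frame(time = ti, pitch = a$pitch, roll = a$roll,
                 compass = a$compass)
    }))
    out[[u$name]] <- list(x = X, fs = fs,
                          attitude = att_log,
                          truth = if (length(truth)) do.call(rbind, truth)
                                  else NULL,
                          warnings = warns, unit = u)
  }
  out
}

#' Write a rendered unit to WAV + CSV + JSON-lines ground truth
#'
#' @param rendered one entry of the list returned by
#'   \code{\link{render_scene}}.
#' @param dir output directory (created if needed).
#' @param full_scale pressure mapped to digital full scale, uPa
#'   (default 1e6).
#' @return invisibly, the paths written.
#' @export
write_rendered_unit <- function(rendered, dir, full_scale = 1e6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  name <- rendered$unit$name
  wav <- file.path(dir, paste0(name, ".wav"))
  write_wav(rendered$x / full_scale, wav, rendered$fs)
  att <- file.path(dir, paste0(name, "_attitude.csv"))
  write_attitude_log(rendered$attitude, att)
  gt <- file.path(dir, paste0(name, "_truth.jsonl"))
  con <- file(gt, "w")
  if (!is.null(rendered$truth))
    for (i in seq_len(nrow(rendered$truth)))
      writeLines(jsonlite::toJSON(as.list(rendered$truth[i, ]),
                                  auto_unbox = TRUE, digits = NA), con)
  close(con)
  invisible(c(wav = wav, attitude = att, truth = gt))
}
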