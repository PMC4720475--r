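# Synthetic source waveforms. Pressures are in linear uPa so that source and
# received levels stay on the dB re 1 uPa scale used by the sonar budget.

#' Convert a level in dB re 1 uPa to an RMS pressure
#' @param db level in dB.
#' @return RMS pressure in uPa.
#' @export
db_to_pressure <- function(db) 10^(db / 20)

#' Pressure (RMS) to dB re 1 uPa
#' @param p RMS pressure, uPa.
#' @return level in dB.
#' @export
pressure_to_db <- function(p) 20 * log10(p)

whistle_shapes <- c("flat", "rise", "fall", "concave", "convex", "sine",
                    "multiloop")

#' Whistle specification
#'
#' Parameters of one frequency-modulated tonal call. The seven contour shapes
#' cover the canonical bottlenose-dolphin whistle repertoire: flat, rising,
#' falling, concave (dip), convex (hump), single sinusoidal loop and
#' multi-loop.
#'
#' @param shape one of \code{"flat"}, \code{"rise"}, \code{"fall"},
#'   \code{"concave"}, \code{"convex"}, \code{"sine"}, \code{"multiloop"}.
#' @param f_start,f_end contour start/end frequency, Hz (default within the
#'   5--15 kHz communication band).
#' @param duration seconds (> 0; 0 is allowed and yields an empty waveform).
#' @param SL source level, dB re 1 uPa at 1 m (default 160).
#' @param excursion modulation depth in Hz for the curved shapes (default
#'   a quarter of the band).
#' @param n_loops loop count for \code{"multiloop"} (default 3).
#' @param wander slow natural frequency wander in Hz added as a gentle arc
#'   to every contour (default 0: exact geometric contour). Real whistles,
#'   including nominally flat ones, are never spectrally pure.
#' @return object of class \code{whistle_spec}.
#' @export
whistle_spec <- function(shape = "flat", f_start = 10e3, f_end = f_start,
                         duration = 0.5, SL = 160, excursion = 2.5e3,
                         n_loops = 3, wander = 0) {
  shape <- match.arg(shape, whistle_shapes)
  stopifnot(duration >= 0, f_start > 0, f_end > 0, wander >= 0)
  structure(list(shape = shape, f_start = f_start, f_end = f_end,
                 duration = duration, SL = SL, excursion = excursion,
                 n_loops = n_loops, wander = wander), class = "whistle_spec")
}

#' Instantaneous-frequency contour of a whistle spec
#'
#' @param spec a \code{\link{whistle_spec}}.
#' @param t times in seconds within [0, duration].
#' @return frequencies in Hz.
#' @export
whistle_contour <- function(spec, t) {
  T <- spec$duration
  u <- if (T > 0) t / T else t * 0
  f0 <- spec$f_start; f1 <- spec$f_end
  w <- if (!is.null(spec$wander)) spec$wander else 0
  base <- f0 + (f1 - f0) * u + w * sin(pi * u)
  switch(spec$shape,
    flat = base,
    rise = base,
    fall = base,
    concave = base - spec$excursion * sin(pi * u),
    convex = base + spec$excursion * sin(pi * u),
    sine = base + spec$excursion * sin(2 * pi * u),
    multiloop = base + spec$excursion * sin(2 * pi * spec$n_loops * u)
  )
}

raised_cosine_taper <- function(n, n_taper) {
  env <- rep(1, n)
  m <- min(n_taper, floor(n / 2))
  if (m > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(m) / (m + 1)))
    env[seq_len(m)] <- ramp
    env[n - m + seq_len(m)] <- rev(ramp)
  }
  env
}

#' Synthesize a whistle waveform
#'
#' FM tone whose instantaneous frequency follows the contour of the spec,
#' with a 10 ms raised-cosine onset/offset taper. The RMS pressure of the
#' untapered tone equals \code{db_to_pressure(spec$SL)}.
#'
#' @param spec a \code{\link{whistle_spec}}.
#' @param fs sample rate, Hz.
#' @return numeric vector of pressures (uPa); empty for zero duration.
#' @export
synth_whistle <- function(spec, fs = 100e3) {
  n <- round(spec$duration * fs)
  if (n == 0) return(numeric(0))
  t <- (seq_len(n) - 1) / fs
  f <- whistle_contour(spec, t)
  if (any(f >= fs / 2)) stop("whistle contour exceeds Nyquist frequency")
  if (any(f <= 0)) stop("whistle contour must stay positive")
  phase <- 2 * pi * cumsum(f) / fs
  a <- sqrt(2) * db_to_pressure(spec$SL)
  a * sin(phase) * raised_cosine_taper(n, round(0.010 * fs))
}

#' Synthesize an echolocation click train
#'
#' Regularly spaced broadband transients: Gaussian-enveloped high-frequency
#' pulses (~0.1 ms), spectrally wide-band within the sampled bandwidth.
#'
#' @param rate clicks per second.
#' @param fs sample rate, Hz.
#' @param duration seconds.
#' @param SL peak-equivalent source level, dB re 1 uPa at 1 m.
#' @param f_center carrier frequency, Hz (default 30 kHz).
#' @return numeric vector of pressures (uPa).
#' @export
synth_clicks <- function(rate, fs = 100e3, duration = 1, SL = 170,
                         f_center = 30e3) {
  n <- round(duration * fs)
  x <- numeric(n)
  if (rate <= 0 || n == 0) return(x)
  peak <- db_to_pressure(SL)
  half <- round(0.2e-3 * fs)            # half support of one click
  k <- seq(-half, half)
  pulse <- peak * exp(-0.5 * (k / (0.05e-3 * fs))^2) * cos(2 * pi * f_center * k / fs)
  centers <- round(seq(fs / rate / 2, n, by = fs / rate))
  for (c0 in centers) {
    idx <- c0 + k
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + pulse[ok]
  }
  x
}

#' Boat-engine source specification
#'
#' Harmonic comb at the engine firing rate plus a broadband cavitation floor.
#'
#' @param f0 fundamental engine frequency, Hz (> 0).
#' @param n_harmonics number of comb harmonics.
#' @param broadband_frac fraction of total power in the broadband component
#'   (in [0, 1]).
#' @param SL total source level, dB re 1 uPa at 1 m.
#' @return object of class \code{boat_spec}.
#' @export
boat_spec <- function(f0 = 120, n_harmonics = 10, broadband_frac = 0.5,
                      SL = 170) {
  stopifnot(f0 > 0, n_harmonics >= 1, broadband_frac >= 0, broadband_frac <= 1)
  structure(list(f0 = f0, n_harmonics = n_harmonics,
                 broadband_frac = broadband_frac, SL = SL),
            class = "boat_spec")
}

#' Synthesize a boat-engine waveform
#'
#' Harmonic comb with 1/k amplitude roll-off plus band-limited Gaussian
#' broadband noise; total RMS pressure matches \code{spec$SL}.
#'
#' @param spec a \code{\link{boat_spec}}.
#' @param fs sample rate, Hz.
#' @param duration seconds.
#' @return numeric vector of pressures (uPa).
#' @export
synth_boat <- function(spec, fs = 100e3, duration = 1) {
  n <- round(duration * fs)
  if (n == 0) return(numeric(0))
  t <- (seq_len(n) - 1) / fs
  p_total <- db_to_pressure(spec$SL)^2   # total power
  k <- seq_len(spec$n_harmonics)
  comb <- numeric(n)
  ph <- stats::runif(spec$n_harmonics, 0, 2 * pi)
  amp2 <- (1 / k)^2; amp2 <- amp2 / sum(amp2)
  for (i in k) {
    a <- sqrt(2 * amp2[i] * p_total * (1 - spec$broadband_frac))
    comb <- comb + a * sin(2 * pi * spec$f0 * i * t + ph[i])
  }
  bb <- stats::rnorm(n)
  bb <- bb * sqrt(p_total * spec$broadband_frac) / stats::sd(bb)
  comb + bb
}

#' Synthesize sea ambient noise
#'
#' Spectrally flat Gaussian noise whose spectral density level equals the
#' noise model's entry for the given sea state, so that the band level over
#' any band B matches \code{band_noise_level(NL, ...)}.
#'
#' @param sea_state sea state key present in the noise model.
#' @param fs sample rate, Hz.
#' @param duration seconds.
#' @param nm a \code{\link{noise_model}}.
#' @return numeric vector of pressures (uPa).
#' @export
synth_ambient <- function(sea_state = 0, fs = 100e3, duration = 1,
                          nm = noise_model()) {
  n <- round(duration * fs)
  NL <- noise_spectral_level(nm, sea_state)
  sigma <- sqrt(10^(NL / 10) * fs / 2)   # flat PSD 10^(NL/10) uPa^2/Hz
  stats::rnorm(n, sd = sigma)
}

#' Band level of a waveform
#'
#' RMS level of the waveform restricted to a frequency band, via FFT power
#' integration; used to verify rendered noise and signal levels.
#'
#' @param x waveform (uPa).
#' @param fs sample rate, Hz.
#' @param f_min,f_max band edges, Hz.
#' @return level in dB re 1 uPa.
#' @export
band_level <- function(x, fs, f_min = 5e3, f_max = 15e3) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= f_min & f <= f_max & f <= fs / 2
  pw <- 2 * sum(Mod(X[keep])^2) / n^2    # one-sided band power
  10 * log10(pw)
}
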