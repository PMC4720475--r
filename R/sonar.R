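# Passive sonar equation and radio-link planning arithmetic.
#
# The passive sonar budget used throughout is
#   L_SN(r) = SL - (TL(r) + NL + BW)  >=  DT
# with TL(r) = k log10(r) + alpha r, NL the ambient spectral density at the
# band centroid and BW = 10 log10(B) the band integration term.

#' Geometric band centroid
#'
#' Centre frequency of a band taken as the geometric mean
#' \eqn{\sqrt{f_{min} f_{max}}}, the conventional reference frequency for
#' reading absorption and ambient-noise curves.
#'
#' @param f_min,f_max band edges in Hz, \code{f_max >= f_min > 0}.
#' @return centroid frequency, Hz.
#' @examples
#' band_centroid(5e3, 15e3)  # 8660 Hz
#' @export
band_centroid <- function(f_min, f_max) {
  if (f_min <= 0 || f_max < f_min) stop("need f_max >= f_min > 0")
  sqrt(f_min * f_max)
}

#' Detection threshold from the detection index
#'
#' With detection index \code{d} (separation of the signal+noise and
#' noise-only densities chosen from ROC curves) and \code{m = f_sampl/f_max}
#' samples per signal period, the required signal-to-noise ratio is
#' \code{S/N0 = d/m} and the threshold as a band level is
#' \code{DT = 10 log10(d/m)} dB.
#'
#' @param d detection index (> 0).
#' @param f_sampl sampling frequency, Hz.
#' @param f_max maximum signal frequency, Hz (< \code{f_sampl}).
#' @return list with \code{DT} (dB) and \code{SN0} (linear ratio).
#' @examples
#' detection_threshold(9, 100e3, 15e3)  # DT = 1.3 dB, S/N0 = 1.35
#' @export
detection_threshold <- function(d, f_sampl, f_max) {
  if (d <= 0) stop("detection index must be positive")
  m <- f_sampl / f_max
  if (!is.finite(m) || m <= 0) stop("invalid m = f_sampl/f_max")
  sn0 <- d / m
  list(DT = 10 * log10(sn0), SN0 = sn0)
}

#' One-way transmission loss
#'
#' \code{TL(r) = k log10(r) + alpha r}, with \code{r} in metres and
#' \code{alpha} in dB/km. Undefined below the 1 m reference distance.
#'
#' @param r range in metres (>= 1).
#' @param k spreading constant (20 for spherical spreading).
#' @param alpha absorption coefficient, dB/km.
#' @return loss in dB.
#' @export
transmission_loss <- function(r, k = 20, alpha = 0.72) {
  if (any(r < 1)) stop("transmission loss undefined below 1 m reference")
  k * log10(r) + alpha * r / 1000
}

#' Band-integrated noise level
#'
#' Adds the bandwidth term 10 log10(B) to a spectral density level.
#'
#' @param NL_spectral spectral density level at the band centroid,
#'   dB re 1 uPa / sqrt(Hz).
#' @param f_min,f_max band edges, Hz.
#' @return band level in dB.
#' @examples
#' band_noise_level(29, 5e3, 15e3)  # 69 dB (sea state 0)
#' band_noise_level(48, 5e3, 15e3)  # 88 dB (sea state 4)
#' @export
band_noise_level <- function(NL_spectral, f_min, f_max) {
  if (f_max <= f_min) stop("empty band")
  NL_spectral + 10 * log10(f_max - f_min)
}

#' Sonar parameter set
#'
#' @param SL source level, dB re 1 uPa at 1 m.
#' @param f_min,f_max signal band, Hz.
#' @param k spreading constant.
#' @param alpha absorption, dB/km.
#' @param DT detection threshold, dB.
#' @param f_sampl sampling frequency, Hz.
#' @param d detection index.
#' @return object of class \code{sonar_params}.
#' @export
sonar_params <- function(SL = 160, f_min = 5e3, f_max = 15e3, k = 20,
                         alpha = 0.72, DT = 5, f_sampl = 100e3, d = 9) {
  stopifnot(f_max > f_min, f_min > 0, k > 0, alpha >= 0)
  structure(list(SL = SL, f_min = f_min, f_max = f_max, k = k, alpha = alpha,
                 DT = DT, f_sampl = f_sampl, d = d), class = "sonar_params")
}

#' Ambient-noise model (Wenz-style table)
#'
#' Spectral density levels at the band centroid keyed by sea state, plus an
#' optional wide-band offset applied to every entry (e.g. a measured local
#' excess over the canonical curves). Values are configuration data read off
#' reference curves, not computed.
#'
#' @param levels named numeric vector: names are sea states ("0", "4", ...),
#'   values spectral density levels in dB re 1 uPa / sqrt(Hz) at the centroid.
#' @param offset wide-band offset in dB added to every level (default 0).
#' @return object of class \code{noise_model}.
#' @export
noise_model <- function(levels = c("0" = 29, "4" = 48), offset = 0) {
  v <- as.numeric(levels)
  o <- order(as.numeric(names(levels)))
  if (is.unsorted(v[o])) stop("noise levels must be non-decreasing in sea state")
  structure(list(levels = levels, offset = offset), class = "noise_model")
}

#' Spectral noise level for a sea state
#' @param nm a \code{\link{noise_model}}.
#' @param sea_state sea state key (number or string present in the table).
#' @return spectral density level in dB (table value plus offset).
#' @export
noise_spectral_level <- function(nm, sea_state) {
  key <- as.character(sea_state)
  if (!key %in% names(nm$levels)) stop("sea state ", key, " not in noise table")
  unname(nm$levels[[key]]) + nm$offset
}

#' Maximum detection range from the passive sonar budget
#'
#' Solves \code{SL - TL(r) - NL_band = DT} for the range \code{r}. TL is
#' strictly increasing so the root is unique; it is bracketed on
#' [1 m, 100 km] and bisected to 0.1 m.
#'
#' @param params a \code{\link{sonar_params}}.
#' @param NL_band band-integrated noise level, dB.
#' @return range in metres, or \code{NA} with attribute
#'   \code{undetectable = TRUE} when the budget is negative already at 1 m.
#' @examples
#' p <- sonar_params()
#' detection_range(p, band_noise_level(29, p$f_min, p$f_max))  # ~9200 m
#' @export
detection_range <- function(params, NL_band) {
  budget <- function(r) params$SL - transmission_loss(r, params$k, params$alpha) -
    NL_band - params$DT
  if (budget(1) < 0) return(structure(NA_real_, undetectable = TRUE))
  if (budget(1) == 0) return(1)
  lo <- 1; hi <- 1e5
  if (budget(hi) > 0) return(hi)
  while (hi - lo > 0.1) {
    mid <- (lo + hi) / 2
    if (budget(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Radio horizon distance
#'
#' Line-of-sight horizon from antenna height \code{h}:
#' \code{D = sqrt(2 R h)} for \code{h << R}.
#'
#' @param h antenna height in metres.
#' @param R_km Earth radius in km (default 6371).
#' @return horizon distance in km.
#' @export
radio_horizon <- function(h, R_km = 6371) {
  stopifnot(h >= 0)
  sqrt(2 * R_km * h / 1000)
}

#' First Fresnel zone radius
#'
#' \code{r = 17.31 sqrt(d1 d2 / (f d))} metres, with distances in km and
#' frequency in GHz.
#'
#' @param d1,d2 distances from the obstacle to each link end, km.
#' @param f_GHz link frequency, GHz.
#' @param d total link distance, km (defaults to d1 + d2).
#' @return radius in metres.
#' @export
fresnel_radius <- function(d1, d2, f_GHz, d = d1 + d2) {
  if (f_GHz <= 0) stop("frequency must be positive")
  stopifnot(d > 0, d1 >= 0, d2 >= 0)
  17.31 * sqrt(d1 * d2 / (f_GHz * d))
}

#' Free-space path loss
#'
#' \code{L_FS = 32.45 + 20 log10(D_km) + 20 log10(f_MHz)} dB.
#'
#' @param D_km link distance, km (>= 0.001).
#' @param f_MHz frequency, MHz.
#' @return loss in dB.
#' @export
free_space_loss <- function(D_km, f_MHz) {
  stopifnot(D_km >= 0.001, f_MHz > 0)
  32.45 + 20 * log10(D_km) + 20 * log10(f_MHz)
}

#' Radio link budget
#'
#' \code{P_RX = P_TX - C_LS + G_TX - L_FS + G_RX - C_LS_RX}; the margin over
#' a receiver sensitivity is \code{P_RX - sensitivity}.
#'
#' @param Ptx transmitter power, dBm.
#' @param Cls transmitter-side cable loss, dB.
#' @param Gtx,Grx antenna gains, dBi.
#' @param Lfs free-space loss, dB (see \code{\link{free_space_loss}}).
#' @param Cls_rx receiver-side cable loss, dB (default \code{Cls}).
#' @param sensitivity optional receiver sensitivity, dBm.
#' @return list with \code{Prx} (dBm) and, when a sensitivity is given,
#'   \code{margin} (dB).
#' @export
link_budget <- function(Ptx, Cls = 0, Gtx = 0, Lfs = 0, Grx = 0,
                        Cls_rx = Cls, sensitivity = NULL) {
  Prx <- Ptx - Cls + Gtx - Lfs + Grx - Cls_rx
  out <- list(Prx = Prx)
  if (!is.null(sensitivity)) out$margin <- Prx - sensitivity
  out
}

#' Minimum raw-stream bandwidth
#'
#' Product of sample rate, channel count and bit depth.
#'
#' @param f_sampl samples per second per channel.
#' @param n_channels number of channels.
#' @param bits bits per sample.
#' @return bit/s.
#' @examples
#' min_stream_bandwidth(100e3, 4, 16)  # 6.4e6 bit/s
#' @export
min_stream_bandwidth <- function(f_sampl, n_channels, bits) {
  stopifnot(f_sampl > 0, n_channels > 0, bits > 0)
  f_sampl * n_channels * bits
}

#' Sonar budget summary table
#'
#' Detection ranges for every sea state in a noise model at the given sonar
#' parameters.
#'
#' @param params a \code{\link{sonar_params}}.
#' @param nm a \code{\link{noise_model}}.
#' @return data.frame with sea state, spectral and band noise levels, and
#'   detection range.
#' @export
sonar_budget_table <- function(params = sonar_params(), nm = noise_model()) {
  ss <- names(nm$levels)
  rows <- lapply(ss, function(s) {
    nl <- noise_spectral_level(nm, s)
    nb <- band_noise_level(nl, params$f_min, params$f_max)
    data.frame(sea_state = s, NL_spectral = nl, NL_band = nb,
               range_m = as.numeric(detection_range(params, nb)))
  })
  do.call(rbind, rows)
}
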