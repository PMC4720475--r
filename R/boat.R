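# Continuous boat bearing estimation from the two orthogonal hydrophone
# pairs. Pair (H0,H2) lies along body x, pair (H1,H3) along body y, so with
# alpha the body-frame azimuth of the source measured from body x,
#   dT20 = t0 - t2 = Lc cos(alpha),  dT31 = t1 - t3 = Lc sin(alpha).
# Each pair alone leaves a mirror ambiguity, removed by multiplying the two
# per-pair probability densities.

#' Streaming per-pair TDOAs (correlogram)
#'
#' Splits the four channels into short windows (default 8 ms, about twice
#' the maximum pair delay) and measures the gated TDOA of each orthogonal
#' pair per window. Windows whose correlation peak does not exceed the
#' adaptive threshold (\code{n_sigma} standard deviations of the correlation
#' values) are recorded as no-data (NA).
#'
#' @param X samples x 4 channel matrix.
#' @param fs sample rate, Hz.
#' @param Lc pair travel time L/c, seconds.
#' @param window window length, seconds (default 8 ms).
#' @param hop window hop, seconds (default = window, non-overlapping).
#' @param n_sigma adaptive gate multiplier (default 4).
#' @param filter apply the whistle-band bandpass first (default TRUE).
#' @return data.frame: \code{time} (window centre, s), \code{dT20},
#'   \code{dT31} (s, NA when gated), \code{peak20}, \code{peak31}.
#' @export
correlogram_stream <- function(X, fs, Lc = 5 / 1500, window = 8e-3,
                               hop = window, n_sigma = 4, filter = TRUE) {
  stopifnot(ncol(X) == 4, window >= 2 * Lc)
  if (filter) X <- apply(X, 2, bandpass, fs = fs)
  wl <- round(window * fs); hl <- round(hop * fs)
  ml <- ceiling(Lc * fs) + 2
  starts <- seq(1, nrow(X) - wl + 1, by = hl)
  res <- lapply(starts, function(s0) {
    idx <- s0:(s0 + wl - 1)
    out <- c(NA_real_, NA_real_, 0, 0)
    # dT20 = t0 - t2 = delay of ch0 relative to ch2
    cc20 <- xcorr_fft(X[idx, 3], X[idx, 1], ml)
    g20 <- adaptive_peak_gate(cc20$vals, n_sigma)
    if (g20$peak > 0) {
      i <- g20$index
      out[1] <- (cc20$lags[i] + parabolic_peak(cc20$vals, i)) / fs
      out[3] <- g20$peak
    }
    cc31 <- xcorr_fft(X[idx, 4], X[idx, 2], ml)
    g31 <- adaptive_peak_gate(cc31$vals, n_sigma)
    if (g31$peak > 0) {
      i <- g31$index
      out[2] <- (cc31$lags[i] + parabolic_peak(cc31$vals, i)) / fs
      out[4] <- g31$peak
    }
    out
  })
  m <- do.call(rbind, res)
  data.frame(time = (starts - 1 + wl / 2) / fs,
             dT20 = m[, 1], dT31 = m[, 2], peak20 = m[, 3], peak31 = m[, 4])
}

#' Candidate azimuths from the two pair TDOAs
#'
#' Inverts the pair forward model: \code{alpha20 = arccos(dT20/Lc)} with
#' mirror \code{2 pi - alpha20}; \code{alpha31 = arcsin(dT31/Lc)} with
#' mirror \code{pi - alpha31}. TDOAs exceeding Lc by at most \code{tol} are
#' clipped (the arccos/arcsin argument saturates); beyond that the sample is
#' discarded.
#'
#' @param dT20,dT31 measured pair TDOAs, seconds.
#' @param Lc pair travel time, seconds.
#' @param tol clipping tolerance, seconds (default 2 samples at 100 kHz).
#' @return list with \code{a20} (real, mirror), \code{a31} (real, mirror),
#'   radians in [0, 2 pi), \code{clipped} logical; or NULL when a TDOA is
#'   out of range beyond tolerance.
#' @export
angles_from_tdoas <- function(dT20, dT31, Lc, tol = 2e-5) {
  if (!is.finite(dT20) || !is.finite(dT31)) return(NULL)
  if (abs(dT20) > Lc + tol || abs(dT31) > Lc + tol) return(NULL)
  clipped <- abs(dT20) > Lc || abs(dT31) > Lc
  c20 <- max(-1, min(1, dT20 / Lc))
  c31 <- max(-1, min(1, dT31 / Lc))
  a20 <- acos(c20)
  a31 <- asin(c31)
  list(a20 = c(a20, (2 * pi - a20) %% (2 * pi)),
       a31 = c(a31 %% (2 * pi), (pi - a31) %% (2 * pi)),
       clipped = clipped)
}

#' Propagated angular error of a pair TDOA
#'
#' Error propagation through arccos: \code{dalpha = dtau / (Lc sqrt(1 -
#' (tau/Lc)^2))} radians. Diverges as tau approaches Lc (the pair's
#' degenerate axis); returns Inf at |tau| >= Lc.
#'
#' @param tau measured TDOA, seconds.
#' @param Lc pair travel time, seconds.
#' @param dtau TDOA resolution, seconds (default one sample at 100 kHz).
#' @return error in radians.
#' @export
angular_error <- function(tau, Lc, dtau = 1e-5) {
  if (abs(tau) >= Lc) return(Inf)
  (dtau / Lc) / sqrt(1 - (tau / Lc)^2)
}

wrapped_gauss <- function(a, center, sd) {
  d <- (a - center + pi) %% (2 * pi) - pi
  stats::dnorm(d, sd = sd) +
    stats::dnorm(d - 2 * pi, sd = sd) + stats::dnorm(d + 2 * pi, sd = sd)
}

#' Two-candidate pair density
#'
#' Circular mixture of two Gaussians centered at the real and mirror
#' candidate angles of one hydrophone pair.
#'
#' @param a evaluation angles, radians.
#' @param candidates 2-vector of candidate angles, radians.
#' @param sd standard deviation, radians.
#' @return density values.
#' @export
pair_density <- function(a, candidates, sd) {
  0.5 * (wrapped_gauss(a, candidates[1], sd) +
         wrapped_gauss(a, candidates[2], sd))
}

circ_dist <- function(a, b) abs((a - b + pi) %% (2 * pi) - pi)

#' Resolve the left/right ambiguity by density product
#'
#' Each pair contributes a circular two-Gaussian mixture (real + mirror
#' candidate) with standard deviation 4 times its propagated angular error;
#' the product of the two pair densities over azimuth suppresses the mirror
#' solutions. The combined angular error is the smaller of the two pair
#' errors (the better-conditioned pair dominates).
#'
#' @param cand candidate list from \code{\link{angles_from_tdoas}}.
#' @param dalpha20,dalpha31 per-pair angular errors, radians.
#' @param sigma_factor multiplier from error to mixture sd (default 4).
#' @return list with \code{alpha} (radians in [0, 2 pi)), \code{dalpha}
#'   (radians), \code{ok}; \code{ok = FALSE} when the pair densities are
#'   mutually inconsistent (product vanishes everywhere).
#' @export
resolve_ambiguity <- function(cand, dalpha20, dalpha31, sigma_factor = 4) {
  s20 <- sigma_factor * dalpha20
  s31 <- sigma_factor * dalpha31
  # degenerate pair: infinite error means that pair carries no information
  if (!is.finite(s20) && !is.finite(s31))
    return(list(alpha = NA_real_, dalpha = Inf, ok = FALSE))
  f <- function(a) {
    d <- 1
    if (is.finite(s20)) d <- d * pair_density(a, cand$a20, s20)
    if (is.finite(s31)) d <- d * pair_density(a, cand$a31, s31)
    d
  }
  # start near the closest (a20, a31) candidate combination
  combos <- expand.grid(a = cand$a20, b = cand$a31)
  dists <- mapply(circ_dist, combos$a, combos$b)
  k <- which.min(dists)
  a0 <- combos$a[k]; b0 <- combos$b[k]
  mid <- a0 + ((b0 - a0 + pi) %% (2 * pi) - pi) / 2
  span <- max(circ_dist(a0, b0), 3 * min(s20, s31, pi / 4), 0.02)
  opt <- stats::optimize(f, interval = c(mid - span, mid + span),
                         maximum = TRUE, tol = 1e-6)
  peak_bound <- 1 / (2 * pi * max(min(s20, s31), 1e-9)^2)
  ok <- opt$objective > peak_bound * exp(-12)
  list(alpha = opt$maximum %% (2 * pi), dalpha = min(dalpha20, dalpha31),
       ok = ok)
}

#' Elevation correction of an extremal pair TDOA
#'
#' For a target at range R and pair depth h the measured extremal TDOA is
#' reduced by cos(beta) with \code{beta = arctan(h/R)}; this divides it back
#' out (calibration context, where R is known).
#'
#' @param dT measured TDOA, seconds.
#' @param h_pair pair depth relative to the target plane, metres (sign
#'   irrelevant).
#' @param R target range, metres.
#' @return corrected TDOA, seconds.
#' @export
elevation_correction <- function(dT, h_pair, R) {
  stopifnot(R > 0)
  dT / cos(atan(h_pair / R))
}

#' Continuous boat bearing stream
#'
#' Full boat-tracking step for one unit: correlogram, candidate angles,
#' error propagation, ambiguity resolution and rotation to a world compass
#' bearing by the attitude log.
#'
#' @param X samples x 4 channel matrix.
#' @param fs sample rate, Hz.
#' @param Lc pair travel time, seconds.
#' @param attitude_log data.frame (see \code{\link{read_attitude_log}}) or
#'   NULL for a static zero attitude.
#' @param psi0 compass offset, degrees.
#' @param n_sigma adaptive gate multiplier.
#' @param dtau TDOA resolution for error propagation, seconds (default one
#'   sample period).
#' @param window,hop correlogram windowing, seconds.
#' @return data.frame: \code{time}, \code{azimuth_deg} (world compass),
#'   \code{alpha_body_deg}, \code{error_deg}, \code{ok}.
#' @export
boat_bearing_stream <- function(X, fs, Lc = 5 / 1500, attitude_log = NULL,
                                psi0 = 0, n_sigma = 4, dtau = 1 / fs,
                                window = 8e-3, hop = window) {
  cg <- correlogram_stream(X, fs, Lc, window, hop, n_sigma)
  rows <- lapply(seq_len(nrow(cg)), function(i) {
    ti <- cg$time[i]
    fail <- data.frame(time = ti, azimuth_deg = NA_real_,
                       alpha_body_deg = NA_real_, error_deg = NA_real_,
                       ok = FALSE)
    cand <- angles_from_tdoas(cg$dT20[i], cg$dT31[i], Lc)
    if (is.null(cand)) return(fail)
    e20 <- angular_error(cg$dT20[i], Lc, dtau)
    e31 <- angular_error(cg$dT31[i], Lc, dtau)
    r <- resolve_ambiguity(cand, e20, e31)
    if (!r$ok) return(fail)
    att <- if (!is.null(attitude_log)) attitude_at(attitude_log, ti, psi0)
           else attitude(0, 0, 0, psi0)
    if (is.null(att)) return(fail)
    s_body <- c(cos(r$alpha), sin(r$alpha), 0)
    az <- enu_bearing(body_to_world(s_body, att))
    data.frame(time = ti, azimuth_deg = az,
               alpha_body_deg = rad2deg(r$alpha),
               error_deg = rad2deg(r$dalpha), ok = TRUE)
  })
  do.call(rbind, rows)
}

#' Aggregate a bearing stream to one sample per second
#'
#' Circular mean of the valid window bearings in each one-second bin.
#'
#' @param stream data.frame from \code{\link{boat_bearing_stream}}.
#' @return data.frame: \code{time} (bin centre), \code{azimuth_deg},
#'   \code{error_deg} (median), \code{n} windows used.
#' @export
aggregate_bearing_stream <- function(stream) {
  s <- stream[stream$ok, , drop = FALSE]
  if (!nrow(s)) return(data.frame(time = numeric(0), azimuth_deg = numeric(0),
                                  error_deg = numeric(0), n = integer(0)))
  bin <- floor(s$time)
  out <- lapply(split(s, bin), function(d) {
    a <- deg2rad(d$azimuth_deg)
    data.frame(time = mean(d$time),
               azimuth_deg = rad2deg(atan2(mean(sin(a)), mean(cos(a)))) %% 360,
               error_deg = stats::median(d$error_deg), n = nrow(d))
  })
  do.call(rbind, out)
}
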