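# Field calibration: recover the pair travel time L/c from the TDOA
# extrema of a boat circling the unit at known range, and the compass offset
# psi0 from the circular mean difference between GPS-derived and tracked
# bearings.

local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(diff(sign(diff(x))) != 0) + 1L
}

#' Estimate the pair travel time L/c from circling-boat TDOAs
#'
#' During a lap around the unit each pair's TDOA series is sinusoid-like;
#' its extrema equal \code{+/- Lc cos(beta)} with beta the elevation of the
#' boat seen from that pair. The series is low-pass filtered to reject
#' window-level jitter, the local extrema are located, each extremal value
#' is corrected by 1/cos(beta) (see \code{\link{elevation_correction}}), and
#' Lc is the average of the corrected |extrema| over both pairs and all
#' laps.
#'
#' @param tdoa20,tdoa31 data.frames with columns \code{time}, \code{dT}
#'   (seconds; NA rows are dropped) for pairs (H0,H2) and (H1,H3).
#' @param R boat range, metres (default 150).
#' @param depth20,depth31 pair depths below the boat plane, metres
#'   (default 20 and 25).
#' @param lp_cutoff low-pass cutoff, Hz (default 0.05).
#' @return list with \code{Lc} (seconds), \code{n_extrema}, and the per-pair
#'   corrected extrema.
#' @export
estimate_Lc <- function(tdoa20, tdoa31, R = 150, depth20 = 20, depth31 = 25,
                        lp_cutoff = 0.05) {
  one_pair <- function(d, h) {
    d <- d[is.finite(d$dT), , drop = FALSE]
    if (nrow(d) < 8) return(numeric(0))
    fs <- 1 / stats::median(diff(d$time))
    x <- d$dT
    margin <- 0
    if (lp_cutoff > 0 && lp_cutoff < fs / 2) {
      bf <- signal::butter(2, lp_cutoff / (fs / 2), type = "low")
      x <- signal::filtfilt(bf, x)
      margin <- 1 / lp_cutoff          # skip zero-phase filter edge transients
    }
    idx <- local_extrema(x)
    tmin <- d$time[1] + margin; tmax <- d$time[nrow(d)] - margin
    idx <- idx[d$time[idx] >= tmin & d$time[idx] <= tmax]
    # keep genuine lobe extrema, not jitter: magnitude above half the series max
    idx <- idx[abs(x[idx]) > 0.5 * max(abs(x))]
    abs(elevation_correction(x[idx], h, R))
  }
  e20 <- one_pair(tdoa20, depth20)
  e31 <- one_pair(tdoa31, depth31)
  ext <- c(e20, e31)
  if (length(ext) < 2) stop("calibration failed: fewer than 2 TDOA extrema")
  list(Lc = mean(ext), n_extrema = length(ext),
       extrema20 = e20, extrema31 = e31)
}

circular_mean_deg <- function(x) {
  rad2deg(atan2(mean(sin(deg2rad(x))), mean(cos(deg2rad(x)))))
}

circular_sd_deg <- function(x) {
  R <- sqrt(mean(sin(deg2rad(x)))^2 + mean(cos(deg2rad(x)))^2)
  rad2deg(sqrt(-2 * log(max(R, 1e-12))))
}

#' Estimate the compass offset psi0
#'
#' Compares the bearings of the calibration boat tracked acoustically (with
#' psi0 = 0) against bearings derived from its GPS track and the unit
#' position; the circular mean of the difference is the compass offset.
#' Tracked and GPS samples are matched by nearest timestamp within
#' \code{max_gap} seconds.
#'
#' @param tracked data.frame with columns \code{time}, \code{azimuth_deg}
#'   (acoustic bearings, world frame, psi0 not yet applied).
#' @param gps data.frame with columns \code{time}, \code{east}, \code{north}
#'   (boat positions, metres ENU) or \code{lat}, \code{lon} plus a
#'   \code{unit_latlon} reference.
#' @param unit_pos unit position, 2-vector (east, north) metres.
#' @param max_gap timestamp matching window, seconds (default 1).
#' @param max_dispersion circular standard deviation above which the
#'   calibration is rejected, degrees (default 20).
#' @return list with \code{psi0} (degrees in (-180, 180]),
#'   \code{dispersion} (degrees), \code{n} matched samples.
#' @export
estimate_psi0 <- function(tracked, gps, unit_pos = c(0, 0), max_gap = 1,
                          max_dispersion = 20) {
  diffs <- numeric(0)
  for (i in seq_len(nrow(tracked))) {
    k <- which.min(abs(gps$time - tracked$time[i]))
    if (abs(gps$time[k] - tracked$time[i]) > max_gap) next
    gb <- enu_bearing(c(gps$east[k] - unit_pos[1],
                        gps$north[k] - unit_pos[2], 0))
    diffs <- c(diffs, gb - tracked$azimuth_deg[i])
  }
  if (length(diffs) < 3) stop("calibration failed: too few matched samples")
  disp <- circular_sd_deg(diffs)
  if (disp > max_dispersion)
    stop(sprintf("calibration rejected: circular dispersion %.1f deg", disp))
  psi0 <- circular_mean_deg(diffs)
  if (psi0 > 180) psi0 <- psi0 - 360
  list(psi0 = psi0, dispersion = disp, n = length(diffs))
}

#' Read a GPS track CSV
#'
#' CSV with header \code{timestamp,lat,lon}; converts to ENU about the given
#' origin.
#'
#' @param path CSV path.
#' @param lat0,lon0 ENU origin, decimal degrees.
#' @return data.frame with \code{time}, \code{lat}, \code{lon}, \code{east},
#'   \code{north}.
#' @export
read_gps_track <- function(path, lat0, lon0) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  t <- suppressWarnings(as.numeric(d$timestamp))
  if (anyNA(t))
    t <- as.numeric(as.POSIXct(d$timestamp, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                              "%Y-%m-%d %H:%M:%OS")))
  en <- t(mapply(latlon_to_enu, d$lat, d$lon,
                 MoreArgs = list(lat0 = lat0, lon0 = lon0)))
  data.frame(time = t, lat = d$lat, lon = d$lon,
             east = en[, 1], north = en[, 2])
}
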