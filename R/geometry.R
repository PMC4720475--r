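#' Four-hydrophone array geometry
#'
#' Builds the body-frame geometry of the tetrahedral array carried by each
#' acoustic unit: two orthogonal hydrophone pairs at different depths. Pair
#' (H0, H2) lies along the body x axis at the upper level; pair (H1, H3) lies
#' along the body y axis, \code{depth_offset} metres deeper. The body frame is
#' right-handed with z up, so the deeper pair sits at negative z.
#'
#' @param L pair spacing in metres (distance between the two hydrophones of a
#'   pair; default 5 m).
#' @param depth_offset vertical separation between the two pair planes in
#'   metres (default 5 m).
#' @return An object of class \code{array_geometry}: a list with a 4 x 3
#'   matrix \code{H} of hydrophone positions (rows H0..H3, metres, body
#'   frame), \code{L}, and \code{depth_offset}.
#' @examples
#' g <- array_geometry()
#' g$H
#' @export
array_geometry <- function(L = 5, depth_offset = 5) {
  stopifnot(is.numeric(L), L > 0, is.numeric(depth_offset))
  h <- L / 2
  H <- rbind(
    H0 = c(-h, 0, 0),
    H1 = c(0, -h, -depth_offset),
    H2 = c(h, 0, 0),
    H3 = c(0, h, -depth_offset)
  )
  colnames(H) <- c("x", "y", "z")
  structure(list(H = H, L = L, depth_offset = depth_offset),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat("4-hydrophone array: pair spacing", x$L, "m, pair depth offset",
      x$depth_offset, "m\n")
  print(x$H)
  invisible(x)
}

#' Buoy attitude
#'
#' Attitude sample from the tilt-compass device on a unit: pitch, roll and
#' compass heading, plus the fixed per-unit compass offset \code{psi0} between
#' the compass indicator and the array body axes (recovered by field
#' calibration, see \code{\link{estimate_psi0}}).
#'
#' @param pitch,roll degrees, each in (-90, 90).
#' @param compass heading in degrees, normalised to [0, 360).
#' @param psi0 static compass offset in degrees (default 0).
#' @param time timestamp (numeric seconds or POSIXct), optional.
#' @return object of class \code{attitude}.
#' @export
attitude <- function(pitch = 0, roll = 0, compass = 0, psi0 = 0, time = NA) {
  vals <- c(pitch, roll, compass, psi0)
  if (!all(is.finite(vals))) stop("attitude angles must be finite")
  if (abs(pitch) >= 90 || abs(roll) >= 90)
    stop("pitch and roll must lie in (-90, 90) degrees")
  structure(list(pitch = pitch, roll = roll,
                 compass = compass %% 360, psi0 = psi0, time = time),
            class = "attitude")
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Body-to-world rotation matrix for an attitude
#'
#' Intrinsic rotation order roll (about body x), then pitch (about body y),
#' then yaw = compass + psi0. At zero attitude the body axes coincide with the
#' local ENU axes (x East, y North, z up); increasing compass turns the buoy
#' clockwise seen from above, as a magnetic compass does.
#'
#' @param att an \code{\link{attitude}}.
#' @return 3 x 3 orthonormal rotation matrix mapping body vectors to world.
#' @export
attitude_rotation <- function(att) {
  stopifnot(inherits(att, "attitude"))
  r <- deg2rad(att$roll); p <- deg2rad(att$pitch)
  y <- deg2rad(att$compass + att$psi0)
  Rx <- rbind(c(1, 0, 0), c(0, cos(r), -sin(r)), c(0, sin(r), cos(r)))
  Ry <- rbind(c(cos(p), 0, sin(p)), c(0, 1, 0), c(-sin(p), 0, cos(p)))
  # clockwise yaw: (x,y) -> (x cos + y sin, -x sin + y cos)
  Rz <- rbind(c(cos(y), sin(y), 0), c(-sin(y), cos(y), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Rotate a body-frame vector into the world (ENU) frame
#'
#' @param v 3-vector in the body frame.
#' @param att an \code{\link{attitude}}.
#' @return 3-vector in the local ENU world frame.
#' @examples
#' body_to_world(c(1, 0, 0), attitude())            # identity
#' body_to_world(c(1, 0, 0), attitude(compass = 90)) # -> (0, -1, 0)
#' @export
body_to_world <- function(v, att) {
  stopifnot(length(v) == 3, all(is.finite(v)))
  drop(attitude_rotation(att) %*% v)
}

#' Rotate a world-frame vector into the body frame
#' @inheritParams body_to_world
#' @export
world_to_body <- function(v, att) {
  stopifnot(length(v) == 3, all(is.finite(v)))
  drop(t(attitude_rotation(att)) %*% v)
}

# the six ordered hydrophone pairs, fixed order used throughout
tdoa_pairs <- function() {
  cbind(i = c(0L, 0L, 0L, 1L, 1L, 2L), j = c(1L, 2L, 3L, 2L, 3L, 3L))
}

pair_names <- function() {
  p <- tdoa_pairs()
  paste0("t", p[, 1], p[, 2])
}

#' Expected TDOAs for a plane wave
#'
#' For a plane wave propagating along unit vector \code{n} (pointing away from
#' the source), the time difference of arrival between hydrophones i and j is
#' \eqn{\Delta t_{ij} = (H_i - H_j) \cdot \hat n / c}: the hydrophone further
#' along the propagation direction is reached later.
#'
#' @param n propagation unit vector (body frame, or world frame if \code{H}
#'   has been rotated accordingly).
#' @param geom an \code{\link{array_geometry}}.
#' @param c_sound sound speed in m/s (default 1500).
#' @param H optional 4 x 3 matrix of hydrophone positions overriding
#'   \code{geom$H} (e.g. attitude-rotated positions).
#' @return named numeric vector of the six \eqn{\Delta t_{ij}} in seconds, in
#'   pair order 01, 02, 03, 12, 13, 23.
#' @export
expected_tdoas <- function(n, geom, c_sound = 1500, H = NULL) {
  stopifnot(length(n) == 3, c_sound > 0)
  nn <- sqrt(sum(n^2))
  if (nn == 0 || !is.finite(nn)) stop("direction vector must be non-zero")
  n <- n / nn
  if (is.null(H)) H <- geom$H
  p <- tdoa_pairs()
  dt <- ((H[p[, "i"] + 1L, , drop = FALSE] -
          H[p[, "j"] + 1L, , drop = FALSE]) %*% n) / c_sound
  stats::setNames(drop(dt), pair_names())
}

#' Spherical angles to propagation unit vector
#'
#' Wave-frame convention: \code{n = (sin(theta) cos(phi), sin(theta) sin(phi),
#' cos(theta))} with azimuth \code{phi} measured in the body x-y plane from
#' the body x axis and polar angle \code{theta} from the body +z axis.
#'
#' @param phi,theta angles in radians.
#' @return unit 3-vector.
#' @export
angles_to_unit <- function(phi, theta) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Propagation unit vector to spherical angles
#' @param n unit 3-vector.
#' @return list with \code{phi} in [0, 2pi) and \code{theta} in [0, pi],
#'   radians.
#' @export
unit_to_angles <- function(n) {
  n <- n / sqrt(sum(n^2))
  list(phi = atan2(n[2], n[1]) %% (2 * pi), theta = acos(max(-1, min(1, n[3]))))
}

#' Compass bearing of a world-frame direction
#'
#' @param v 3-vector in ENU coordinates.
#' @return bearing in degrees clockwise from North, in [0, 360).
#' @export
enu_bearing <- function(v) {
  rad2deg(atan2(v[1], v[2])) %% 360
}

#' Unit configuration
#'
#' Static description of one acoustic unit: its geographic position, array
#' depth, field-calibrated pair travel time \code{Lc} = L/c (seconds) and
#' compass offset \code{psi0}.
#'
#' @param name unit name.
#' @param lat,lon WGS84 decimal degrees.
#' @param depth array depth in metres (> 0).
#' @param Lc pair spacing over sound speed, seconds (> 0).
#' @param psi0 compass offset, degrees.
#' @param declination optional magnetic declination added to compass readings,
#'   degrees (default 0).
#' @return object of class \code{unit_config}.
#' @export
unit_config <- function(name, lat, lon, depth = 20, Lc = 5 / 1500, psi0 = 0,
                        declination = 0) {
  stopifnot(Lc > 0, depth > 0)
  structure(list(name = name, lat = lat, lon = lon, depth = depth,
                 Lc = Lc, psi0 = psi0, declination = declination),
            class = "unit_config")
}

#' Local ENU coordinates of a lat/lon point
#'
#' Flat tangent-plane conversion about a reference origin; adequate for study
#' areas a few kilometres across.
#'
#' @param lat,lon point, decimal degrees.
#' @param lat0,lon0 origin, decimal degrees.
#' @return 2-vector (east, north) in metres.
#' @export
latlon_to_enu <- function(lat, lon, lat0, lon0) {
  Rearth <- 6371000
  e <- deg2rad(lon - lon0) * Rearth * cos(deg2rad(lat0))
  n <- deg2rad(lat - lat0) * Rearth
  c(east = e, north = n)
}

#' Inverse of \code{\link{latlon_to_enu}}
#' @param east,north metres from the origin.
#' @param lat0,lon0 origin, decimal degrees.
#' @return c(lat, lon) decimal degrees.
#' @export
enu_to_latlon <- function(east, north, lat0, lon0) {
  Rearth <- 6371000
  c(lat = lat0 + rad2deg(north / Rearth),
    lon = lon0 + rad2deg(east / (Rearth * cos(deg2rad(lat0)))))
}

#' Read an attitude log
#'
#' CSV with header \code{timestamp,pitch_deg,roll_deg,compass_deg}; timestamps
#' UTC ISO-8601 or numeric seconds.
#'
#' @param path CSV file path.
#' @return data.frame with columns \code{time} (numeric seconds),
#'   \code{pitch}, \code{roll}, \code{compass}.
#' @export
read_attitude_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "pitch_deg", "roll_deg", "compass_deg")
  if (!all(need %in% names(d)))
    stop("attitude log must have columns: ", paste(need, collapse = ", "))
  t <- suppressWarnings(as.numeric(d$timestamp))
  if (anyNA(t))
    t <- as.numeric(as.POSIXct(d$timestamp, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                              "%Y-%m-%d %H:%M:%OS")))
  data.frame(time = t, pitch = d$pitch_deg, roll = d$roll_deg,
             compass = d$compass_deg)
}

#' Write an attitude log
#' @param d data.frame as returned by \code{\link{read_attitude_log}}.
#' @param path output CSV path.
#' @export
write_attitude_log <- function(d, path) {
  out <- data.frame(timestamp = d$time, pitch_deg = d$pitch,
                    roll_deg = d$roll, compass_deg = d$compass)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Interpolate an attitude log at a given time
#'
#' Linear interpolation of pitch/roll and circular interpolation of compass;
#' returns NULL when no sample lies within \code{max_gap} seconds.
#'
#' @param log data.frame from \code{\link{read_attitude_log}}.
#' @param time query time (seconds).
#' @param psi0 compass offset for the returned attitude.
#' @param max_gap maximum allowed distance to the nearest log sample, seconds.
#' @return an \code{\link{attitude}} or NULL.
#' @export
attitude_at <- function(log, time, psi0 = 0, max_gap = 5) {
  if (nrow(log) == 0 || min(abs(log$time - time)) > max_gap) return(NULL)
  if (nrow(log) == 1) {
    s <- log[1, ]
    return(attitude(s$pitch, s$roll, s$compass, psi0, time))
  }
  p <- stats::approx(log$time, log$pitch, time, rule = 2)$y
  r <- stats::approx(log$time, log$roll, time, rule = 2)$y
  cs <- stats::approx(log$time, cos(deg2rad(log$compass)), time, rule = 2)$y
  sn <- stats::approx(log$time, sin(deg2rad(log$compass)), time, rule = 2)$y
  attitude(p, r, rad2deg(atan2(sn, cs)) %% 360, psi0, time)
}
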