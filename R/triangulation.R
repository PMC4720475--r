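# Two-unit triangulation: intersect simultaneous azimuth rays in the
# horizontal plane, check the fix against the inter-unit TDOA hyperbola, and
# report the error-square side.

#' Intersect two azimuth rays into a position fix
#'
#' Least-squares intersection of the two compass-bearing rays from the two
#' units in the horizontal ENU plane. Rays within \code{min_angle} degrees
#' of parallel, or intersecting behind either unit, yield a no-fix sentinel.
#'
#' @param bearing_A,bearing_B \code{\link{bearing}} objects (world frame) or
#'   plain azimuths in degrees.
#' @param pos_A,pos_B unit positions, 2-vectors (east, north), metres.
#' @param min_angle minimum ray opening angle, degrees (default 3).
#' @return object of class \code{fix}: list with \code{ok}, \code{east},
#'   \code{north}, \code{range_A}, \code{range_B}, and the inputs; or
#'   \code{ok = FALSE} when degenerate.
#' @export
intersect_bearings <- function(bearing_A, bearing_B, pos_A, pos_B,
                               min_angle = 3) {
  azA <- if (inherits(bearing_A, "bearing")) bearing_A$azimuth else bearing_A
  azB <- if (inherits(bearing_B, "bearing")) bearing_B$azimuth else bearing_B
  dA <- c(sin(deg2rad(azA)), cos(deg2rad(azA)))
  dB <- c(sin(deg2rad(azB)), cos(deg2rad(azB)))
  cross <- dA[1] * dB[2] - dA[2] * dB[1]
  if (abs(cross) < sin(deg2rad(min_angle)))
    return(structure(list(ok = FALSE, reason = "near-parallel bearings"),
                     class = "fix"))
  rhs <- c(pos_B[1] - pos_A[1], pos_B[2] - pos_A[2])
  # pos_A + tA dA = pos_B + tB dB
  tA <- (rhs[1] * dB[2] - rhs[2] * dB[1]) / cross
  tB <- (rhs[1] * dA[2] - rhs[2] * dA[1]) / cross
  eps <- 1e-9 * sqrt(sum(rhs^2))
  if (tA < -eps || tB < -eps)
    return(structure(list(ok = FALSE, reason = "diverging bearings"),
                     class = "fix"))
  p <- c(pos_A[1] + tA * dA[1], pos_A[2] + tA * dA[2])
  structure(list(ok = TRUE, east = p[1], north = p[2],
                 range_A = tA, range_B = tB,
                 azimuth_A = azA, azimuth_B = azB,
                 pos_A = pos_A, pos_B = pos_B), class = "fix")
}

#' @export
print.fix <- function(x, ...) {
  if (!x$ok) cat("no fix:", x$reason, "\n")
  else cat(sprintf("fix at E %.0f m, N %.0f m (ranges %.0f / %.0f m)\n",
                   x$east, x$north, x$range_A, x$range_B))
  invisible(x)
}

#' Hyperbola consistency of a fix
#'
#' The inter-unit arrival-time difference of the same event constrains the
#' source to a hyperbola with the units as foci. The residual
#' \code{|(r_A - r_B) - c dt_AB|} in metres measures how far the
#' triangulated fix is from that locus.
#'
#' @param fix a \code{\link{intersect_bearings}} fix.
#' @param dt_AB arrival time at unit A minus arrival time at unit B,
#'   seconds; NA skips the check.
#' @param c_sound sound speed, m/s.
#' @param threshold consistency threshold, metres (default 50).
#' @return list with \code{residual} (m; NA if skipped), \code{consistent}
#'   (logical; NA if skipped).
#' @export
hyperbola_consistency <- function(fix, dt_AB, c_sound = 1500,
                                  threshold = 50) {
  if (!fix$ok) stop("no fix to check")
  if (is.na(dt_AB))
    return(list(residual = NA_real_, consistent = NA))
  res <- abs((fix$range_A - fix$range_B) - c_sound * dt_AB)
  list(residual = res, consistent = res < threshold)
}

#' Error-square side at range
#'
#' A bearing uncertainty of \code{dalpha} degrees at range r spans an arc of
#' \code{r * dalpha} (radians) metres, taken as the side of the square error
#' area around the triangulated position.
#'
#' @param range_m target range, metres.
#' @param dalpha_deg angular error, degrees.
#' @return side in metres.
#' @examples
#' error_square(3700, 2)  # ~130 m
#' @export
error_square <- function(range_m, dalpha_deg) {
  stopifnot(range_m > 0)
  range_m * deg2rad(dalpha_deg)
}

#' Match detection events across the two units
#'
#' Pairs events whose peak times differ by less than the inter-unit
#' acoustic travel window and whose whistle contours are similar (normalized
#' cross-correlation of the two maxima tracks).
#'
#' @param det_A,det_B detection frames from \code{\link{detect_whistles}}.
#' @param max_dt matching window, seconds (default 3: generous against a
#'   1.2 s maximum acoustic delay at 1.8 km).
#' @param contour_A,contour_B optional list of per-event contour vectors for
#'   similarity checking.
#' @param min_similarity minimum normalized contour correlation
#'   (default 0.7).
#' @return data.frame of matched index pairs \code{iA}, \code{iB} and
#'   \code{dt} (peak time difference A - B, s).
#' @export
match_events <- function(det_A, det_B, max_dt = 3, contour_A = NULL,
                         contour_B = NULL, min_similarity = 0.7) {
  out <- list()
  for (i in seq_len(nrow(det_A))) {
    dts <- det_A$peak_time[i] - det_B$peak_time
    j <- which(abs(dts) <= max_dt)
    if (!length(j)) next
    j <- j[which.min(abs(dts[j]))]
    if (!is.null(contour_A) && !is.null(contour_B)) {
      ca <- contour_A[[i]]; cb <- contour_B[[j]]
      n <- min(length(ca), length(cb))
      if (n >= 4) {
        sim <- suppressWarnings(stats::cor(ca[seq_len(n)], cb[seq_len(n)]))
        if (!is.na(sim) && sim < min_similarity) next
      }
    }
    out[[length(out) + 1]] <- data.frame(iA = i, iB = j, dt = dts[j])
  }
  if (!length(out)) return(data.frame(iA = integer(0), iB = integer(0),
                                      dt = numeric(0)))
  do.call(rbind, out)
}
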