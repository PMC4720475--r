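# Plane-wave bearing estimation from a measured TDOA set: direct linear
# solve on contiguous pairs, least-squares grid minimization over the full
# direction sphere, and rotation into the world frame.

#' Direct linear solve for the wave direction
#'
#' Solves the 3x3 linear system \code{(H_i - H_j) . n = c dt_ij} over the
#' contiguous hydrophone pairs (H0H1, H1H2, H2H3) for the plane-wave
#' propagation vector \code{n = (u, v, w)}. The raw solution length is a
#' quality metric: it deviates from 1 in proportion to TDOA error.
#'
#' @param tdoas a \code{\link{tdoa_set}} or named vector of six TDOAs.
#' @param geom an \code{\link{array_geometry}}.
#' @param c_sound sound speed, m/s.
#' @return list with \code{n} (unit propagation vector, body frame),
#'   \code{norm_residual} = |1 - |n_raw||, \code{reliable} (FALSE when the
#'   residual exceeds 0.2).
#' @export
solve_linear <- function(tdoas, geom = array_geometry(), c_sound = 1500) {
  dt <- if (inherits(tdoas, "tdoa_set")) tdoas$dt else tdoas
  H <- geom$H
  A <- rbind(H[1, ] - H[2, ], H[2, ] - H[3, ], H[3, ] - H[4, ])
  # (H_i - H_j) . n = c dt_ij for contiguous pairs
  b <- c_sound * c(dt[["t01"]], dt[["t12"]], dt[["t23"]])
  if (abs(det(A)) < 1e-9) stop("singular contiguous-pair geometry")
  n_raw <- unname(solve(A, b))
  len <- sqrt(sum(n_raw^2))
  list(n = n_raw / len, norm_residual = abs(1 - len),
       reliable = abs(1 - len) <= 0.2)
}

#' TDOA least-squares functional G
#'
#' Sum of squared differences between measured and model TDOAs over all six
#' pairs for a trial direction.
#'
#' @param phi,theta trial wave azimuth/polar angles, radians (wave-frame
#'   convention of \code{\link{angles_to_unit}}).
#' @param dt named vector of measured TDOAs, seconds.
#' @param geom an \code{\link{array_geometry}}.
#' @param c_sound sound speed, m/s.
#' @return G value (s^2).
#' @export
G_functional <- function(phi, theta, dt, geom = array_geometry(),
                         c_sound = 1500) {
  model <- expected_tdoas(angles_to_unit(phi, theta), geom, c_sound)
  sum((dt - model)^2)
}

#' Grid minimization of the TDOA functional
#'
#' Evaluates G on a coarse azimuth x polar grid covering the full sphere,
#' then refines the argmin on two successively finer local grids (final
#' resolution ~0.02 degrees). When the G minimum is elevation-ambiguous the
#' upper half-space (waves travelling downward from near-surface sources,
#' theta_W > 90 deg is excluded) is preferred via the refinement start.
#'
#' @param tdoas a \code{\link{tdoa_set}} or named TDOA vector.
#' @param geom an \code{\link{array_geometry}}.
#' @param c_sound sound speed, m/s.
#' @param coarse_deg coarse grid step, degrees (default 2).
#' @return list with \code{phi}, \code{theta} (radians), \code{G} at the
#'   optimum, or a no-bearing sentinel (\code{ok = FALSE}) when the surface
#'   is flat (all TDOAs zero/undefined).
#' @export
grid_search_G <- function(tdoas, geom = array_geometry(), c_sound = 1500,
                          coarse_deg = 2) {
  dt <- if (inherits(tdoas, "tdoa_set")) tdoas$dt else tdoas
  if (anyNA(dt) || all(dt == 0))
    return(list(ok = FALSE, phi = NA_real_, theta = NA_real_, G = NA_real_))
  H <- geom$H
  p <- tdoa_pairs()
  Dh <- H[p[, "i"] + 1L, ] - H[p[, "j"] + 1L, ]     # 6 x 3
  Ggrid <- function(phis, thetas) {
    # all combinations; returns matrix length(phis) x length(thetas)
    sapply(thetas, function(th) {
      N <- rbind(sin(th) * cos(phis), sin(th) * sin(phis),
                 rep(cos(th), length(phis)))        # 3 x np
      M <- (Dh %*% N) / c_sound                      # 6 x np
      colSums((M - dt)^2)
    })
  }
  step <- deg2rad(coarse_deg)
  phis <- seq(0, 2 * pi - step, by = step)
  thetas <- seq(0, pi, by = step)
  G0 <- Ggrid(phis, thetas)
  i <- which(G0 == min(G0), arr.ind = TRUE)[1, ]
  phi <- phis[i[1]]; theta <- thetas[i[2]]
  for (ref in c(10, 100)) {
    st <- step / ref
    phis_r <- phi + seq(-10, 10) * st
    thetas_r <- pmax(0, pmin(pi, theta + seq(-10, 10) * st))
    Gr <- Ggrid(phis_r, thetas_r)
    ir <- which(Gr == min(Gr), arr.ind = TRUE)[1, ]
    phi <- phis_r[ir[1]] %% (2 * pi); theta <- thetas_r[ir[2]]
  }
  list(ok = TRUE, phi = phi, theta = theta,
       G = G_functional(phi, theta, dt, geom, c_sound))
}

#' World-frame source bearing
#'
#' @param azimuth compass azimuth, degrees in [0, 360).
#' @param elevation polar angle from the world +z (up) axis, degrees in
#'   [0, 180] (90 = horizontal).
#' @param error angular error, degrees.
#' @param time timestamp.
#' @param frame \code{"world"} or \code{"body"} (body-only when no attitude
#'   was available).
#' @return object of class \code{bearing}.
#' @export
bearing <- function(azimuth, elevation = 90, error = NA_real_, time = NA,
                    frame = "world") {
  structure(list(azimuth = azimuth %% 360, elevation = elevation,
                 error = error, time = time, frame = frame),
            class = "bearing")
}

#' @export
print.bearing <- function(x, ...) {
  cat(sprintf("bearing %.2f deg (%s frame), elevation %.2f deg",
              x$azimuth, x$frame, x$elevation))
  if (is.finite(x$error)) cat(sprintf(" +/- %.2f deg", x$error))
  cat("\n")
  invisible(x)
}

#' Wave direction to world-frame source bearing
#'
#' The source lies opposite to the wave propagation direction:
#' \code{phi_S = phi_W + pi}, \code{theta_S = pi - theta_W} in the body
#' frame. The body-frame source direction is then rotated into the world
#' frame by the unit attitude (compass + psi0) and reported as a compass
#' azimuth plus polar elevation. With a NULL attitude the bearing is emitted
#' in the body frame and flagged.
#'
#' @param phi,theta wave direction angles, radians (body frame).
#' @param att an \code{\link{attitude}} or NULL.
#' @param error angular error to attach, degrees.
#' @param time timestamp.
#' @return a \code{\link{bearing}}.
#' @export
wave_to_source_bearing <- function(phi, theta, att, error = NA_real_,
                                   time = NA) {
  s_body <- angles_to_unit(phi + pi, pi - theta)
  if (is.null(att)) {
    return(bearing(enu_bearing(s_body), rad2deg(acos(s_body[3])),
                   error, time, frame = "body"))
  }
  s_world <- body_to_world(s_body, att)
  bearing(enu_bearing(s_world),
          rad2deg(acos(max(-1, min(1, s_world[3])))),
          error, time, frame = "world")
}

#' Whistle-triggered bearing estimation
#'
#' Full dolphin-tracking step for one unit: for each accepted whistle
#' detection, measure the TDOA set around the event, minimize the TDOA
#' functional, and rotate the wave direction into the world frame using the
#' attitude log. When the whistle spans several correlation windows the
#' event bearing is the correlation-peak-weighted circular mean of
#' per-window bearings.
#'
#' @param X samples x 4 channel matrix of the unit.
#' @param fs sample rate, Hz.
#' @param detections data.frame from \code{\link{detect_whistles}} (accepted
#'   rows are processed).
#' @param attitude_log data.frame as from \code{\link{read_attitude_log}}.
#' @param psi0 compass offset of the unit, degrees.
#' @param geom an \code{\link{array_geometry}}.
#' @param c_sound sound speed, m/s.
#' @param window correlation window length, seconds; NULL (default) uses
#'   one window spanning the whole event padded by 50 ms (the full FM sweep
#'   makes the cross-correlations unambiguous), a finite value splits the
#'   event into sub-windows whose bearings are combined by a
#'   correlation-peak-weighted circular mean.
#' @return list of \code{\link{bearing}} objects (one per accepted event,
#'   with \code{tdoa} and \code{G} attached as attributes), possibly empty.
#' @export
dolphin_bearings <- function(X, fs, detections, attitude_log = NULL,
                             psi0 = 0, geom = array_geometry(),
                             c_sound = 1500, window = NULL) {
  acc <- detections[detections$accepted, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(acc))) {
    ev <- acc[i, ]
    t0 <- max(0, ev$start - 0.05); t1 <- ev$end + 0.05
    # one window over the event, or several whose bearings are averaged
    edges <- if (is.null(window)) c(t0, t1) else {
      e <- seq(t0, t1, by = window)
      if (length(e) < 2 || e[length(e)] < t1) e <- c(e, t1)
      e
    }
    az <- el <- wt <- numeric(0)
    best <- NULL
    for (k in seq_len(length(edges) - 1)) {
      ts <- event_tdoa_set(X, fs, edges[k], edges[k + 1], pad = 0,
                           geom = geom, c_sound = c_sound)
      if (!ts$valid) next
      g <- grid_search_G(ts, geom, c_sound)
      if (!g$ok) next
      att <- if (!is.null(attitude_log))
        attitude_at(attitude_log, (edges[k] + edges[k + 1]) / 2, psi0)
      else attitude(0, 0, 0, psi0)
      b <- wave_to_source_bearing(g$phi, g$theta, att,
                                  time = (edges[k] + edges[k + 1]) / 2)
      az <- c(az, b$azimuth); el <- c(el, b$elevation)
      wt <- c(wt, mean(ts$peaks))
      if (is.null(best) || g$G < attr(best, "G")) {
        attr(b, "G") <- g$G; attr(b, "tdoa") <- ts
        best <- b
      }
    }
    if (!length(az)) next
    mean_az <- rad2deg(atan2(sum(wt * sin(deg2rad(az))),
                             sum(wt * cos(deg2rad(az))))) %% 360
    b <- bearing(mean_az, stats::weighted.mean(el, wt),
                 time = ev$peak_time, frame = best$frame)
    attr(b, "G") <- attr(best, "G"); attr(b, "tdoa") <- attr(best, "tdoa")
    out[[length(out) + 1]] <- b
  }
  out
}
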