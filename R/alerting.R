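# Sector-based alerting: the study area is divided into rectangular sectors;
# each sector carries a green/yellow/red state driven by timestamped dolphin
# and boat events (yellow = dolphins present, red = dolphins and boats
# simultaneously present).

#' Sector grid
#'
#' Rectangular sectors over the study area in local ENU metres. The default
#' layout is five ~2 km square sectors in a cross/row arrangement; any
#' rectangle list can be configured.
#'
#' @param sectors named list of rectangles, each \code{c(xmin, xmax, ymin,
#'   ymax)} metres.
#' @return object of class \code{sector_grid}.
#' @export
sector_grid <- function(sectors = NULL) {
  if (is.null(sectors)) {
    s <- 2000
    sectors <- list(
      "1" = c(-2 * s, -s, 0, s), "2" = c(-s, 0, 0, s),
      "3" = c(0, s, 0, s), "4" = c(s, 2 * s, 0, s),
      "5" = c(-s / 2, s / 2, -s, 0))
  }
  structure(list(sectors = sectors), class = "sector_grid")
}

#' Assign a position or a bearing ray to sectors
#'
#' A position fix maps to its containing sector ("outside" when in none). A
#' bearing-only detection maps to every sector crossed by the bearing ray
#' from the unit out to the detection range.
#'
#' @param grid a \code{\link{sector_grid}}.
#' @param east,north position, metres (for a fix).
#' @param unit_pos,azimuth_deg,range_m ray origin, compass azimuth and
#'   length (for a bearing-only detection).
#' @return character vector of sector ids (possibly "outside").
#' @export
assign_sector <- function(grid, east = NULL, north = NULL, unit_pos = NULL,
                          azimuth_deg = NULL, range_m = NULL) {
  inside <- function(p, r) p[1] >= r[1] && p[1] <= r[2] &&
    p[2] >= r[3] && p[2] <= r[4]
  if (!is.null(east)) {
    for (id in names(grid$sectors))
      if (inside(c(east, north), grid$sectors[[id]])) return(id)
    return("outside")
  }
  stopifnot(!is.null(unit_pos), !is.null(azimuth_deg), !is.null(range_m))
  d <- c(sin(deg2rad(azimuth_deg)), cos(deg2rad(azimuth_deg)))
  hit <- character(0)
  for (id in names(grid$sectors)) {
    r <- grid$sectors[[id]]
    # slab intersection of the ray [0, range] with the rectangle
    t0 <- 0; t1 <- range_m; ok <- TRUE
    for (ax in 1:2) {
      lo <- r[2 * ax - 1] - unit_pos[ax]; hi <- r[2 * ax] - unit_pos[ax]
      if (d[ax] == 0) {
        if (0 < lo || 0 > hi) { ok <- FALSE; break }
      } else {
        ta <- lo / d[ax]; tb <- hi / d[ax]
        t0 <- max(t0, min(ta, tb)); t1 <- min(t1, max(ta, tb))
        if (t0 > t1) { ok <- FALSE; break }
      }
    }
    if (ok) hit <- c(hit, id)
  }
  if (!length(hit)) "outside" else hit
}

#' Update per-sector alarm states
#'
#' A sector is yellow when a dolphin event occurred in it within the hold
#' time before \code{now}, red when additionally a boat event occurred in it
#' within the hold time, green otherwise (precedence red > yellow > green).
#'
#' @param grid a \code{\link{sector_grid}}.
#' @param dolphin_events,boat_events data.frames with columns \code{time}
#'   and \code{sector} (ids as returned by \code{\link{assign_sector}}).
#' @param now current time, seconds.
#' @param hold_s hold time, seconds (default 600).
#' @return named character vector of states ("green"/"yellow"/"red") per
#'   sector.
#' @export
update_state <- function(grid, dolphin_events = NULL, boat_events = NULL,
                         now = 0, hold_s = 600) {
  recent <- function(ev, id) {
    !is.null(ev) && nrow(ev) > 0 &&
      any(ev$sector == id & ev$time <= now & ev$time > now - hold_s)
  }
  st <- vapply(names(grid$sectors), function(id) {
    if (recent(dolphin_events, id)) {
      if (recent(boat_events, id)) "red" else "yellow"
    } else "green"
  }, character(1))
  st
}

#' Alarm state machine with transition log
#'
#' Replays timestamped dolphin/boat event streams and records every
#' per-sector state transition; replaying the same log yields an identical
#' history.
#'
#' @param grid a \code{\link{sector_grid}}.
#' @param dolphin_events,boat_events event frames (columns \code{time},
#'   \code{sector}).
#' @param times evaluation times (default: all event times and their
#'   hold-time expiries, sorted).
#' @param hold_s hold time, seconds.
#' @return data.frame log of transitions: \code{time}, \code{sector},
#'   \code{from}, \code{to}.
#' @export
alarm_history <- function(grid, dolphin_events = NULL, boat_events = NULL,
                          times = NULL, hold_s = 600) {
  if (is.null(times)) {
    tt <- c(if (!is.null(dolphin_events)) dolphin_events$time,
            if (!is.null(boat_events)) boat_events$time)
    times <- sort(unique(c(tt, tt + hold_s + 1e-9)))
  }
  state <- stats::setNames(rep("green", length(grid$sectors)),
                           names(grid$sectors))
  log <- list()
  for (tm in times) {
    new <- update_state(grid, dolphin_events, boat_events, tm, hold_s)
    ch <- which(new != state)
    for (k in ch)
      log[[length(log) + 1]] <- data.frame(time = tm,
                                           sector = names(state)[k],
                                           from = unname(state[k]),
                                           to = unname(new[k]))
    state <- new
  }
  if (!length(log)) return(data.frame(time = numeric(0),
                                      sector = character(0),
                                      from = character(0), to = character(0)))
  do.call(rbind, log)
}

#' Detection report
#'
#' Self-contained report for one detection event: date-time, the whistle
#' spectrogram excerpt, the cross-correlation snapshot and the tracking
#' results. Missing products are marked absent rather than failing.
#'
#' @param event one detection row (from \code{\link{detect_whistles}}).
#' @param spectrogram optional \code{\link{spectrogram}} excerpt.
#' @param tdoas optional \code{\link{tdoa_set}} (carries the correlograms).
#' @param bearing optional \code{\link{bearing}}.
#' @param fix optional triangulation \code{fix}.
#' @param path optional path; when given the report is written as JSON.
#' @return the report as a list (invisibly when written to file).
#' @export
detection_report <- function(event, spectrogram = NULL, tdoas = NULL,
                             bearing = NULL, fix = NULL, path = NULL) {
  rep <- list(
    datetime = if (!is.null(event$peak_time)) event$peak_time else NA,
    event = as.list(event),
    spectrogram = if (is.null(spectrogram)) "absent" else
      list(f = spectrogram$f, t = spectrogram$t,
           P_db = round(10 * log10(pmax(spectrogram$P, 1e-30)), 1)),
    cross_correlation = if (is.null(tdoas)) "absent" else
      list(dt_s = as.list(tdoas$dt), peaks = as.list(tdoas$peaks),
           residual_s = tdoas$residual, valid = tdoas$valid),
    tracking = if (!is.null(fix) && isTRUE(fix$ok))
      list(mode = "triangulated", east = fix$east, north = fix$north)
    else if (!is.null(bearing))
      list(mode = "bearing-only", azimuth_deg = bearing$azimuth,
           elevation_deg = bearing$elevation, frame = bearing$frame)
    else "absent")
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
    return(invisible(rep))
  }
  rep
}
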