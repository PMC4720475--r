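#' Default pipeline configuration
#'
#' Nested list mirroring the YAML schema accepted by
#' \code{\link{read_config}}. Keys: \code{sonar} (see
#' \code{\link{sonar_params}}), \code{noise} (Wenz-style table and offset),
#' \code{array} (pair spacing and depth offset), \code{detector}
#' (spectrogram and detection-function settings, gate enablement),
#' \code{tdoa} (bandpass edges, adaptive gate), \code{units} (list of unit
#' entries: name, lat, lon, depth, Lc, psi0, declination), \code{alert}
#' (hold time).
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    sonar = list(SL = 160, f_min = 5000, f_max = 15000, k = 20,
                 alpha = 0.72, DT = 5, f_sampl = 100000, d = 9),
    noise = list(levels = list("0" = 29, "4" = 48), offset = 0),
    array = list(L = 5, depth_offset = 5),
    detector = list(nfft = 1024, overlap = 0.75, P = 10,
                    threshold_bins = 2, W_threshold = 0.8^2,
                    gate_enabled = TRUE),
    tdoa = list(f_lo = 3000, f_hi = 23000, n_sigma = 4),
    c_sound = 1500,
    units = list(),
    alert = list(hold_s = 600)
  )
}

#' Read a YAML configuration file
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path YAML file path (NULL returns the defaults).
#' @return nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_lists(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  merge_lists(cfg, user)
}
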