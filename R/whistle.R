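# Whistle detection on a single-channel spectrogram: click suppression by the
# negative second spectral derivative, per-time-bin maxima track M(i), a
# linearity detection function W(m), and a slope/duration false-positive gate.

#' Spectrogram parameters
#'
#' @param nfft FFT size (power of two, default 1024).
#' @param overlap fractional window overlap in [0, 1) (default 0.75).
#' @param fs sample rate, Hz (default 100 kHz).
#' @return object of class \code{spectrogram_params}; the implied frequency
#'   step is \code{fs/nfft} and the hop \code{nfft * (1 - overlap)} samples.
#' @export
spectrogram_params <- function(nfft = 1024, overlap = 0.75, fs = 100e3) {
  stopifnot(overlap >= 0, overlap < 1, bitwAnd(nfft, nfft - 1L) == 0)
  structure(list(nfft = nfft, overlap = overlap, fs = fs,
                 hop = as.integer(round(nfft * (1 - overlap)))),
            class = "spectrogram_params")
}

#' Compute a power spectrogram
#'
#' Hann-windowed short-time FFT. Power is |X|^2 summed over the window,
#' normalised so that the total power over all frames and (one-sided) bins
#' approximates the windowed signal energy (Parseval).
#'
#' @param x waveform.
#' @param params a \code{\link{spectrogram_params}}.
#' @return object of class \code{spectrogram}: list with \code{P}
#'   (frequency x time power matrix), \code{f} (Hz), \code{t} (frame centre
#'   times, s), and the params.
#' @export
compute_spectrogram <- function(x, params = spectrogram_params()) {
  nfft <- params$nfft; hop <- params$hop; fs <- params$fs
  if (length(x) < nfft) stop("input shorter than one FFT frame")
  starts <- seq(1, length(x) - nfft + 1, by = hop)
  frames <- matrix(x[outer(0:(nfft - 1), starts, "+")], nrow = nfft)
  w <- hann_window(nfft)
  frames <- frames * w
  X <- stats::mvfft(frames)
  nb <- nfft / 2 + 1
  P <- Mod(X[seq_len(nb), , drop = FALSE])^2 / (sum(w^2) * nfft)
  P[2:(nb - 1), ] <- 2 * P[2:(nb - 1), ]
  structure(list(P = P, f = (seq_len(nb) - 1) * fs / nfft,
                 t = (starts - 1 + nfft / 2) / fs, params = params),
            class = "spectrogram")
}

#' Click suppression and maxima track extraction
#'
#' For each time bin the negative second derivative of the spectrum,
#' \code{D_i(f) = 2 P_i(f) - (P_i(f - df) + P_i(f + df))}, emphasises
#' narrow-band tonal peaks over wide-band impulsive clicks. The per-time-bin
#' frequency of the maximum of D within the analysis band forms the maxima
#' track M(i).
#'
#' @param spec a \code{\link{spectrogram}}.
#' @param f_min,f_max analysis band, Hz (default 5--15 kHz).
#' @return list with \code{M} (track frequencies, Hz), \code{bin} (bin
#'   indices), \code{t} (frame times), \code{D} (band D matrix), \code{f}
#'   (band frequencies).
#' @export
click_suppress <- function(spec, f_min = 5e3, f_max = 15e3) {
  f <- spec$f
  if (f_min < f[1] || f_max > f[length(f)]) stop("band outside spectrogram range")
  P <- spec$P
  nb <- nrow(P)
  D <- 2 * P - (rbind(P[1, ], P[-nb, ]) + rbind(P[-1, ], P[nb, ]))
  keep <- which(f >= f_min & f <= f_max)
  Db <- D[keep, , drop = FALSE]
  idx <- max.col(t(Db), ties.method = "first")
  list(M = f[keep][idx], bin = keep[idx], t = spec$t,
       D = Db, f = f[keep])
}

#' Whistle detection function
#'
#' Tests the local linearity of the maxima track: with first derivative
#' \code{M'(k) = M(k+2) - M(k)} and increments
#' \code{L(j) = M'(m+j) - M'(m+j-1)}, each window of length P contributes
#' \code{W(m) = prod_j w(j)} with \code{w(j) = 1} when
#' \code{|L(j)| <= threshold} and 0.8 otherwise. A smooth tonal track keeps W
#' near 1; scattered noise drives it toward \code{0.8^P}. Windows with
#' \code{W >= W_threshold} are merged into candidate events.
#'
#' @param M maxima track frequencies, Hz (from \code{\link{click_suppress}}).
#' @param times frame times matching M, seconds.
#' @param P linearity window length in samples (default 10).
#' @param threshold allowed |L| step, Hz (default 2 frequency bins at the
#'   default spectrogram resolution, ~195 Hz).
#' @param W_threshold detection threshold on W (default 0.8^2: at most two
#'   violations tolerated).
#' @return list with \code{W}, \code{W_t} (times of W samples),
#'   \code{detected} (logical), and \code{events}: data.frame with columns
#'   \code{start}, \code{end}, \code{peak_time}, \code{peak_index} (index
#'   into M), \code{peak_W}, \code{peak_freq}.
#' @export
detection_function <- function(M, times, P = 10, threshold = 2 * 100e3 / 1024,
                               W_threshold = 0.8^2) {
  n <- length(M)
  if (n < P + 3) stop("track shorter than the linearity window")
  Mp <- M[3:n] - M[1:(n - 2)]              # M'(k), k = 1..n-2
  L <- diff(Mp)                            # L at positions 1..n-3
  w <- ifelse(abs(L) <= threshold, 1, 0.8)
  cl <- c(0, cumsum(log(w)))
  nm <- length(L) - P + 1                  # windows m = 1..nm
  W <- exp(cl[(P + 1):(P + nm)] - cl[1:nm])
  W_t <- times[seq_len(nm) + 1]            # centre-ish anchor of window m
  det <- W >= W_threshold
  events <- NULL
  if (any(det)) {
    r <- rle(det)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    runs <- which(r$values)
    events <- do.call(rbind, lapply(runs, function(k) {
      i0 <- starts[k]; i1 <- ends[k]
      mx <- which(W[i0:i1] == max(W[i0:i1]))
      pk <- i0 + mx[ceiling(length(mx) / 2)] - 1   # centre of tied maxima
      mi <- min(n, pk + 1 + floor(P / 2))  # track index near window centre
      data.frame(start = times[i0], end = times[min(n, i1 + P + 2)],
                 peak_time = W_t[pk], peak_index = mi,
                 peak_W = W[pk], peak_freq = M[mi])
    }))
  }
  list(W = W, W_t = W_t, detected = det, events = events)
}

bisquare_fit <- function(x, y, iter = 10) {
  # iteratively reweighted least squares with Tukey bisquare weights
  fit <- stats::lm.fit(cbind(1, x), y)
  for (it in seq_len(iter)) {
    r <- fit$residuals
    s <- stats::median(abs(r)) / 0.6745
    if (s <= 0) break
    u <- r / (4.685 * s)
    wt <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (all(wt == 0)) break
    fit <- stats::lm.wfit(cbind(1, x), y, wt)
  }
  fit$coefficients[2]
}

#' Slope and duration of a detected whistle
#'
#' The frequency slope is a robust (bisquare) linear fit of the maxima track
#' over a \code{win}-sample interval centred on the detection-function peak,
#' after discarding samples beyond 3 standard deviations of the residuals of
#' an initial fit. The duration is the length of the maximal run of
#' consecutive track samples within +/- 25 percent of the frequency at the
#' peak.
#'
#' @param event one row of the \code{events} frame from
#'   \code{\link{detection_function}}.
#' @param M,times maxima track and frame times.
#' @param win slope window length in track samples (default 40).
#' @param dev_frac relative frequency tolerance for the duration run
#'   (default 0.25).
#' @return list with \code{slope} (Hz/s), \code{duration} (s), and
#'   \code{truncated} (TRUE when the window hit a record edge).
#' @export
measure_slope_duration <- function(event, M, times, win = 40,
                                   dev_frac = 0.25) {
  n <- length(M)
  pk <- event$peak_index
  half <- floor(win / 2)
  i0 <- max(1, pk - half); i1 <- min(n, pk + half - 1)
  truncated <- (i1 - i0 + 1) < win
  tt <- times[i0:i1]; ff <- M[i0:i1]
  fit0 <- stats::lm.fit(cbind(1, tt), ff)
  s <- stats::sd(fit0$residuals)
  keep <- if (s > 0) abs(fit0$residuals) <= 3 * s else rep(TRUE, length(ff))
  slope <- if (sum(keep) >= 3) bisquare_fit(tt[keep], ff[keep])
           else fit0$coefficients[2]
  f_ref <- M[pk]
  inside <- abs(M - f_ref) <= dev_frac * f_ref
  # maximal consecutive run containing the peak
  lo <- pk; while (lo > 1 && inside[lo - 1]) lo <- lo - 1
  hi <- pk; while (hi < n && inside[hi + 1]) hi <- hi + 1
  hop_t <- if (length(times) > 1) stats::median(diff(times)) else 0
  list(slope = unname(slope), duration = (hi - lo + 1) * hop_t,
       truncated = truncated)
}

point_in_polygon <- function(px, py, poly) {
  # ray casting; poly: matrix with columns x, y
  n <- nrow(poly); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

#' False-positive gate configuration
#'
#' The gate accepts a detection when its (duration, slope) point lies inside
#' the whistle acceptance polygon and outside every rejection polygon. The
#' default rejection region excludes near-zero-slope, long-duration tracks:
#' sustained flat tones such as mooring-cable screech that mimic flat
#' whistles.
#'
#' @param accept polygon (matrix, columns duration s and slope Hz/s) of the
#'   whistle region.
#' @param reject list of rejection polygons in the same space.
#' @param enabled logical; FALSE passes everything through.
#' @return object of class \code{gate_config}.
#' @export
gate_config <- function(accept = NULL, reject = NULL, enabled = TRUE) {
  if (is.null(accept))
    accept <- cbind(duration = c(0.02, 3, 3, 0.02),
                    slope = c(-6e4, -6e4, 6e4, 6e4))
  if (is.null(reject))
    reject <- list(cbind(duration = c(1.2, 10, 10, 1.2),
                         slope = c(-300, -300, 300, 300)))
  structure(list(accept = accept, reject = reject, enabled = enabled),
            class = "gate_config")
}

#' Apply the slope/duration false-positive gate
#'
#' @param slope Hz/s.
#' @param duration s.
#' @param gate a \code{\link{gate_config}}.
#' @return logical: TRUE when accepted as a whistle.
#' @export
false_positive_gate <- function(slope, duration, gate = gate_config()) {
  if (!gate$enabled) return(TRUE)
  if (!is.finite(slope) || !is.finite(duration)) return(FALSE)
  if (!point_in_polygon(duration, slope, gate$accept)) return(FALSE)
  for (rp in gate$reject)
    if (point_in_polygon(duration, slope, rp)) return(FALSE)
  TRUE
}

#' Detect whistles in a waveform
#'
#' Full single-channel detection chain: spectrogram, click suppression,
#' detection function, slope/duration measurement and the false-positive
#' gate. Long records are processed in chunks; events straddling a chunk
#' boundary are deduplicated.
#'
#' @param x single-channel waveform.
#' @param params a \code{\link{spectrogram_params}}.
#' @param f_min,f_max analysis band, Hz.
#' @param P,threshold,W_threshold see \code{\link{detection_function}}.
#' @param gate a \code{\link{gate_config}}.
#' @param chunk_s chunk length for long records, seconds.
#' @return data.frame of detections (possibly 0 rows): start, end,
#'   peak_time, peak_freq, peak_W, slope, duration, accepted.
#' @export
detect_whistles <- function(x, params = spectrogram_params(),
                            f_min = 5e3, f_max = 15e3, P = 10,
                            threshold = 2 * params$fs / params$nfft,
                            W_threshold = 0.8^2, gate = gate_config(),
                            chunk_s = 10) {
  fs <- params$fs
  nchunk <- fs * chunk_s
  ovl <- fs                                 # 1 s chunk overlap
  starts <- if (length(x) <= nchunk + ovl) 1 else
    seq(1, length(x) - params$nfft, by = nchunk)
  rows <- list()
  for (s0 in starts) {
    seg <- x[s0:min(length(x), s0 + nchunk + ovl - 1)]
    if (length(seg) < params$nfft + (P + 3) * params$hop) next
    sp <- compute_spectrogram(seg, params)
    cs <- click_suppress(sp, f_min, f_max)
    if (length(cs$M) < P + 3) next
    df <- detection_function(cs$M, cs$t, P, threshold, W_threshold)
    if (is.null(df$events)) next
    t_off <- (s0 - 1) / fs
    for (i in seq_len(nrow(df$events))) {
      ev <- df$events[i, ]
      sd <- measure_slope_duration(ev, cs$M, cs$t)
      rows[[length(rows) + 1]] <- data.frame(
        start = ev$start + t_off, end = ev$end + t_off,
        peak_time = ev$peak_time + t_off, peak_freq = ev$peak_freq,
        peak_W = ev$peak_W, slope = sd$slope, duration = sd$duration,
        accepted = false_positive_gate(sd$slope, sd$duration, gate))
    }
  }
  if (!length(rows))
    return(data.frame(start = numeric(0), end = numeric(0),
                      peak_time = numeric(0), peak_freq = numeric(0),
                      peak_W = numeric(0), slope = numeric(0),
                      duration = numeric(0), accepted = logical(0)))
  d <- do.call(rbind, rows)
  d <- d[order(d$peak_time), , drop = FALSE]
  # dedupe events found twice in overlapping chunks
  keep <- c(TRUE, diff(d$peak_time) > 0.2)
  d[keep, , drop = FALSE]
}

#' Write detections as JSON lines and CSV
#' @param d detections data.frame from \code{\link{detect_whistles}}.
#' @param path_jsonl,path_csv output paths (either may be NULL).
#' @return invisibly, d.
#' @export
write_detections <- function(d, path_jsonl = NULL, path_csv = NULL) {
  if (!is.null(path_jsonl)) {
    con <- file(path_jsonl, "w")
    for (i in seq_len(nrow(d)))
      writeLines(jsonlite::toJSON(as.list(d[i, ]), auto_unbox = TRUE,
                                  digits = NA), con)
    close(con)
  }
  if (!is.null(path_csv))
    utils::write.csv(d, path_csv, row.names = FALSE)
  invisible(d)
}
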