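# Shared fixture builders: tiny rendered scenes with known ground truth.

render_single_whistle <- function(spec = whistle_spec("rise", 6e3, 12e3, 0.5,
                                                      SL = 165),
                                  pos = c(1000, 0, 2), seed = 42,
                                  sea_state = 0, unit = scene_unit("A"),
                                  t0 = 0.1) {
  r0 <- sqrt(sum((pos[1:2] - unit$pos)^2))
  sc <- scene(list(scene_source("w", "whistle", spec, t0 = t0,
                                trajectory = pos)),
              duration = t0 + r0 / 1500 + spec$duration + 0.25,
              sea_state = sea_state, seed = seed)
  render_scene(sc, list(unit))[[1]]
}

# four channels of a noiseless plane wave from direction (phi, theta):
# a broadband burst fractionally delayed per hydrophone
plane_wave_channels <- function(phi, theta, fs = 100e3, geom = array_geometry(),
                                c_sound = 1500, n = 20000, seed = 1) {
  set.seed(seed)
  w <- synth_whistle(whistle_spec("rise", 6e3, 12e3, 0.1, SL = 120), fs)
  n_hat <- angles_to_unit(phi, theta)
  dts <- expected_tdoas(n_hat, geom, c_sound)
  # per-channel absolute delays relative to array centre
  del <- (geom$H %*% n_hat) / c_sound
  X <- matrix(0, n, 4)
  for (ch in 1:4) {
    dw <- pamtrack:::delayed_waveform(w, 5000 + del[ch] * fs)
    idx <- dw$start + seq_along(dw$w) - 1
    ok <- idx >= 1 & idx <= n
    X[idx[ok], ch] <- X[idx[ok], ch] + dw$w[ok]
  }
  X
}
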