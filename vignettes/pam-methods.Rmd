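---
title: "Methods: passive acoustic detection and tracking of dolphins and boats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: passive acoustic detection and tracking of dolphins and boats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamtrack)
```

## The problem

A permanent passive acoustic monitoring (PAM) station for coastal bottlenose
dolphins listens with two moored acoustic units, each carrying a
four-hydrophone array, and must in real time (i) decide whether a dolphin
whistle is present, (ii) measure the direction of the whistle source from
each unit, (iii) cross the two directions into a position, and (iv) raise a
sector alarm when dolphins and boats share the same patch of sea. `pamtrack`
implements that full chain, together with the design calculators used to
dimension such a station and a synthetic scene simulator that makes every
stage testable without sea data.

## Sonar and link budgets

The station design rests on the passive sonar equation: the signal-to-noise
ratio at range $r$ is

$$L_{SN}(r) = SL - \big(TL(r) + NL + 10\log_{10} B\big),$$

with source level $SL$ (160 dB re 1 µPa @ 1 m for a typical whistle),
transmission loss $TL(r) = k \log_{10} r + \alpha r$ (spherical spreading
$k = 20$; absorption $\alpha = 0.72$ dB/km at the band centroid
$\sqrt{f_{\min} f_{\max}} = 8.66$ kHz), and the ambient spectral density $NL$
read from Wenz-style curves and integrated over the $B = 10$ kHz whistle
band. A whistle is detectable while $L_{SN}(r) \ge DT$. The detection
threshold follows from a chosen operating point on the receiver operating
characteristic: detection index $d = 9$ and $m = f_s/f_{\max}$ samples give
$DT = 10\log_{10}(d/m) = 1.3$ dB, raised to a 5 dB safety value for a
passive system that does not know its signal exactly. `detection_range()`
solves the budget by bisection on [1 m, 100 km] to 0.1 m; monotonicity of
$TL$ makes the root unique.

The Wenz levels are configuration data, not code: the model only needs the
spectral density at the band centroid per sea state (29 dB at sea state 0,
48 dB at sea state 4), and local measurements are accommodated by a
wide-band offset. The radio-link helpers (`radio_horizon`, `fresnel_radius`,
`free_space_loss`, `link_budget`, `min_stream_bandwidth`) are closed-form
arithmetic used to plan the shore link; they are kept because station
planning is part of the workflow the package supports.

## The synthetic scene simulator

`render_scene()` produces what the hardware would record: per unit, four
channels of pressure at 100 kHz. Every source contributes as a *plane wave*:
the channel delays are $(H_i \cdot \hat n)/c$ for the propagation direction
$\hat n$, on top of the common range delay, implemented with 64-tap
windowed-sinc fractional-delay interpolation so that sub-sample TDOAs are
faithful. Amplitude uses spherical-spreading-plus-absorption transmission
loss, so received levels stay physical while the wavefront geometry matches
the plane-wave model the trackers assume (valid beyond roughly 100 m;
closer sources are rendered but flagged). Ambient noise is spectrally flat
Gaussian noise whose density equals the configured Wenz level, so its band
level over any band reproduces `band_noise_level()` by construction.

Whistles are FM tones over one of the seven canonical contour shapes (flat,
rise, fall, concave, convex, sine, multi-loop) with a 10 ms raised-cosine
taper. The study generator additionally draws a 150–400 Hz slow frequency
*wander* for every whistle: natural whistles, including nominally flat
ones, are never spectrally pure, and a laser-flat synthetic tone is both
unrealistic and pathological for time-delay estimation (see below). Unit
tests that verify exact contours use `wander = 0`.

Clicks are Gaussian-enveloped broadband transients; boats are a harmonic
comb at the engine rate plus a broadband cavitation floor. Attitude is
generated by a slow sinusoidal wobble emulating a moored spar buoy and
logged at 5 Hz — tilt-compass hardware samples continuously, and the log
must resolve the ~8 s rocking period, since the tracker interpolates the
log at event time. The renderer applies the attitude at *reception* time
(emission time plus range over $c$), which is the orientation the array
actually has when the wavefront arrives.

What the simulator deliberately omits: multipath and surface reflection,
Doppler, whistle directivity, and real oceanic noise nonstationarity.
Passing tests therefore demonstrate correctness of the algorithms under the
model's own assumptions, not field performance; field detection and
tracking rates depend on conditions the simulator does not emulate.

## Whistle detection

Detection runs on the spectrogram (1024-point FFT, Hann window, 75%
overlap; about 98 Hz × 2.56 ms resolution at 100 kHz). Clicks — broadband
impulses that would otherwise dominate — are suppressed by the negative
second spectral derivative $D_i(f) = 2P_i(f) - P_i(f-df) - P_i(f+df)$,
which rewards narrowband ridges and penalises flat spectra. The per-column
argmax of $D$ inside the 5–15 kHz band forms the maxima track $M(i)$: on a
whistle it hugs the contour, on noise it scatters.

The detection function tests local linearity of the track: with
$M'(k) = M(k+2) - M(k)$ and increments $L(j) = M'(m+j) - M'(m+j-1)$,

$$W(m) = \prod_{j=1}^{P} w(j), \qquad
  w(j) = \begin{cases} 1 & |L(j)| \le \text{threshold} \\
                       0.8 & \text{otherwise}, \end{cases}$$

so $W \in [0.8^P, 1]$, near 1 on smooth tracks and near $0.8^P$ on noise.
Defaults — window $P = 10$, step threshold two frequency bins, event
threshold $W \ge 0.8^2$ (at most two violations) — were chosen on simulated
fixtures and are all configurable; the second-difference form makes the
detector insensitive to the contour slope itself, so all seven shapes pass
with one threshold.

Each event is then measured: the *slope* by a Tukey-bisquare robust line
fit of the track over 40 spectrogram frames centred on the $W$ peak (after
discarding residuals beyond 3σ of an initial fit), and the *duration* as
the longest run of track samples within ±25% of the peak frequency. A
slope/duration gate rejects the classic false positive of moored stations:
mooring-cable screech, which mimics a flat whistle but is near-zero-slope
and sustained. The default gate accepts durations 0.02–3 s and slopes up to
±60 kHz/s, minus a rejection region (duration > 1.2 s and |slope| <
300 Hz/s); both polygons are configuration.

With 40 frames at the 2.56 ms hop the slope window spans ~102 ms; a
40-sample window is honoured as the defining quantity and the millisecond
figure follows from the actual hop. Per-bin spectral equalization is
available but off by default; the second-derivative operator already
removes slowly varying spectral colour.

## TDOA measurement

Bearings rest on the six pairwise time differences of arrival
$\Delta t_{ij}$ measured by plain cross-correlation of the bandpassed
channels (3–23 kHz, mirroring the analogue front end), with the peak
refined to sub-sample precision by parabolic interpolation — at 100 kHz one
sample corresponds to ~3° at broadside for a 5 m pair, so sub-sample care
matters. The redundant set is checked by closure
($\Delta t_{01} + \Delta t_{12} = \Delta t_{02}$, and cyclic variants);
sets whose worst residual exceeds two samples are flagged invalid.

Narrowband signals expose the classic failure of correlation delay
estimation: the correlogram of a weakly modulated tone is periodic in the
lag, and the global peak can sit an integer number of carrier cycles away
from the true delay. When the naive peak set fails closure, `tdoa_set()`
re-derives it by array consistency: candidate directions on a grid are
scored by the correlation *envelope* (magnitude of the analytic signal,
which is cycle-free) each direction predicts on all six pairs, and each
pair's raw peak is re-picked near the best direction's predicted lag. Plain
cross-correlation remains the primary path; generalized cross-correlation
weightings are intentionally not used.

The boat tracker needs no trigger: it computes 8 ms gated correlograms of
the two horizontal pairs continuously. The adaptive gate keeps a window's
peak only above $n_\sigma = 4$ standard deviations of the correlation
values — on pure noise fewer than 5% of windows survive, which fixed the
default.

## Bearing estimation

For a plane wave with direction $\hat n(\varphi_W, \vartheta_W)$, each pair
satisfies $(H_i - H_j)\cdot\hat n = c\,\Delta t_{ij}$. Two routes solve for
$\hat n$: a direct 3×3 linear solve on the contiguous pairs (exact on
noiseless data; the deviation of the raw solution length from 1 is a
quality flag), and minimization of the least-squares functional

$$G(\varphi_W, \vartheta_W) = \sum_{i,j} \big(\Delta t_{ij}^{meas} -
  \Delta t_{ij}^{theo}(\varphi_W, \vartheta_W)\big)^2$$

over the full direction sphere, which is robust to inconsistent measured
sets. The grid minimization uses a 2° coarse grid — matching the system's
overall angular accuracy — followed by two nested local refinements to
~0.02°; nested grids were preferred to a line-search refinement because
they are deterministic and vectorize over all six pairs at once. The two
routes agree within 1° on consistent sets and serve as mutual oracles in
the tests.

The source lies opposite the wave: $\varphi_S = \varphi_W + \pi$,
$\vartheta_S = \pi - \vartheta_W$, rotated into the world frame by the
attitude (roll → pitch → yaw, yaw = compass + $\psi_0$) and reported as a
compass bearing. The world frame is a local ENU tangent plane; at zero
attitude the body axes coincide with ENU and increasing compass turns the
buoy clockwise. If no attitude sample lies within 5 s, the bearing is
emitted body-frame and flagged.

For boats the calculation collapses to the sea-surface plane:
$\Delta T_{20} = L_c\cos\alpha$, $\Delta T_{31} = L_c\sin\alpha$ with
$L_c = L/c$ the field-calibrated pair travel time. Each pair alone leaves a
mirror ambiguity ($2\pi - \alpha_{20}$; $\pi - \alpha_{31}$); each
contributes a circular two-Gaussian mixture with σ set to four times its
propagated error $\Delta\alpha = \Delta\tau / (L_c\sqrt{1 - (\tau/L_c)^2})$,
and the product of the two densities suppresses the mirrors. The reported
error is the smaller of the two pair errors: near a pair's axis
($\tau \to L_c$) its error diverges and the orthogonal pair takes over. The
implementation maximizes the product locally from the most consistent
candidate pair and matches a brute-force 0.1° grid argmax of the same
density in the tests.

## Triangulation and alerting

Simultaneous world-frame azimuths from the two units (1.8 km apart,
GPS-synchronized) are intersected in the horizontal plane; rays within 3°
of parallel, or intersecting behind a unit, yield an honest no-fix. The
inter-unit arrival-time difference provides an independent check: the fix
must lie near the hyperbola of equal range difference, with a 50 m default
residual threshold (configurable; the value is a length scale of the
station geometry, not a physical constant). At bearing accuracy
$\Delta\alpha$ a target at range $r$ carries a square error area of side
$r\,\Delta\alpha$ — 2° at 3700 m gives the ~130 m side used as the
acceptance yardstick.

Alerting divides the study area into five ~2 km rectangular sectors
(geometry from configuration). A fix maps to its containing sector; a
bearing-only detection maps to every sector its ray crosses within
detection range. A sector turns yellow with a dolphin event inside the hold
time (default 10 min — no published value; chosen as the time scale over
which a pod plausibly stays within a 2 km sector), red when a boat event
joins it, green otherwise. The state machine logs every transition and
replays deterministically.

## Calibration

Two quantities are field-calibrated with a circling boat of known GPS
track. The pair travel time $L_c$ comes from the extrema of each pair's
TDOA series over the laps: at the extremum the boat is aligned with the
pair axis and the delay equals $L_c \cos\beta$, with
$\beta = \arctan(h/R)$ the elevation of the boat seen from the pair
(≈ 7° at 150 m range and 20–25 m depth, a 0.9% correction). The series is
low-pass filtered (0.05 Hz) against window-level jitter; extrema within one
filter time constant of the record edges are discarded because the
zero-phase filter's edge transients create spurious ones. $L_c$ is the mean
of the corrected absolute extrema over both pairs and all laps.

The compass offset $\psi_0$ — the unknown angle between the compass
indicator and the array axes — is the circular mean of (GPS-derived
bearing − acoustically tracked bearing) over the lap, matched at 1 Hz; a
circular dispersion above 20° rejects the calibration. Any mean magnetic
declination is absorbed into $\psi_0$ by construction.

## Numerical choices and edge cases

- Sound speed defaults to 1500 m/s; wherever $L/c$ appears, the calibrated
  value supersedes it.
- Hydrophone indexing puts pair (H0, H2) on body x and (H1, H3) on body y,
  5 m deeper; this makes the contiguous-pair matrix of the linear solve
  non-singular (determinant 125 m³).
- Correlation ties between equal peaks resolve to the smallest |lag|;
  all-zero windows yield an undefined-TDOA sentinel, and any undefined pair
  invalidates the set.
- `detection_range` returns an `undetectable` sentinel rather than an error
  when the budget is negative at the 1 m reference.
- $|\Delta T| \le L_c$ is enforced with a two-sample clipping tolerance
  (arccos/arcsin saturate); beyond that the sample is discarded.
- Elevation is constrained toward the surface half-space only through the
  refinement start; the functional itself is searched over the full sphere.

## Study sizes

The bundled studies use 100 rendered whistle scenes for bearing/
triangulation recovery, 50 whistles plus 10 noise-only minutes for the
detector, and 3 laps × 2 sound speeds for calibration; these sizes give
stable rates while keeping a full run in a few minutes on one CPU.

## Known limitations

Near-pure-tone whistles remain the hardest case for correlation-based
TDOAs even with envelope disambiguation; the residual outliers in the
bearing study are flat-contour whistles. Multiple simultaneous sources per
trigger window are not separated (first peak wins), multipath is not
modelled, and the alerting hold time and sector geometry are policy
choices, not measurements.
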