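# pamtrack

Passive acoustic monitoring (PAM) toolkit for detecting and tracking
bottlenose dolphins and boats from moored hydrophone arrays.

Coastal dolphin populations overlap heavily with leisure-boat traffic, and
collision/disturbance mitigation needs to know — in real time — when
dolphins and boats share the same patch of sea. A permanent PAM station
answers that with two moored acoustic units, each carrying two orthogonal
5 m hydrophone pairs at different depths, recording 4-channel audio at
100 kHz. `pamtrack` implements the complete processing chain of such a
station, plus the design calculators used to dimension it and a synthetic
acoustic-scene simulator so that every stage is testable without sea data.

It is aimed at bioacousticians and marine-conservation engineers building
or studying whistle-based monitoring systems.

## What it computes

**Station design.** The passive sonar equation
`L_SN(r) = SL − (k·log10 r + α r + NL + 10·log10 B)` with a
ROC-derived detection threshold `DT = 10·log10(d·f_max/f_s)`, Wenz-style
ambient noise tables, and a bisection solve of `L_SN(r) = DT` for the
maximum detection range; radio-link arithmetic (horizon, Fresnel zone,
free-space loss, link budget, stream bandwidth).

**Whistle detection.** Spectrogram (1024-pt FFT, Hann, 75% overlap), click
suppression by the negative second spectral derivative, the per-frame
maxima track `M(i)`, a multiplicative linearity detection function
`W(m) ∈ [0.8^P, 1]`, and a slope/duration gate that rejects
mooring-cable screech and similar false positives.

**Bearing estimation.** Six pairwise TDOAs by cross-correlation with
sub-sample parabolic refinement and closure consistency
(`Δt01 + Δt12 = Δt02`); plane-wave direction by direct linear solve and by
grid minimization of the least-squares functional
`G(φ_W, θ_W) = Σ (Δt_meas − Δt_theo)²`; rotation to a world compass
bearing through the buoy attitude (roll → pitch → yaw = compass + ψ0).
For boats, continuous 8 ms gated correlograms of the horizontal pairs give
`ΔT20 = Lc·cos α`, `ΔT31 = Lc·sin α`; mirror ambiguities are removed by
multiplying the two per-pair Gaussian-mixture densities, with the
propagated error `Δα = Δτ/(Lc·√(1−(τ/Lc)²))`.

**Triangulation, calibration, alerting.** Two-ray intersection with an
inter-unit TDOA hyperbola check and the `r·Δα` error-square side;
field-calibration estimators for `Lc = L/c` (circling-boat TDOA extrema,
elevation-corrected) and the compass offset `ψ0` (circular mean of GPS
minus tracked bearings); a five-sector green/yellow/red alarm state
machine with replayable transition logs.

**Simulation.** `render_scene()` renders whistles (7 contour shapes),
echolocation clicks, boat engines and sea-state ambient noise to each
unit's four channels with fractional-delay plane-wave arrivals and
physical received levels, returning per-sample ground truth for use as a
test oracle.

## Worked example

Design table, then one simulated whistle tracked end to end:

```r
library(pamtrack)

p <- sonar_params()                     # SL 160 dB, 5–15 kHz, k 20, α 0.72, DT 5
sonar_budget_table(p)
#>   sea_state NL_spectral NL_band  range_m
#> 1         0          29      69 9260.370
#> 2         4          48      88 1910.761
detection_threshold(9, 100e3, 15e3)
#> DT = 1.3 dB (S/N0 = 1.35)

spec <- whistle_spec("rise", 6e3, 12e3, 0.5, SL = 160)
src  <- scene_source("w1", "whistle", spec, t0 = 0.1, trajectory = c(700, 1200, 1))
sc   <- scene(list(src), duration = 1.6, sea_state = 0, seed = 7)
r    <- render_scene(sc, list(scene_unit("A", pos = c(0, 0))))

det <- detect_whistles(r$A$x[, 1])
det[, c("start", "end", "peak_freq", "slope", "duration", "accepted")]
#>     start     end peak_freq    slope duration accepted
#> 1 1.02144 1.53088  8984.375 12057.64    0.384     TRUE

dolphin_bearings(r$A$x, r$A$fs, det, attitude_log = r$A$attitude)[[1]]
#> bearing 30.26 deg (world frame), elevation 89.22 deg
r$A$truth$bearing_deg[1]
#> [1] 30.26                                  # ground truth

error_square(3700, 2)
#> [1] 129.2                                  # metres, at the range limit
```

The detector found the whistle where it was rendered (it arrives at
~1.02 s: emission at 0.1 s plus 1389 m of travel), measured a 12 kHz/s
rising contour of 0.38 s, and the recovered compass bearing matches the
ground truth to within a hundredth of a degree at this SNR. `130 m` is the
error-square side implied by 2° bearing accuracy at the 3.7 km range
limit.

A thin CLI over the same functions is in `inst/cli/pam.R`
(`budget`, `simulate`, `detect` subcommands).

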