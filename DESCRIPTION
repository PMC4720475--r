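Package: pamtrack
Title: Passive Acoustic Monitoring, Whistle Detection and Acoustic Tracking of Dolphins and Boats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for a two-unit permanent passive acoustic monitoring (PAM)
    station targeting coastal bottlenose dolphins. Provides passive sonar and
    radio-link budget calculators, a synthetic underwater acoustic scene
    simulator (whistles, echolocation clicks, boat engines, sea-state dependent
    ambient noise rendered to a four-hydrophone array), spectrogram-based
    whistle detection with click suppression and a slope/duration
    false-positive gate, cross-correlation time-difference-of-arrival (TDOA)
    measurement, plane-wave bearing estimation for dolphins and boats,
    two-unit triangulation, on-field calibration recovery (pair travel time
    L/c and compass offset), and sector-based alerting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
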