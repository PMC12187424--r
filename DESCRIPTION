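Package: jvpradar
Title: Jugular Venous Pulse Extraction from 60 GHz FMCW Radar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-contact extraction of the jugular venous pulse (JVP) from
    60 GHz frequency-modulated continuous-wave (FMCW) radar data cubes.
    Implements the full processing chain: fast-time range FFT with first-peak
    range-bin selection, per-antenna slow-time I/Q extraction, SNR-based
    antenna selection, eigen-beamforming of a half-wavelength receive pair
    with a direction-of-arrival power scan, Taubin SVD circle fitting for
    I/Q offset correction, phase-difference skin-displacement reconstruction,
    JVP band filtering with transient trimming, template-correlation pulse
    detection, and common-frequency synchronization against a finger
    photoplethysmogram.  A physically parameterized FMCW echo simulator
    (JVP-like surface motion, two-tone speaker plate, real-valued I-only
    mixer, half-wavelength antenna pair) makes every stage testable without
    radar hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
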