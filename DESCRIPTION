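Package: ovomech
Title: Oocyte Mechanics from AFM Force Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of atomic-force-microscopy force spectroscopy on
    mammalian oocytes during postovulatory aging. Reads tab-separated
    force-distance curves and stress-relaxation traces, calibrates
    cantilever spring constants (thermal noise and spring-on-spring),
    detects contact points, fits single- and two-layer spherical Hertz
    models (outer and inner zona pellucida moduli E1 and E2), integrates
    the viscous energy dissipated between approach and retraction, fits
    two-element generalized Maxwell stress-relaxation models, quantifies
    cortical-granule exocytosis from fluorescence line profiles, and
    assembles degradation-aligned per-oocyte timelines with group
    statistics. Ships synthetic-data generators that stand in for raw
    oocyte recordings in all tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
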