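Package: corridorprobe
Title: Virtual Bore-Probe Feasibility Analysis of Transpubic Screw Corridors
Version: 0.1.0
Authors@R: person("Corridor", "Probe Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Feasibility analysis of retrograde transpubic screw corridors on
    CT volumes in Hounsfield units. Places a straight cylindrical virtual bore
    probe between entry and exit landmarks, samples grey values at 1 mm
    stations with trilinear interpolation, detects cortical perforation
    (HU > 400) outside the entry and exit crossings, decides corridor
    accessibility, measures screw length, classifies perforation sites, and
    aggregates cohorts into length-normalized HU profiles, summary tables and
    nonparametric test results. Includes a parametric curved arc-tube bone
    phantom generator with analytic ground truth for end-to-end validation,
    and readers/writers for NIfTI-1 and MetaImage volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
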