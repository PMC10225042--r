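Package: tussilab
Title: Acoustic Analysis of Coughs and Airway-Clearance Maneuvers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the acoustic analysis of transient airway-protective
    maneuvers: voluntary coughs, voluntary throat clearings, and induced
    reflexive coughs. Provides envelope-based segmentation of single
    maneuvers (-30 dB trimming and energy normalization), temporal contours
    of amplitude, sample entropy, and kurtosis summarized by discrete cosine
    transform shape descriptors (average, slope, curvature), an exact DCT
    filter-bank spectral decomposition with relative band energies and
    zero-crossing band frequencies, nonparametric group comparisons
    (Wilcoxon signed-rank, Mann-Whitney U, bootstrap confidence intervals
    for medians), and a seeded synthetic-maneuver generator for end-to-end
    pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
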