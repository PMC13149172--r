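Package: cardiomap
Title: Optical Mapping Analysis of Cardiomyocyte Syncytia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of voltage- and calcium-sensitive fluorescence
    recordings of spontaneously active cardiomyocyte monolayers: beat
    detection and per-beat quantification of action potentials and calcium
    transients (durations at configurable recovery fractions,
    triangulation, upstroke slope, diastolic baseline, amplitude,
    Fridericia rate correction), per-pixel activation-time mapping with
    plane-fit conduction-velocity estimation, rule-based rhythm and
    arrhythmia classification, isoproterenol response ratios, and a
    decision-tree group-statistics layer (Kolmogorov-Smirnov, F-test,
    ANOVA/Tukey or Kruskal-Wallis/Mann-Whitney with Bonferroni
    correction, chi-square incidence tests). Includes a kinematic
    synthetic-syncytium simulator that produces fluorescence movies with
    exact ground truth, so every stage of the pipeline is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    rhdf5,
    signal,
    stats,
    tiff,
    tools,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
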