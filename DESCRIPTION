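Package: homecage8
Title: Homecage Behavioral Phenotyping for the 8-Cage Imaging Assay
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for 22-hour homecage behavioral phenotyping of
    mice in an 8-cage timelapse imaging assay. Computes tracking-derived and
    pose-derived behavior parameters (movement classes, acclimation,
    habituation to visual stimuli, quadrant occupancy, stretch-attend
    posture, sociability), summarizes discrete behavioral-syllable sequences
    (frequencies, bout durations, transition graphs), derives CatWalk-style
    gait parameters from footfall event logs (step sequence patterns,
    support, base of support, cadence), assembles 125-parameter behavioral
    profiles, and clusters them with PC1-loading-weighted Ward linkage.
    Includes seeded synthetic-data generators with planted, recoverable
    group effects for validation, and the nonparametric screening layer
    (Shapiro-Wilk gate, Wilcoxon rank-sum screens, Kruskal-Wallis with
    Dunn post hoc, two-way ANOVA with Tukey HSD).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    png,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
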