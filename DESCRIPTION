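Package: myomech
Title: In Situ Skeletal Muscle Mechanics and Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for in situ skeletal muscle contractile and
    morphological phenotyping. Decomposes tetanic length-force series into
    passive (second-order exponential) and active (nested-polynomial,
    F-test selected) components and extracts optimum length, active slack
    length and optimum force; computes the maximal rate of force
    development, normalized force-frequency curves and the fatigue index
    from force-time traces; derives serial sarcomere number, optimum fiber
    length, muscle volume, physiological cross-sectional area, tendon
    length, section-corrected myonuclear number and myonuclear domain;
    quantifies fiber cross-sectional area, fiber-type proportions, SDH
    activity and endomysium/perimysium thickness from label masks; and
    converts qPCR cycle thresholds to relative transcript levels. A
    synthetic-data generator with known ground truth makes every stage
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
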