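Package: tibslope
Title: Three-Dimensional Measurement of the Posterior Tibial Slope from Bone Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the posterior tibial slope of the medial and lateral
    tibial plateau and rim directly on a three-dimensional surface model of
    the proximal tibia. The anatomical tibial axis is fitted through centroids
    of serial shaft cross-sections (5 mm steps starting 15 cm distal to the
    joint surface, stopping when the section area exceeds 1.6 times the first
    section), articular regions are summarised by total-least-squares (PCA)
    planes, and the slope is the signed sagittal-plane angle between each
    plane normal and the axis. Also provides the conventional two-line
    radiographic slope measurement, two-way random-effects absolute-agreement
    single-measures intraclass correlation for reader-reliability studies,
    and a deterministic parametric generator of synthetic proximal tibiae
    with known ground-truth slopes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
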