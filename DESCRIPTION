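Package: monorecruit
Title: Monocyte Recruitment Quantification and Chemotaxis Coefficient
    Estimation for Vascularized Tumor-on-Chip Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing monocyte trafficking in microfluidic
    vascularized tumor models. Segments self-assembled microvascular
    networks from confocal max-projections, locates the central tumor well
    by morphological closing, detects fluorescently labelled monocytes and
    classifies them into luminal, extravasated and recruited compartments.
    Fits a one-dimensional Keller-Segel drift-diffusion model to endpoint
    cell positions from unidirectional gel-channel migration assays to
    estimate the random-motility coefficient D (from no-chemoattractant
    controls) and the chemotaxis coefficient chi per condition, and
    discriminates chemotaxis from chemokinesis. Includes seeded synthetic
    generators for vascular-network images with ground-truth cell labels
    and for biased-random-walk migration snapshots, so every stage of the
    pipeline is verifiable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    yaml,
    jsonlite,
    tiff,
    png,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
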