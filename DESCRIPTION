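Package: dropletkit
Title: Quantification of Engineered Protein Droplets from Microscopy and
    Turbidity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify liquid-liquid phase separation of engineered
    multivalent RGG-domain proteins. Detects circular droplets in fluorescence
    or transmitted-light time-lapse images with a circular Hough transform,
    links them into trajectories, and derives dissolution/assembly kinetics,
    turbidity transition temperatures, salt-concentration phase diagrams,
    cargo enrichment indices, and FRAP-based diffusion coefficients. A
    constructs module predicts protease digestion products, fragment masses,
    RGG valency, and rule-based phase and recruitment behavior of fusion
    proteins. A synthetic-data module generates images, movies, FRAP traces,
    and turbidity ramps with bundled ground truth so every estimator can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
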