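Package: chromotype
Title: Classification of Sister-Chromatid Cohesion Morphology in Metaphase
    Chromosome Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for scoring sister-chromatid cohesion (SCC) from cropped
    single-chromosome images of Giemsa-stained metaphase spreads. Chromosomes
    are classified into three morphology types (A: tightly cohered; B: arms
    separated but joined at the centromere; C: sister chromatids fully
    separated) with a frozen convolutional feature extractor and a trainable
    linear classification head. The package implements the full image
    preprocessing chain (white-out of bystander objects, resizing,
    contrast/brightness and gamma adjustment, per-channel shade
    standardization), a repeated-trial evaluation protocol with balanced
    training subsets, Grad-CAM saliency maps, genotype-contrast readouts for
    cohesion-defect detection, and a seeded synthetic chromosome-image
    generator so the whole pipeline runs and is testable without any external
    image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    EBImage,
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
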