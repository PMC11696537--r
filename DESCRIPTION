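Package: dreamon
Title: REM-Dream-Inspired GAN Class Interpolation and Noise-Robustness
    Benchmarking for Medical-Style Image Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how data augmentation affects the robustness
    of image classifiers to parametric noise, built around DreamOn: a
    generative augmentation scheme in which a dual conditional GAN (one
    generator for lesion masks, one conditional image generator) is fed
    interpolated two-class weight vectors to synthesize training images that
    sit between diagnostic categories, the way REM dreams recombine episodic
    memories. Includes a synthetic breast-ultrasound-like phantom generator
    with lesion masks, the comparison augmentations (standard geometric and
    photometric augmentation, pixel-space Mixup, Manifold Mixup), Gaussian,
    speckle, and salt-and-pepper noise ladders with doubling intensities and
    chance-level calibration, a compact residual-network classifier harness
    with soft-label cross-entropy and validation-balanced-accuracy
    checkpointing, and evaluation statistics: balanced accuracy, expected
    calibration error, stability deltas, binomial above-chance thresholds,
    and Fleiss' kappa for inter-rater agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
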