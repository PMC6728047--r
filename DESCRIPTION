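Package: halometry
Title: Morphometry of Asymmetric Neurite Outgrowth from Ganglion Explants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies asymmetric radial neurite outgrowth ("halo" asymmetry)
    from ganglion explant cultures. Provides a seeded synthetic dish-image
    generator with per-explant ground truth, automatic halo/core segmentation,
    moment-based ellipse fitting with a percent core-displacement asymmetry
    index, a blinded random-rotation orientation protocol with an automated
    morphology scorer and simulated observers, circular statistics for
    co-orientation (Rayleigh test, von Mises sampling and concentration
    estimation), Fourier-spectrum anisotropy detection, and cohort-level
    summaries tying the stages into a reproducible pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
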