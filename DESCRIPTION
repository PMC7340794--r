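Package: lineprofiler
Title: Filament Tracing and Transverse Profile Analysis for Expansion
    Single-Molecule Localization Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated tracing of filamentous structures in rendered
    single-molecule localization microscopy (SMLM) images, extraction and
    model fitting of transverse intensity profiles (Gaussian, bi-Gaussian,
    tri-Gaussian, cylinder and multi-cylinder cross-section models), and a
    cylindrical-distribution forward model of immunolabeled, optionally
    expanded microtubules.  The forward model predicts peak-to-peak sidewall
    distances for configurable labeling geometries (antibody and DNA-linker
    shells, pre- versus post-expansion labeling), quantifies linkage error,
    and inverts measured peak-to-peak distances into molecular expansion
    factors.  Includes a seeded synthetic-data generator producing ground
    truth localization tables and rendered images for end-to-end validation,
    plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
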