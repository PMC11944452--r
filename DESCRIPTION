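Package: lignocomp
Title: Predicting GC-MS Composition of Depolymerized Lignin from TGA and FT-IR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for estimating the GC-MS group composition of
    hydrothermally depolymerized lignin from inexpensive thermogravimetric
    (TGA) and infrared (FT-IR) measurements. Provides a seeded simulator of
    study-like raw data at arbitrary hydrothermal liquefaction temperatures,
    preprocessing pipelines for the three analytical modalities, conditional
    one-dimensional convolutional generators for data augmentation, a
    multimodal variational autoencoder with product-of-experts latent fusion
    and a mixture-of-experts prediction head, and an evaluation suite based
    on linear-interpolation references with MAE, R-squared, Pearson and
    Wasserstein-1 metrics. All neural components are implemented in base R
    with reproducible seeded training.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
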