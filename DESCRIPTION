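Package: owapool
Title: Size-Intensive Pooling Functions for Atomistic Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physically motivated pooling functions (sum, average, max, softmax,
    weighted average, orbital weighted average and coefficient pooling) for
    predicting localized intensive molecular properties such as HOMO energies
    and ionization energies with atomistic neural networks. Includes Mulliken
    orbital localization fractions and a localization index, a tight-binding
    synthetic-data generator producing molecules with HOMOs spanning localized
    and delocalized regimes, a reference radial-symmetry-function descriptor,
    a compact multilayer-perceptron training engine with a joint
    energy-plus-localization loss, stratified evaluation utilities, and an
    extended-XYZ reader and writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
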