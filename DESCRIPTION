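Package: isohb
Title: Multispectral Imaging of Hemoglobin Concentration and Scattering
    Power at Isosbestic Wavelengths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates maps of total hemoglobin concentration (Cth) and
    scattering power (b) of skin from diffuse reflectance images acquired
    at four isosbestic wavelengths of hemoglobin (420, 450, 500, 585 nm).
    Includes a weighted-photon Monte Carlo transport kernel for layered
    media, generation of a training grid of two-layer skin states, fitting
    of the empirical multiple-regression formulas that map per-pixel
    absorbances to Cth and b, relative-change time courses over regions of
    interest, inverse Monte Carlo recovery of absorption and reduced
    scattering from slab reflectance/transmittance pairs, and a synthetic
    data generator for phantom sets, image stacks, time courses and
    layer-thickness sensitivity studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    tiff,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
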