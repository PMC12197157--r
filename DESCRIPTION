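Package: tuberlight
Title: Tissue Optics and Monte Carlo Light Transport for Blackheart
    Detection in Potato Tubers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Characterizes light propagation in healthy and blackhearted
    potato tuber tissue for non-destructive Vis-NIR detection of the
    disorder.  Provides a synthetic generator of absorption and reduced
    scattering spectra for healthy, slightly blackhearted and blackhearted
    medulla tissue; a forward adding-doubling radiative-transfer solver for
    slab reflectance and transmittance with the inverse (IAD) search that
    recovers optical properties from integrating-sphere measurements; a
    voxel-based Monte Carlo photon transport engine with Henyey-Greenstein
    scattering, Fresnel boundaries and Russian-roulette termination,
    together with slice, half-tuber and whole-tuber layered geometries;
    diffusion-approximation penetration depth and wavelength-selection
    metrics; PLS-DA and SVM-DA discrimination of tissue classes from
    optical features; and an end-to-end pipeline that chains generation,
    inversion, simulation and classification into a reproducible run.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    mixOmics,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
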