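Package: fibrilsaxs
Title: Scanning SAXS/WAXS Analysis of Collagen Fibril Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of scanning small- and wide-angle X-ray
    scattering (SAXS/WAXS) data from type 1 collagen tissues, as used to
    monitor structural changes induced by sugar glycation. Implements a
    periodic two-level (gap/overlap) axial electron-density forward model of
    the meridional SAXS profile with a staged coordinate-descent fitting
    routine, per-pixel Gaussian peak fitting on power-law backgrounds with
    per-sample histogram condensation by Gaussian mixtures, an even/odd
    Bragg-order asymmetry statistic, gap-fraction error landscapes, PCA plus
    k-means segmentation of scan grids, and a ground-truth-labelled synthetic
    scan generator so that the entire pipeline is testable without beamline
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
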