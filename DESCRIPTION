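Package: specmetal
Title: Optimized Spectral Indices for Mapping Heavy-Metal Content in Plant Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates foliar heavy-metal concentrations (Cr, Cu, Ni, Zn) from
    visible/near-infrared (VNIR) reflectance spectra using optimized
    normalized-difference vegetation indices. Provides an exhaustive two-band
    index search against leaf chemistry, Kennard-Stone calibration/validation
    splitting, univariate index-concentration regression with RMSE and
    residual-predictive-deviation (RPD) assessment, and per-pixel concentration
    mapping on hyperspectral image cubes with NDVI-based vegetation masking and
    polygon clipping. Includes spectral preprocessing (Savitzky-Golay smoothing,
    empirical-line radiance-to-reflectance correction, band-grid resampling),
    descriptive phytoextraction chemistry (bioconcentration and enrichment
    factors), and a synthetic-data generator that emulates metal-induced
    pigment responses in leaf spectra for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
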