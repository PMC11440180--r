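Package: multiflim
Title: Multispectral Fluorescence Lifetime Image Analysis by Global
    Three-Component Decay Unmixing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of multispectral time-correlated single photon
    counting (TCSPC) fluorescence lifetime imaging (FLIM) data. Fits
    fluorescence decays recorded in many spectral channels either
    channel-by-channel with an IRF-convolved bi-exponential model, or
    globally with a constrained three-component model (free NAD(P)H,
    protein-bound NAD(P)H, flavins) in which lifetimes are shared across
    channels, the NAD(P)H emission spectra are fixed, and the flavin
    spectrum is free above a wavelength cutoff. Includes a photon-realistic
    simulator of multispectral TCSPC image cubes, cell- and pixel-level
    pipelines (spatial binning, lambda-average maps, cell-integrated
    decays, spheroid distance-to-border profiles), and group-level
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    data.table,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
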