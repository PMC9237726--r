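Package: spectromap
Title: Cross-Sample Analysis of FTIR Microspectroscopy Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control, pre-processing and downstream analysis of
    spatially resolved Fourier transform infrared (FTIR) microspectroscopy
    data across multiple samples. Provides per-pixel spectral QC (hole and
    light-scatter exclusion with saved positions for later spatial
    repopulation), CO2-region excision, vector normalization and
    Savitzky-Golay second-derivative spectra; principal component analysis
    with eigen-spectra and explained variance; k-nearest-neighbour graph
    clustering of pixels with the Leiden algorithm; band-area integration,
    peak-shift-aware window selection and amide I secondary-structure
    fraction estimation; and reconstruction of per-pixel results as 2-D
    maps in acquisition layout. Includes a seeded synthetic-scene generator
    emulating region-structured tissue maps for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    png,
    pracma,
    signal,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
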