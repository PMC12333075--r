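Package: peatspec
Title: Spectral Unmixing and Alpha-Diversity Modelling for Boreal Peatland
    Vegetation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for analysing close-range reflectance
    spectra of boreal peatland vegetation. Harmonizes field and laboratory
    reflectance-factor spectra (segmented Savitzky-Golay smoothing, removal
    of atmospheric water-absorption regions, species-level averaging),
    simulates Sentinel-2 MSI bands from hyperspectral data via spectral
    response functions, estimates species fractional cover by non-negative
    least-squares spectral unmixing against an endmember library, computes
    Shannon-Wiener and Simpson alpha-diversity from point-intercept cover
    data, and predicts plot diversity from spectra with partial least
    squares regression using cross-validated component selection. Includes
    a seeded synthetic-data generator emulating minerotrophic and
    ombrotrophic plant communities so the full pipeline is testable without
    external spectral libraries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    vegan,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
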