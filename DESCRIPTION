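Package: phenospectra
Title: Spectral Phenotyping of Field Trials Across Handheld and Aerial Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for plot-level spectral phenotyping of plant breeding
    trials. Implements empirical-line radiometric calibration of aerial
    multispectral imagery (single- and multi-panel), quantum-efficiency
    derivation of a near-infrared band, hyperspectral quality control and
    narrowband-to-broadband synthesis, within-trial normalization, soil
    masking and zonal extraction from orthomosaics, the standard
    spectral reflectance indices (NDVI, NDRE, TCARI, NWI, MTVI),
    broad-sense heritability from variance components estimated by REML
    or by expected mean squares, and cross-platform association analyses
    (Pearson correlation, linear regression, principal components).
    Includes a synthetic field-trial generator (augmented and
    alpha-lattice designs, latent genetic values, parametric canopy
    spectra, platform observation channels with solar-drift noise) so
    the whole chain can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
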