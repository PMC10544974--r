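# phenospectra

Plot-level spectral phenotyping for plant breeding trials, across the two
platform families breeders actually use: handheld radiometers
(broadband or full-range hyperspectral) and UAS-mounted multispectral
cameras. The package implements the full analysis chain from raw sensor
readings to breeding-relevant statistics, plus a synthetic field-trial
generator so every stage can be validated end to end without field data.

## What it computes

**Radiometric calibration (empirical line).** UAS cameras record digital
numbers (DN), not reflectance. Given panel readings, each band is calibrated
as

    SR = DN × m + b

with `m`, `b` fit per band by ordinary least squares of known panel
reflectance on observed DN (multi-panel strategy), or as a ratio through the
origin from a single bright panel. Cameras without a native NIR band get one
derived from quantum-efficiency coefficients,
`NIR = 2.921 × Blue − 0.754 × Red`, normalized by 3.07 when indices are
computed.

**Hyperspectral processing.** Full-range curves (338–2515 nm) are
quality-controlled below 1000 nm (negative reflectance, implausible values,
red-edge inversion, spikes), averaged into 50 nm broadbands, and optionally
normalized by the within-trial standard deviation per band.

**Spectral reflectance indices** (exact published forms):

| Index | Formula |
|-------|---------|
| NDVI  | (R800 − R680)/(R800 + R680) |
| NDRE  | (R800 − R700)/(R800 + R700) |
| TCARI | 3[(R700 − R680) − 0.2(R700 − R550)(R700/R680)] |
| NWI   | (R970 − R800)/(R970 + R800) |
| MTVI  | (R700 − R550)/√((2·R800 + 1)² − (6·R800 − 5·√R680) − 0.5) |

**Broad-sense heritability.** Variance components (genotype, genotype ×
environment, replicate, block, residual) are estimated by REML (lme4) or by
expected-mean-squares moments on balanced designs, and combined on an
entry-mean basis:

    H² = σ²G / (σ²G + σ²GE/x + σ²ε/(x·r))

with `x` environments and `r` replications.

**Association analytics.** Pairwise-complete Pearson correlation matrices,
per-trial OLS regressions of yield on each index, and PCA of
trait/platform columns with variance explained per component.

**Orthomosaic utilities.** Simulated georeferenced multi-band rasters with
plot polygons, NDVI-threshold soil masking, and pixel-center zonal
extraction of plot means.

**Synthetic trials.** Augmented designs with repeated checks and resolvable
alpha-lattices; Gaussian genetic/G×E/residual effects with a yield trait
genetically correlated to the canopy trait; parametric vegetation spectra
driven by the latent trait and a water driver; and observation channels with
collection-window solar drift — so the handheld-versus-UAS contrast can be
studied with known ground truth.

## Worked example

```r
library(phenospectra)

cfg <- pipeline_config(era = "era_2020", out_dir = tempfile(), seed = 7)
res <- run_pipeline(cfg)
#> generate: 304 plots, 120 entries, x=2
#> calibrate: multi_panel on 6 band(s), 0 value(s) clipped
#> process: 0/304 curves removed by quality control
#> indices: ndvi, ndre, tcari, nwi, mtvi
#> heritability: 11 trait/platform fits
#> association: correlation, PCA (Dim1 69.6%), 10 regressions

subset(res$heritability, trait %in% c("ndvi", "nwi", "yield"))[,
       c("platform", "trait", "H2")]
#>  platform trait    H2
#>       uas  ndvi 0.669
#>       uas   nwi 0.294
#>  handheld  ndvi 0.672
#>  handheld   nwi 0.624
#>    ground yield 0.764

round(res$correlation$r["yield",
      c("uas_ndvi", "handheld_ndvi", "uas_nwi", "handheld_nwi")], 2)
#>      uas_ndvi handheld_ndvi       uas_nwi  handheld_nwi
#>          0.46          0.47         -0.55         -0.80
```

The run simulates a two-environment augmented trial (120 entries, 8 checks),
observes every plot through a five-panel-calibrated UAS channel and a
quality-controlled hyperspectral handheld channel, computes the five indices
per platform, and reports heritability, correlations, regressions and PCA.
Vegetation indices correlate positively with grain yield; the water index
NWI correlates negatively, as expected — a lower NWI means a wetter, cooler
canopy. All stage artifacts (CSV/JSON, orthomosaic TIFF + GeoJSON when
enabled) land in `cfg$out_dir` with a provenance manifest.

The `era_2018` preset switches to the earlier processing regime:
single-panel calibration, quantum-efficiency-derived NIR, and a broadband
radiometer handheld channel.

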