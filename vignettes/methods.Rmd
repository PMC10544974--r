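---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models, the tunable parameters, and
the design decisions behind `phenospectra`, in the spirit of a methods
section: what is assumed, what is configurable, and what the synthetic
experiments do and do not demonstrate.

## The trait model

Every simulated plot value — the latent canopy trait and grain yield alike —
follows the standard random-effects decomposition used in multi-environment
breeding trials:

$$y_{ijkl} = \mu + g_i + (ge)_{ij} + r_{jk} + b_{jkl} + \varepsilon_{ijkl}$$

with independent Gaussian effects: genotype $g_i \sim N(0, \sigma^2_G)$,
genotype-by-environment $(ge)_{ij} \sim N(0, \sigma^2_{GE})$, replicate
within environment, block within replicate, and plot residual
$\varepsilon \sim N(0, \sigma^2_\varepsilon)$. Gaussian effects were chosen
because they match the assumptions of the linear mixed model used for
estimation; nothing in the estimation code depends on the generator.

Yield has its own effect set, with its genotype effects correlated to the
canopy-trait genotype effects at `genetic_corr_yield` (default 0.7, a
moderately strong genetic association typical of a useful secondary trait).
The plot water driver is the standardized yield deviation, so wetter, cooler
canopies accompany higher yield; this single choice produces the expected
negative association of a 970 nm water index with both yield and the
vegetation indices.

Broad-sense heritability on an entry-mean basis is

$$H^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_{GE}/x +
\sigma^2_\varepsilon/(xr)}$$

with $x$ environments and $r$ replications. With nonnegative components the
ratio is in $[0, 1]$ by construction; no clamping is applied. For
populations that pool replicated and unreplicated trials the choice of $r$
is a convention, not an estimate; `broad_sense_heritability()` takes $r$
explicitly and $r = 1$ is the conservative choice for augmented material.

Variance components are estimated two ways. The REML route fits the model
with `lme4::lmer()` (which constrains components to be nonnegative),
dropping terms the design cannot identify: a single environment collapses
G×E into error, single-replicate designs drop the replicate term. The
`anova_moments` route computes the classical expected-mean-squares
estimators from the genotype × environment ANOVA with replicates nested in
environments ($MS_G = \sigma^2_\varepsilon + r\sigma^2_{GE} +
xr\sigma^2_G$, $MS_{GE} = \sigma^2_\varepsilon + r\sigma^2_{GE}$,
$MSE = \sigma^2_\varepsilon$), floored at zero; it is valid for balanced
designs and serves as an independent cross-check on the REML route.

Adjusted entry means use a fixed-genotype companion fit per environment with
sum-to-zero contrasts on replicate and block, so a genotype's coefficient is
its mean at the average design level. In orthogonal layouts (complete
blocks) these equal raw means exactly; in incomplete-block layouts they
correct for block contamination.

## Trial designs

Two layouts are generated. Resolvable alpha-lattices require $r \ge 2$
complete replicates, each partitioned into incomplete blocks of equal size
(`block_size` must divide `n_entries`). Augmented designs leave test entries
unreplicated and repeat each of `n_checks` check genotypes once per
incomplete block; with `checks_rep` blocks the plot count is
`n_entries + n_checks × (checks_rep − 1)`. The check placement (one
occurrence of every check per block, tests spread evenly) is a design
decision: real programs vary here, and only the totals are typically
reported.

## The canopy spectrum family

Canopy reflectance is a piecewise-logistic vegetation curve on 338–2515 nm.
The latent trait is squashed to a canopy-density proxy
$c = \mathrm{plogis}(\text{latent})$ which (i) deepens the red absorption
floor, $R_{680} \approx 0.28 - 0.24c$, (ii) raises the NIR plateau,
$\approx 0.32 + 0.28c$, joined through a logistic red edge centered at
715 nm, and (iii) adds a green reflectance bump at 550 nm. The water driver
$w = \mathrm{plogis}(\text{water})$ deepens Gaussian absorption features at
970, 1200, 1450 and 1940 nm. Reflectance is clamped to $[0, 1.2]$.

The family guarantees, by construction: a local reflectance minimum in the
red absorption region below the NIR shoulder; a strictly monotone red edge
on 680–780 nm; NDVI strictly increasing in the latent trait with other
drivers held fixed; 970 nm reflectance strictly decreasing in the water
driver; and a flat, soil-like curve (NDVI well below 0.3) at the latent
minimum. Any curve family with these properties would serve; no
radiative-transfer realism (leaf-angle distributions, soil coupling,
directional effects) is claimed.

## Observation channels and solar drift

A sensor is a band set (center/width; band value = left-closed window mean
of the curve), an affine DN transfer (`dn_gain`, `dn_offset`; identity for
reflectance-reporting handhelds), additive Gaussian noise (`noise_sd`,
default 0.008 reflectance units — a realistic plot-mean repeatability), a
collection window half-width (3 h for handheld sweeps, i.e. a six-hour
window around solar noon; 2 h for the UAS), and a solar-drift process.

Drift is multiplicative and linear in hours from solar noon:

$$d(t, \lambda) = 1 - a\,|t|\,w_\lambda, \qquad d(0, \cdot) = 1$$

floored at zero, with `drift_amplitude` $a = 0.05\,\mathrm{h^{-1}}$ by
default. The per-band sensitivity weights $w_\lambda$ (1.0 at 550 nm, 0.55
at 680, 0.8 at 700, 1.35 at 800, 1.45 at 970 by default) are the one
deliberate extension of a scalar linear drift law: a drift that multiplies
every band equally cancels exactly in normalized-ratio indices, so a scalar
law would make the collection-window mechanism invisible in NDVI, NDRE and
NWI. Physically, illumination-geometry changes are band-dependent — canopy
NIR reflectance is dominated by multiple scattering and is considerably more
sensitive to sun angle and canopy shadowing than the strongly absorbed red —
so the weights rise into the NIR. A sinusoidal-in-time alternative would be
equally defensible; the linear form was chosen for closed-form testability.

The 2018-era UAS preset has no native NIR band. Its blue channel carries a
strong secondary 775–825 nm response (weight 3; the red channel a weak one,
0.2), which is the sensor property that makes a quantum-efficiency NIR
derivation meaningful in the first place: after panel calibration,
`2.921 × Blue − 0.754 × Red` recovers an NIR proxy that ranks canopies
correctly but is attenuated and biased relative to a measured NIR band —
deliberately emulating the lower data quality of a single-panel,
derived-NIR era. Whether the 3.07 normalization multiplies or divides is
ambiguous as usually stated; the package divides (configurable in
`qe_coefficients()`), which keeps the derived band on a reflectance-like
scale.

## Calibration

`SR = DN × m + b` is fit per band with true reflectance regressed on DN, so
the coefficients apply directly to DN. The `±` sometimes written in the
empirical-line relation is read as a free-signed intercept. Single-panel
calibration forces $b = 0$; on a channel with a nonzero offset this leaves a
reflectance-dependent bias (exact at the calibration panel, inflated for
darker targets) that multi-panel calibration removes exactly — the
mechanistic reason multi-panel strategies improve data quality. Negative
fitted slopes are returned but flagged, not silently accepted. Calibrated
reflectance is clipped to $[0, 1.2]$ rather than $[0, 1]$ to tolerate
specular returns; clip counts are always reported.

## Hyperspectral processing

"Abnormal" curves are screened below 1000 nm with four independently
switchable rules: reflectance $< -0.01$, reflectance $> 1.2$, red-edge
inversion (mean on 760–800 nm below the mean on 660–690 nm), and adjacent-
sample jumps $> 0.3$. The thresholds are defaults, not dogma; each rule can
be disabled. Broadband synthesis is the unweighted mean of narrowband
samples in a left-closed 50 nm window — left-closed so a sampling grid
partitions unambiguously. Within-trial normalization divides each band by
its sample (n−1) standard deviation within the trial; zero-spread groups
are an error naming the group. Note that per-band SD normalization is *not*
neutral for ratio indices (each band gets its own divisor), so normalized
and unnormalized variants genuinely differ; the pipeline exposes
`normalize_handheld` rather than guessing, with the normalized variant as
the default.

## Orthomosaics, masking, extraction

Simulated orthomosaics place 1.5 m × 3.5 m sown plots on an axis-aligned
grid at 0.1 m ground-sampling distance (0.25 m is the accepted maximum, so
each plot spans at least 6 × 14 pixels), with 0.5 m alleys of flat soil
(NDVI 0.10 — separable from any live canopy by a single threshold) and plot
polygons inset 0.2 m from the sown edges to avoid border pixels. Soil
masking thresholds per-pixel NDVI at 0.3 by default — configurable because
canopy closure varies with growth stage; fully masked plots are flagged and
their means set missing rather than silently averaged. Zonal extraction
uses the pixel-center-in-polygon rule (no area weighting), which matches
common zonal-statistics defaults and is exactly testable against
brute-force enumeration. Rasters are written as 32-bit-float multi-page
TIFF with an ESRI world file and a band-order sidecar; polygons as GeoJSON
with a `plot_id` property.

## Association analytics

Correlations are pairwise-complete Pearson with per-cell sample sizes;
constant columns yield missing cells with the reason recorded. PCA is
listwise-complete (the two conventions mirror the defaults of the usual
statistical routines), on the correlation matrix by default since traits mix
units, with a deterministic sign convention (largest-magnitude loading
positive). PCA is run at plot level by default; genotype-mean PCA is a
caller-side aggregation.

## The collection-window experiment

`collection_window_experiment()` isolates the mechanism by which slow
handheld sweeps degrade index heritability. Identical genetics, spectra
*and observation-noise draws* are pushed through two channels that differ
only in when plots are observed: a handheld sweep spreading plot times
across ±3 h of solar noon versus a 20-minute UAS capture (±10 min). The
solar drift then perturbs handheld observations plot-by-plot, inflating
the residual variance of every index and depressing $H^2$; because the
channels are paired, the contrast is structural rather than a race against
sampling noise, and the per-index UAS-minus-handheld difference is positive
for all five indices when averaged over seeds. The experiment demonstrates
the *direction* and mechanism of the platform difference; its magnitude
depends directly on `drift_amplitude` and the drift weights and is not a
calibrated estimate of any particular field campaign.

## Problem sizes and numerical choices

The validation suite uses sizes chosen to give stable estimates at
interactive run times: variance-component recovery uses balanced
alpha-lattices of 300 entries × 2 environments × 3 replicates over 20
simulations (REML); the window experiment uses 150 entries × 2 × 2 over 20
paired simulations (moments estimators, valid on the balanced design);
index oracles use 1000 random band vectors. Seeds propagate from a single
master seed through a deterministic child-seed scheme, so every artifact is
bit-reproducible; all derived seeds stay within 32-bit integer range.
Undefined index values (zero denominators, negative red reflectance under a
square root) propagate as missing-with-reason rather than exceptions, so
plot-level defects never abort trial-level runs.

## Limitations

The generator emulates the statistical structure of multi-platform trials —
variance components, design layouts, band arithmetic, collection-window
drift — not radiometric physics. It does not model atmospheric effects,
BRDF, vignetting, mixed pixels at plot borders beyond the soil/canopy
dichotomy, spatial field trend, or non-Gaussian residuals. Passing tests
therefore demonstrate that the analysis chain is correct and that the
platform contrast follows from the drift mechanism; they do not certify
performance on any particular real sensor. The heritability machinery
assumes independent effects; kinship-informed BLUP and spatial correction
are out of scope.
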