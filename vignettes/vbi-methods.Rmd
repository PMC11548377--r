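---
title: "Mapping aquatic vegetation with vegetation and bloom indices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping aquatic vegetation with vegetation and bloom indices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbimap)
```

## The problem

Shallow lakes switch between a clear-water state stabilised by submerged
macrophytes and a turbid state dominated by phytoplankton. Tracking that
transition needs decade-scale maps of four cover types over the lake
surface: submerged aquatic vegetation (SAV), floating/emergent aquatic
vegetation (FEAV), algal blooms (AB), and open water (OW). Field campaigns
cannot deliver that coverage retrospectively; Landsat-class surface
reflectance can, provided the classification is simple enough to apply
uniformly across sensors and decades.

`vbimap` implements the vegetation-and-bloom-indices (VBI) approach: four
per-pixel spectral indices feed a fixed three-step decision tree, and the
resulting class maps are turned into coverage time series and related to
water-quality drivers.

## The indices

For a pixel with surface reflectances $R_{\lambda_i}$ in the six reflective
bands (blue, green, red, NIR, SWIR1, SWIR2):

* **AVI** (aquatic vegetation index) is negated tasseled-cap wetness,
  $\mathrm{AVI} = -\sum_{i=1}^{6} k_{\lambda_i} R_{\lambda_i}$. The
  coefficients $k_{\lambda_i}$ depend only on the sensor. Open water has
  high wetness and hence low AVI; any macrophyte canopy — emergent or
  submerged near the surface — depresses wetness and raises AVI.
* **FAI** (floating algae index) is the height of the NIR reflectance above
  a linear baseline interpolated between the red and SWIR1 bands at the NIR
  band centre:
  $\mathrm{FAI} = R_{NIR} - \left[R_{Red} + (R_{SWIR1} - R_{Red})
  \frac{\lambda_{NIR}-\lambda_{Red}}{\lambda_{SWIR1}-\lambda_{Red}}\right]$.
  Surface algal accumulations push NIR above the baseline; water sits
  below. The baseline construction makes FAI insensitive to flat additive
  perturbations such as thin haze.
* **NDVI** $= (R_{NIR}-R_{Red})/(R_{NIR}+R_{Red})$ separates vigorous
  emergent canopies (high) from water-attenuated submerged canopies (near
  zero).
* **NDWI** $= (R_{Green}-R_{NIR})/(R_{Green}+R_{NIR})$ is positive over
  open water and is used only to extract the water population for
  calibration.

The wetness coefficient sets shipped in `get_profile()` are the standard
reflectance-domain derivations (Crist for TM, Huang et al. for ETM+, Baig
et al. for OLI), and the band centres are nominal Landsat values (TM red
660 nm, NIR 830 nm, SWIR1 1650 nm; OLI 655/865/1609 nm). The source
method does not pin a particular published wetness set, so both the
coefficients and the wavelengths are override arguments of
`get_profile()`: substituting another published set is a one-line change
and everything downstream follows.

Zero-denominator pixels in NDVI/NDWI become nodata rather than 0 — a 0/0
ratio carries no information and must not masquerade as a valid index
value. Reflectance is not clipped to $[0, 1]$: small negative values are a
normal outcome of atmospheric correction over dark water, and clipping
would bias exactly the population (open water) that the calibration relies
on.

## The decision tree

Per valid pixel:

1. **AVI > t_avi** → aquatic vegetation, else non-vegetation.
2. Within vegetation: **NDVI > t_ndvi** → FEAV, else SAV.
3. Within non-vegetation: **FAI > t_fai** → AB, else OW.

Every node uses a strict inequality; a value exactly on a threshold falls
to the lower branch. This fixed tie-break makes the tree a deterministic
function of the indices, which the test suite exploits by comparing the
vectorized implementation against a per-pixel nested-conditional reference.

### Thresholds

The method's published description fixes the tree's structure but not its
cut values, so the defaults here are the package's own choices, all exposed
in `vbi_thresholds()`:

* `t_ndwi = 0` — the conventional water cut for a green/NIR normalized
  difference.
* `t_avi` — calibrated per scene: the mean AVI of the NDWI-extracted water,
  plus `k_sigma = 2` water standard deviations. The water-mean statistic
  alone would split open water 50/50 under symmetric noise; the $+2\sigma$
  offset keeps the expected false-vegetation rate of open water near 2.3%
  under a Gaussian water model. Calibration requires at least 30 water
  pixels and fails loudly otherwise. A fixed global `t_avi` is equally
  supported (`classify_batch()` runs either mode), since whether one global
  cut or per-scene recalibration is preferable depends on how stable the
  sensor and atmosphere are across the archive.
* `t_ndvi = 0.2` — NDVI below about 0.1 means essentially no vegetation
  signal; emergent canopies sit far above 0.2 while submerged canopies,
  NIR-attenuated by the overlying water, stay near zero. 0.2 splits the
  gap with margin on both sides.
* `t_fai = 0` — any positive baseline exceedance is treated as bloom.

Lake masking happens *before* classification (`lake_mask` argument), so
terrestrial vegetation can never leak into the FEAV class; cloud/shadow
screening is assumed done upstream and an arbitrary invalid-pixel mask is
honored the same way.

## Accuracy assessment

`build_confusion()` counts reference/predicted label pairs with rows as
reference; `overall_accuracy()` is the diagonal fraction and
`cohen_kappa()` the chance-corrected agreement
$\kappa = (p_o - p_e)/(1 - p_e)$. Both statistics are invariant under
transposition, so the row/column convention only matters for the per-class
producer's and user's accuracies in `accuracy_report()`. A degenerate
matrix with $p_e = 1$ raises an error instead of returning a number. The
package ships the published Bao'an Lake validation counts
(`baoan_reference_confusion()`), for which it computes an overall accuracy
of 93.42% and $\kappa = 0.87$ (the matrix's full-precision kappa is 0.8669;
coarser roundings of the same matrix appear elsewhere as 93% / 0.86).

## Coverage dynamics

`coverage_fraction()` divides class pixel counts by the number of *valid*
lake pixels, not the total lake area, so cloud-masked pixels do not deflate
coverage; the denominator choice is recorded with the output. Dates map to
meteorological seasons (Mar–May spring, Jun–Aug summer, Sep–Nov autumn,
Dec–Feb winter), which contain the April–May and July–August imaging
windows typically used for spring and summer mapping and extend naturally
to the quarterly water-quality joins.

## Environmental drivers

`linear_fit()` is ordinary least squares with the two-sided t-test on the
slope — deliberately the same model a spreadsheet-era limnology workflow
would use, so its $R^2$ and $p$ are directly comparable with published
values. The depth/transparency ratio $Z_M/Z_{SD}$ proxies underwater light
at the canopy: `flag_light_limitation()` flags ratios strictly above 5.17,
the value at which SAV disappearance was observed in Bao'an Lake (a nearby
report rounds the same phenomenon to 5.2; the threshold is an argument).
`seasonal_compare()` summarises a water-quality variable by season and
letters the seasons by pairwise Welch tests with Holm correction — chosen
over a pooled-variance ANOVA/Tukey because quarterly field series routinely
have unequal variances and unequal group sizes — followed by an
insert-and-absorb compact letter display.

## The synthetic generators

Real multi-decade Landsat archives and field chemistry tables cannot ship
with a package, so every pipeline stage is exercised against synthetic data
with known truth:

* `generate_scene()` builds a six-band scene as class-mean spectra plus
  independent per-band Gaussian noise, alongside its ground-truth class
  map. The default spectra (`default_class_spectra()`) emulate the four
  signatures at Landsat scale: green-peaked dark water, an NIR-peaked bloom
  above the red–SWIR baseline, a near-surface submerged canopy (water-like
  visible bands, NDVI ≈ 0, wetness depressed below water), and an emergent
  canopy with an NIR plateau. The generator evaluates the decision tree on
  its own noiseless spectra before emitting anything and refuses — naming
  the violated node — if any class would land on the wrong branch, so an
  untestable fixture cannot silently appear.
* `generate_lake_timeseries()` interpolates the SAV region's area linearly
  between a start and end fraction across years (vacated area becomes open
  water) over a constant emergent fringe, emulating the declining-coverage
  pattern of a macrophyte-losing lake.
* `generate_env_series()` draws quarterly TP, TN, depth and Secchi depth
  around season-specific means (low-TP clear springs, higher-TP turbid
  summers, values of a eutrophic shallow lake: spring TP 0.032 mg/L,
  summer 0.085 mg/L) and ties SAV coverage to one driver through
  `coverage = a + b·driver + N(0, σ²)`, returning the truth for recovery
  tests. Concentrations are truncated at zero; the default relation
  (a = 0.65, b = −5 per mg/L TP, σ = 0.08) spans the observed coverage
  range over the realistic TP range.

What the generators deliberately do *not* model: spatially correlated
noise, mixed pixels at class boundaries, sun glint, thin clouds,
atmospheric residuals, and the spectral diversity of real macrophyte
communities. Passing tests on synthetic scenes therefore demonstrate that
the algorithmic machinery is correct and robust to independent sensor
noise — not that the default thresholds are optimal for any particular
lake. All generators are bit-for-bit reproducible under their seed.

## Numerical and design notes

* The printed form of the FAI baseline in the method's source is
  typographically garbled; the implementation uses the canonical linear
  baseline of the index's original derivation (red-to-SWIR1 interpolation
  evaluated at the NIR centre), which that source itself cites.
* Rasters are plain matrices with north-up pixel-centre georeferencing;
  point sampling (accuracy assessment, mask rasterization) consistently
  uses nearest pixel centre, preventing off-by-one-pixel drift between
  modules. Files travel as TIFF with a JSON sidecar carrying geotransform,
  CRS, band order, sensor and the affine packing applied for storage;
  class maps use a frozen code table (0 nodata, 1 SAV, 2 FEAV, 3 AB, 4 OW).
* Problem sizes used in the validation suite and acceptance script —
  256×256 scenes over 20 seeds for noise robustness, 200 simulated
  campaigns of 40 dates for CI coverage and type-I rate, 50 small random
  scenes for the classifier-oracle comparison — were chosen to bound
  Monte-Carlo error well below the margins being tested while keeping a
  full run in seconds.
* A flat (zero-variance) response in `linear_fit()` returns slope 0 and
  $R^2 = 0$ by convention rather than the 0/0 that a raw least-squares
  summary would produce.

## Known limitations

The classifier is pixel-wise and threshold-based: no spatial context, no
sub-pixel mixing, no species discrimination. Index thresholds other than
the calibrated AVI cut are global constants, so lakes with optically
extreme water (high CDOM, suspended sediment) may need different `t_ndvi` /
`t_fai`. The regression module fits independent-error OLS; interannual
coverage series are autocorrelated in reality, and the reported p-values
inherit that caveat. The published field results the method was built
around (per-year coverage percentages, driver $R^2$ values measured on
real scenes and field tables) depend on data that is not public; the
package validates the machinery by simulation instead, and the shipped
validation counts are the one fully reproducible published quantity.
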