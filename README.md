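# vbimap

Mapping submerged aquatic vegetation (SAV), floating/emergent aquatic
vegetation (FEAV), algal blooms (AB) and open water (OW) in shallow lakes
from multiband surface-reflectance imagery — the vegetation-and-bloom-indices
(VBI) workflow, for lake ecologists and remote-sensing practitioners who
need decade-scale macrophyte coverage series from Landsat-class data.

## The method

Four per-pixel spectral indices are computed from the six reflective bands
(blue, green, red, NIR, SWIR1, SWIR2):

* **AVI** = −Σᵢ k_λᵢ·R_λᵢ — negated tasseled-cap wetness (k are the
  sensor-specific wetness coefficients); rises over any macrophyte canopy.
* **FAI** = R_NIR − [R_Red + (R_SWIR1 − R_Red)·(λ_NIR − λ_Red)/(λ_SWIR1 −
  λ_Red)] — NIR height above the red–SWIR1 baseline; positive over surface
  algae.
* **NDVI** = (R_NIR − R_Red)/(R_NIR + R_Red) — high for emergent canopies,
  near zero for submerged ones.
* **NDWI** = (R_Green − R_NIR)/(R_Green + R_NIR) — positive over open
  water; used to extract the water population for calibration.

A fixed three-step decision tree classifies each pixel: AVI > t_avi splits
vegetation from non-vegetation; within vegetation NDVI > t_ndvi splits
FEAV from SAV; within non-vegetation FAI > t_fai splits bloom from open
water. The AVI cut is calibrated per scene as mean + 2·sd of the AVI over
NDWI-extracted water. Downstream, class maps become per-class coverage
fractions and seasonal/interannual time series; accuracy is assessed with
a confusion matrix (overall accuracy, Cohen's κ); coverage is related to
water-quality drivers (TP, TN, Z_M/Z_SD) by ordinary least squares, with a
light-limitation flag at the Z_M/Z_SD = 5.17 SAV-disappearance threshold.

Synthetic generators (`generate_scene()`, `generate_lake_timeseries()`,
`generate_env_series()`) produce scenes and water-quality campaigns with
known ground truth so the whole pipeline runs and validates at desk scale.

## Worked example

```r
library(vbimap)

# a 64x64 synthetic scene with known classes, mild sensor noise
g <- generate_scene(64, 64, noise_sd = 0.01, seed = 7)
cm <- classify_scene(g$scene)          # per-scene AVI calibration
print(cm)
#> class_map: 64 x 64 pixels
#>
#>  SAV FEAV   AB   OW
#> 1023 1031 1028 1014

mean(cm$codes == g$truth$codes)        # agreement with ground truth
#> [1] 0.9958496

coverage_fraction(cm, date = "2012-04-25")$fractions
#>       SAV      FEAV        AB        OW
#> 0.2497559 0.2517090 0.2509766 0.2475586

# the shipped Bao'an Lake validation counts
rep <- accuracy_report(baoan_reference_confusion())
print(rep)
#> accuracy_report (n = 3191)
#>          predicted
#> reference FEAV SAV  AB   OW
#>      FEAV   10   0   0    0
#>      SAV    88 775  17    0
#>      AB      0   0 160    0
#>      OW     11  88   6 2036
#> overall accuracy: 93.42%   kappa: 0.87

# coverage vs a driver
sim <- generate_env_series(n_dates = 24, a = 0.65, b = -5, seed = 42)
linear_fit(sim$env$TP, sim$coverage$sav_coverage)
#> linear fit (n = 24): y = 0.6399 + -4.917 x   R^2 = 0.570, p = 2.01e-05
```

The class map recovers the generator's four quadrants almost perfectly
(99.6% of pixels at this noise level); the validation counts reproduce the
published 93.42% overall accuracy and κ = 0.87; and the regression
recovers the planted coverage–TP slope (−5 per mg/L) within its standard
error.

## Analysis workflow

The `analysis/` scripts run the pipeline end to end as a narrative
workflow, writing tables under `results/` (bulky rasters go to
`scratch/`):

```sh
Rscript analysis/01_simulate.R      # 24-year declining-SAV lake series
Rscript analysis/02_classify.R      # per-scene calibration + classification
Rscript analysis/03_accuracy.R      # published counts + point-sampling check
Rscript analysis/04_env_drivers.R   # OLS fits, light limitation, seasonal TP
```

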