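# ezcc

Quantification of photoreceptor integrity and choriocapillaris perfusion
from macular OCT/OCTA, with a synthetic phantom generator that makes every
stage verifiable without patient data.

## The problem

In intermediate age-related macular degeneration (AMD), drusen elevate the
retinal pigment epithelium (RPE) while photoreceptors and the
choriocapillaris (CC) — the capillary bed supplying them — degenerate as a
unit. Two en-face readouts, both measured in a 5-mm circle centred on the
fovea of a 6 × 6 mm macular scan (500 × 500 A-scans), quantify the two
sides of that unit:

* **EZ normalized reflectivity.** The ellipsoid-zone (EZ) band is extracted
  as a 21 µm slab whose inner boundary sits 45 µm above the RPE reference;
  its mean en-face intensity is rescaled between a dark (vitreous) and a
  bright (RNFL) reference,
  `(mu_EZ - mu_vit) / (mu_RNFL - mu_vit)`,
  making the readout invariant to global intensity gain/offset.
* **CC flow deficits.** The CC en-face flow image (20 µm slab, 29 µm below
  the RPE-fit floor) is compensated by its structural image to undo drusen
  shadowing, binarized with the Phansalkar local threshold
  (`T = m (1 + 2 e^{-10 m} + 0.25 (s/0.5 - 1))`, circular window of radius
  3 px), cleaned of components with equivalent diameter < 24 µm, and
  summarized as FD% (deficit area fraction), mean deficit size (µm²) and
  count.

Drusen are delineated by maximum-entropy (Kapur) binarization of the RPE
elevation map (RPE minus its pathology-excluding quadratic floor fit,
rendered on 8 bits with a 100 µm ceiling), and every metric is also
reported for the drusen-free part of the circle. Cohort analysis follows
the standard plan: Shapiro–Wilk-gated t / Mann–Whitney group comparisons
and Spearman correlations between EZ reflectivity and CC/drusen metrics.

The package is aimed at readers who want to reproduce, probe or extend
this class of en-face OCT/OCTA analyses with fully synthetic, seeded data:
the `phantom` module plants drusen mounds, EZ attenuation fields,
flow-deficit fractions and group/correlation structure as known ground
truth, so thresholds, masks, compensation and statistics are all testable
as parameter-recovery problems.

## Worked example

```r
library(ezcc)

# one affected phantom eye: two drusen, default speckle
cfg <- phantom_config(grid_rows = 96, grid_cols = 96,
                      lateral_pitch_um = 62.5, depth_voxels = 100,
                      axial_pitch_um = 5, bm_center_um = 400,
                      drusen_spec = data.frame(center_row = c(34, 62),
                                               center_col = c(38, 60),
                                               radius_um = c(300, 250),
                                               peak_um = c(60, 90)),
                      ez_attenuation = 0.75, seed = 7)
run <- run_eye(cfg)
round(t(run$record[, c("ez_norm_whole", "ez_norm_drusen_free",
                       "fd_percent_whole", "fd_percent_drusen_free",
                       "drusen_area_mm2", "drusen_percent_of_roi")]), 3)
#> ez_norm_whole           0.877
#> ez_norm_drusen_free     0.878
#> fd_percent_whole       25.796
#> fd_percent_drusen_free 25.984
#> drusen_area_mm2         0.453
#> drusen_percent_of_roi   2.309
```

The planted EZ attenuation of 0.75 corresponds to a normalized
reflectivity of `(0.75 * 130 - 4) / (110 - 4) = 0.88`, recovered here as
0.877; the two planted drusen cover 2.3 % of the 5-mm circle (0.45 mm²),
and 25.8 % of the analysed CC area falls below the local flow threshold
(the planted deficit fraction for this seed is 20.0 %, plus the phantom's
speckle noise floor and deficit-edge pixels at this coarse 62.5 µm
pitch).

A full synthetic cohort (35 affected vs 35 control eyes, planted EZ means
0.76 vs 0.85, FD% 24.1 vs 19.2, rank coupling −0.4 between EZ attenuation
and deficit fraction in the affected group):

```r
out <- run_cohort(generate_cohort(35, seed = 1))
summarize_cohort(out$records)   # mean ± SD, median, IQR per group/region
out$comparisons                 # gated t / Mann-Whitney per variable
out$correlations                # Spearman rho per group and region
```

## The analysis scripts

`analysis/` contains the numbered drivers that produce the package's
result tables under `results/`:

1. `01_recovery.R` — planted FD fractions {10, 20, 30} % recovered at the
   native 500 × 500 geometry; drusen-footprint Dice; shadow-compensation
   efficacy.
2. `02_cohort.R` — the full 35 + 35 phantom cohort: per-eye records, group
   summary tables, group tests, correlations.
3. `03_calibration.R` — type-I error of the gated comparison and the
   noncentral-t power function vs Monte Carlo.

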