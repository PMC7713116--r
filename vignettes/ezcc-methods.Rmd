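---
title: "Quantifying photoreceptor reflectivity and choriocapillaris flow deficits: methods and phantom design"
author: "ezcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying photoreceptor reflectivity and choriocapillaris flow deficits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ezcc)
```

## The measurement problem

In intermediate age-related macular degeneration (AMD), drusen lift the
retinal pigment epithelium (RPE) off Bruch's membrane while the
photoreceptors and the choriocapillaris (CC) — the capillary bed that feeds
them — degenerate together. Two en-face readouts quantify this unit from
swept-source OCT/OCTA of the macula (a 6 × 6 mm field sampled on a
500 × 500 lateral grid, 12 µm/pixel, analysed within a 5-mm circle centred
on the fovea):

* **EZ normalized reflectivity** — mean intensity of the en-face image of a
  21 µm slab whose inner boundary sits 45 µm above the RPE reference,
  rescaled between a dark reference (vitreous) and a bright reference
  (retinal nerve fibre layer, RNFL):
  \[
  \tilde{I}_{EZ} \;=\; \frac{\mu_{EZ}-\mu_{vit}}{\mu_{RNFL}-\mu_{vit}} .
  \]
  The two-point rescaling makes the readout invariant under any global
  affine intensity transform $I \mapsto aI + b$ ($a>0$), which is the whole
  point: absolute OCT brightness depends on uncontrollable acquisition
  factors.
* **CC flow deficits (FD%)** — the CC en-face flow image (a 20 µm slab
  29 µm below the RPE-fit floor) is compensated by its structural
  counterpart to undo drusen shadowing, binarized with the Phansalkar local
  threshold (window radius 3 px), cleaned of isolated deficits with
  equivalent diameter $2\sqrt{A/\pi} < 24$ µm, and summarized as the deficit
  area fraction, the mean deficit size (µm²) and the deficit count.

Because drusen both distort the EZ and shadow the CC, every metric is also
computed in the **drusen-free region**: the 5-mm circle minus the drusen
footprint obtained by maximum-entropy binarization of the RPE elevation map.

No patient data ship with this package. Instead, a synthetic phantom
generator plants known ground truth — drusen mounds, EZ attenuation
fields, flow-deficit fractions, group effects and rank couplings — so that
every stage is testable as a parameter-recovery problem.

## Pipeline

For one eye (`run_eye()`): segment the RPE from the structural volume →
fit the pathology-excluding floor → elevation map → maximum-entropy drusen
partition of the ROI → EZ slab, reference sampling and normalization →
CC compensation, Phansalkar binarization, small-deficit removal and
regional FD metrics. `run_cohort()` repeats this per eye and reproduces the
cohort analysis plan: Shapiro–Wilk-gated t / Mann–Whitney comparisons and
Spearman correlations.

### RPE segmentation and the floor fit

The segmentation is deliberately phantom-grade (the clinical source of such
maps is the device's proprietary multilayer segmentation): per A-scan the
depth profile is averaged over a 3 × 3 lateral neighbourhood, the brightest
band is located on a heavily smoothed profile (20 µm boxcar — spanning the
RPE band, so speckle cannot pull the argmax into the dimmer EZ band), and
the band's superficial edge is then placed on a lightly smoothed (10 µm)
profile as the most vitreal contiguous voxel above the midpoint between the
band peak and the local baseline just above the band. Using a
profile-derived baseline keeps the edge affine-invariant; using the
peak-to-gap midpoint maximizes the decision margin against speckle.
Residual outlier clusters are replaced by a wide (9-point separable) median
reference, and the surface gets a final light median filter.

The "RPE fit" floor is a total-degree-2 polynomial fitted by iterated
outlier exclusion: A-scans where the RPE sits more than 10 µm above the
current fit (towards the vitreous — i.e. drusen) are discarded and the fit
repeated (≤ 10 iterations). If fewer than 40 % of A-scans survive, the fit
is declared unreliable. A quadratic floor is exact for the phantom's
quadratic Bruch's membrane and matches the smooth, pathology-ignoring
behaviour expected of an RPE-fit reference. Elevation is
$\max(0, z_{floor}-z_{RPE})$ in µm, rendered linearly onto 8 bits with a
100 µm ceiling.

### Drusen delineation

The maximum-entropy (Kapur) threshold maximizes the summed Shannon
entropies of the background and foreground class histograms over the 256
8-bit bins, restricted to ROI pixels; ties break to the lowest level. Empty
bins contribute zero entropy ($0\log 0 \equiv 0$). On elevation maps the
histogram is a large spike near zero plus the drusen mass, and the chosen
threshold usually lands just above the noise floor (≈ 5 µm of elevation),
so the recovered mask approximates the full planted footprint;
occasionally the entropy functional has a second, mid-dome optimum and the
threshold jumps inside the dome height range — both behaviours are
intrinsic to the method and visible in the recovery distribution, which is
why the mask-recovery experiment reports the 10-seed mean Dice. In
`run_eye()` the binarization is only attempted when some ROI pixel reaches
the "considerable elevation" criterion (20 µm by default): binarizing a
flat elevation map would merely partition segmentation noise, and a healthy
eye is reported as drusen-free.

Drusen area is the ROI area with elevation ≥ 20 µm and drusen volume the
integral of elevation over it. The 20 µm default stands in for the
unpublished internal criterion of clinical RPE-analysis software and is
fully configurable.

### CC compensation and binarization

Compensation multiplies the flow raster by
$S_{ref}/\max(S_{smooth},\,\varepsilon S_{ref})$, where $S_{smooth}$ is the
structure raster smoothed by an isotropic Gaussian (15 µm, about the
lateral optical resolution — wide enough to suppress per-pixel speckle in
the divisor, narrow enough to track shadow edges at drusen shoulders) and
$S_{ref}$
its ROI median. The floor fraction $\varepsilon = 0.2$ caps amplification
at 5× so that near-zero structural signal cannot blow up noise; output is
clipped to the input dynamic range. Because the phantom applies one
multiplicative shadow to flow and structure alike, compensation is exactly
recoverable there, and the recovery experiment checks that the
drusen-vs-drusen-free FD% gap closes to under a third of its uncompensated
size.

The Phansalkar threshold for a pixel with local window mean $m$ and
population SD $s$ (circular window, radius 3 px, truncated at borders) is
\[
T = m\left(1 + p\,e^{-q m} + k\left(\frac{s}{R}-1\right)\right),
\qquad p=2,\; q=10,\; k=0.25,\; R=0.5,
\]
on intensities in $[0,1]$; a pixel is a deficit iff its value is $\le T$.
Only the window radius is study-specific; the constants are the method's
published defaults. Images already inside $[0,1]$ are used as-is (so a
constant 0.5 image is valid and yields an empty deficit mask, and an
all-zero image is validly all-deficit); anything else is min-max rescaled,
and a constant image outside $[0,1]$ is rejected as non-normalizable.
A cited calibration of this radius assumed 1024 × 1024 sampling of 6 × 6 mm
scans; whether the device resamples 500 × 500 scans is unstated, so the
radius is kept in pixels of whatever grid is analysed and no resampling is
performed. The radius-3 window's quoted area (~103 µm²) is not consistent
with any obvious pixel pitch and is not used.

Connected components are 8-connected. The < 24 µm equivalent-diameter
removal is strict; at the native 12 µm pitch it removes components of ≤ 3
pixels (432 µm², 23.4 µm) and keeps 4-pixel ones (576 µm², 27.1 µm).
Components clipped by an analysis mask count only their in-mask area, which
makes whole-ROI FD% exactly the area-weighted mean of the drusen and
drusen-free values.

### Statistics

`compare_groups()` runs Shapiro–Wilk on both samples and reports a Welch
t-test unless either sample rejects normality at α = 0.05, in which case a
two-sided Mann–Whitney U is reported; the gate and its level are recorded
with every result. No multiple-testing correction is applied, matching the
analysis plan this reproduces. `spearman_corr()` uses midranks and
asymptotic two-sided p-values. `power_two_sample()` evaluates the
noncentral-t power of the two-sided two-sample t-test
($\nu = 2n-2$, $\lambda = d\sqrt{n/2}$); it is cross-checked in the tests
against both `stats::power.t.test(strict = TRUE)` and a 200 000-replicate
Monte-Carlo simulation.

## The phantom: what it emulates, and what it does not

`generate_volume()` builds a layered retina on a quadratic Bruch's-membrane
floor: vitreous (intensity 4), RNFL (110, 40 µm), inner layers (55,
140 µm), EZ band (130, 21 µm, positioned exactly in the slab window),
hyporeflective outer-segment gap (35), RPE (150, 25 µm) and choroid (60).
Intensities are arbitrary units chosen to preserve the qualitative OCT
contrast ordering (vitreous ≪ gap < inner < RNFL < EZ < RPE). Multiplicative
gamma speckle with mean 1 and shape 4 (`Inf` disables it) is the standard
first-order surrogate for fully developed OCT speckle. Three design points
deserve explanation:

* **Voxel-snapped boundaries.** The RPE reference is snapped to voxel
  centres before any layer boundary is derived from it, so every
  surface-relative band lands on the same axial quantization grid the slab
  extractors use. Construction and measurement then agree exactly in the
  noiseless case, making "en-face slab mean = planted layer mean" an exact
  oracle rather than an approximate one.
* **Flat-topped drusen.** Drusen are mounds at their peak height over 90 %
  of their radius with a raised-cosine shoulder. With a smooth dome profile
  no single global threshold can recover the half-peak footprint of every
  dome — for concentric disks, Dice ≥ 0.9 forces the radius ratio above
  0.904, i.e. the threshold would have to fall within 42–57 % of *each*
  dome's peak, impossible for peaks spanning 30–100 µm. A steep shoulder
  makes the planted footprint a well-defined object that any mid-range
  threshold recovers, while keeping the peak height analytic.
* **Shadowing as one multiplicative factor.** Sub-RPE signal under drusen,
  and both CC rasters, are attenuated by the same factor (default 0.6;
  0.5 in the compensation experiments), which makes structural compensation
  an exact inverse problem with a known answer.

`generate_cc_pair()` plants elliptical flow-deficit blobs (characteristic
diameter 40 µm by default, jittered ×1–1.6, aspect 0.75–1.33) wholly inside
the grid until the target area fraction is covered; the *achieved* fraction
is recorded in the truth and is the oracle for recovery tests. CC rasters
live on [0, 1] with background flow 0.6, structure 0.65, 5 % residual flow
inside deficits, and gamma noise of shape 50 — chosen so that the
false-deficit floor after the 24 µm cleanup stays in the low percent range,
as for averaged en-face OCTA. The paper trail for these magnitudes does not
exist (acquisition noise is never quantified in the source analyses), so
they are calibration knobs of the phantom, not claims about device physics.

`generate_cohort()` draws per-eye (EZ target, FD fraction) pairs from
group-specific normal distributions through a Gaussian copula with Pearson
parameter $2\sin(\pi\rho_s/6)$ for a target Spearman $\rho_s$ (−0.4 in the
affected group by default, 0 in controls). The EZ target is planted by
inverting the normalization: the EZ attenuation is set to
$a = (x(\mu_{RNFL}-\mu_{vit})+\mu_{vit})/\mu_{EZ,0}$, so the dual-reference
readout recovers $x$ directly. Affected eyes get 3–8 random drusen
(radius 150–300 µm, peak 30–75 µm, ~2–5 % of the ROI — the scale reported
for intermediate AMD) and an extra ×0.93 EZ attenuation under the drusen
footprint, reproducing the observed ordering (drusen < drusen-free <
control). Group defaults (EZ 0.76 ± 0.10 vs 0.85 ± 0.08; FD% 24.1 ± 5.3 vs
19.2 ± 6.2) are representative of reported intermediate-AMD vs control
cohorts at this scan geometry.

**Problem sizes.** Cohort eyes are generated at 96 × 96 × 90 voxels
(62.5 µm lateral, 5 µm axial) so that a full 35 + 35 cohort runs in well
under a minute and a 20-seed recovery experiment stays tractable on one
CPU; recovery experiments that probe the native scan geometry (FD-fraction
recovery) run at the full 500 × 500 / 12 µm grid, and drusen-footprint
recovery at 300 × 300 / 20 µm. The flat-macula check (elevation ≤ 1 µm
everywhere in a drusen-free eye) runs noiseless at 0.5 µm axial sampling:
it verifies the floor-fit and elevation machinery, which no measurement
can do below its own axial quantization step. At the coarse cohort pitch a single pixel
already exceeds the 24 µm cutoff, so the speck filter cannot remove
speckle false-positives; the cohort CC noise shape is therefore raised to
150 to keep the false-deficit floor equivalent to the native geometry. The
deficit blob scale is likewise raised to 130 µm so blobs remain resolvable.

**What passing recovery tests does and does not show.** The phantom shares
with real data the geometry, the contrast ordering, multiplicative
speckle, drusen-shaped RPE elevation with shadowing, and planted effect
structure. It does not model wave optics, beam directionality (a known
confounder of EZ reflectivity), motion or projection artifacts, subretinal
drusenoid deposits, or real CC vascular texture (the deficit-free CC is
speckled background, not a capillary meshwork). Recovery results therefore
validate the *measurement machinery* — thresholds, masks, compensation,
normalization, statistics — not the clinical sensitivity of the readouts.

## Numerical choices and degenerate inputs

* ROI pixels are included iff their centre lies within the radius; the
  circle must fit inside the raster, otherwise the fovea was mis-specified.
* All axial bands are half-open intervals $[z_{top}, z_{bot})$ evaluated at
  voxel centres $z_i = (i-\tfrac12)\,\Delta z$; one shared rule for
  construction and extraction.
* Phansalkar windows and local statistics use exact shift-accumulated
  sums (no FFT), so the brute-force per-pixel oracle agrees bit-for-bit.
* Kapur ties break to the lowest threshold; constant images are rejected
  (no threshold exists), and a constant elevation map inside the ROI is the
  healthy-eye path (empty drusen mask, warning).
* The EZ slab must stay inside the volume on ≥ 99 % of A-scans; reference
  bands must be non-empty; inverted references ($\mu_{RNFL} \le \mu_{vit}$)
  are rejected as invalid scans.
* Missing regions (e.g. a control eye's drusen region, or a region emptied
  by vessel exclusion) propagate as `NA` and are dropped pairwise in the
  statistics with the count recorded.
* Vessel masks are inputs; no vessel segmentation is attempted (none is
  specified by the workflow this reproduces). Eyes analysed here are
  phantom eyes without planted vessels unless a mask is supplied.
* Reference sampling is global (one vitreous mean, one RNFL mean per eye);
  whether the clinical algorithm samples per B-scan is unstated.

## Known limitations

* The RPE segmentation is phantom-grade: sufficient for mounds on a smooth
  floor under gamma speckle, not for real pathology such as RPE atrophy,
  serous detachments or hyperreflective foci.
* MaxEntropy binarization of near-healthy (but not flat) elevation maps is
  unstable by nature; the 20 µm gate in `run_eye()` papers over this for
  phantom controls but is itself a heuristic.
* Printed Spearman p-values in the source cohort are not exactly
  reproducible under standard approximations at n = 35; the package reports
  standard asymptotic two-sided p-values and does not attempt to match
  them.
* FD mean size depends strongly on pixel pitch (components merge at coarse
  grids), so only its direction — larger deficits in affected eyes — is a
  scale-free statement.
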