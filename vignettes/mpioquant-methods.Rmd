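---
title: "Methods: simulating and quantifying MPIO-induced T2* hypointensities"
author: "mpioquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying MPIO-induced T2* hypointensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpioquant)
```

## The problem

Micron-sized particles of iron oxide (MPIO) conjugated to a targeting ligand
(an RGD peptide against integrin αvβ3, or an anti-VCAM-1 antibody) bind to
activated endothelium. Bound iron shortens T2\* locally and each particle
"blooms" into a cluster of dark voxels on T2\*-weighted images, so target
expression can be read out in vivo as focal hypointensities. Two confounds
complicate the readout in brain macrometastases:

* **Endogenous iron.** Larger metastases recruit iron-laden perivascular
  macrophages, which produce hypointense foci *before* any contrast agent is
  given. The quantification must therefore difference post- against
  pre-contrast scans rather than count dark voxels in a single scan.
* **Non-specific uptake.** Peptide-targeted particles can themselves be taken
  up by perivascular macrophages, adding contrast that does not report
  endothelial target expression. Histologically these appear as large
  aggregations of iron inside macrophages near vessels, distinct from the
  single endothelium-bound beads.

The package implements both quantification arms — the MRI voxel statistic and
the histological spatial statistics — together with seed-controlled synthetic
generators that reproduce the statistical structure the analysis assumes, so
every operator can be validated end-to-end against known ground truth.

## MRI signal model

Phantoms are R2\* (= 1/T2\*) maps. Iron deposits are modelled as spheres of
elevated R2\*: a focus with radius $r$ and amplitude $\Delta R_2^*$ adds that
amount to every voxel whose centre lies within $r$ (physical distance, so
anisotropic voxels are handled). No dipole field or phase simulation is
attempted: the downstream statistic consumes magnitude hypointensity only,
for which a local $\Delta R_2^*$ sphere is the minimal sufficient model.
Macrophage foci appear in both scan states; MPIO foci only post-contrast.

Each echo of the multi-gradient-echo (MGE3D) acquisition is evaluated with
the spoiled gradient-echo steady-state equation

$$S(\mathrm{TE}) = \mathrm{PD}\,\sin\alpha\,
  \frac{1 - E_1}{1 - E_1\cos\alpha}\, e^{-\mathrm{TE}\cdot R_2^*},
  \qquad E_1 = e^{-\mathrm{TR}/T_1},$$

with the default protocol TR = 32.55 ms, TE = 2.5, 6.5, …, 22.5 ms
(6 echoes, 4 ms spacing), flip angle 13°, FOV 22.5 mm isotropic. Tissue
defaults are generic high-field brain values (R2\* 25 s⁻¹, T1 1.7 s,
PD 100 a.u.). Magnitude noise is Rician,
$\sqrt{(s + n_1)^2 + n_2^2}$ with $n_i \sim \mathcal N(0, \sigma)$, and SNR
is defined against the noiseless contralateral-striatum mean at the first
echo — the same region the detection threshold is calibrated on, so
simulated SNR and detection share a footing. The in vivo SNR of such scans
is not a published quantity; the default SNR = 40 in `run_config()` is a
free simulation parameter representative of 3D gradient-echo mouse brain
imaging, and the scenario-ordering checks hold over a broad SNR range.

Reconstruction mirrors standard magnitude processing: square-root of
sum-of-squares is a generic axis reducer (`sqrt_sos()`), serving both
receive-channel combination and optional echo combination, because the
combined axis is a free choice for single-coil data. Zero-filling operates
on centred k-space with DC at index `floor(n/2) + 1` and floor-split
padding, which makes `crop_kspace()` an exact inverse; the inverse transform
is normalised by the *acquired* sample count so grid-aligned features keep
their magnitude after interpolation.

## The hypointensity statistic

For each scan the contralateral striatum supplies a mean $\mu$ and SD
$\sigma$ (sample definition, $n-1$; the convention is documented because
either choice is defensible and the difference is negligible at ROI sizes
of hundreds of voxels). A voxel is hypointense when its value is *more than*
$k\sigma$ below $\mu$, i.e. strictly $v < \mu - k\sigma$ with $k = 3$ by
default. Counting is voxelwise, with no cluster filtering. Each scan is
thresholded against its own contralateral statistics; the MPIO-induced count
is

$$\Delta = N_\text{post} - N_\text{pre}, \qquad
  \Delta_\text{clipped} = \max(\Delta, 0),$$

per hemisphere. A negative $\Delta$ means the technique's noise floor, not
particle removal, so it is reported as zero; raw differences from
non-binding control cohorts feed `noise_floor()`, which summarises the
detection limit as mean ± SD and as a fraction of the contralateral ROI.
The default analysis volume is the last echo (TE = 22.5 ms), where T2\*
contrast is strongest; this is configurable (`echo`, `combine`) because the
choice of analysis echo is not standardised.

Two exact properties pin the implementation down and are enforced in the
test suite: flagged sets are invariant under affine intensity maps
$x \mapsto ax + b$, $a > 0$, applied to volume and reference alike; and on
noiseless phantoms the pipeline count equals a brute-force per-voxel oracle
exactly, because with $\sigma = 0$ the threshold degenerates to $\mu$ and
the strict inequality decides every voxel deterministically.

## Scenario presets

`scenario_presets()` encodes the targeting conditions as MPIO focus counts
in the ipsilateral striatum: VCAM 120, RGD 40, RDG/IgG 0, and PBS 0 with no
macrophage foci either. The counts are study conditions of the simulation,
fixed in advance: only the qualitative ordering (antibody ≫ peptide ≫
non-binding controls ≈ noise floor) is empirically grounded, and that
ordering — not the absolute counts — is what the cohort-level acceptance
check asserts, over 20 simulated animals per preset at matched SNR and
seeds. Tumour-bearing presets carry 8 macrophage foci (ΔR2\* 300 s⁻¹,
radius 0.5 mm) in both scan states, which reproduces the pre-existing
hypointensity phenomenon: controls end near zero *because* their endogenous
dark voxels cancel in the difference, not because they lack dark voxels.

## Histology generator and quantification

Scenes live in a 1000 × 1000 µm field (0.5 µm/px by default). Vessel lumen
centres are uniform with ≥ 80 µm spacing; each macrophage draws a
centre-to-lumen distance from a lognormal with median 10 µm and
$\sigma_{\log} = \log(2.5)/z_{0.9} = 0.715$, the two-parameter family fixed
by the two published quantiles (median 10 µm, 90th percentile 25 µm) and
positive support. Placement keeps the assigned vessel the *nearest* lumen
centre, so realised nearest-centre distances follow the model by
construction; macrophages are placed smallest-distance-first so the crowded
near-lumen ring fills before outer shells (the draw multiset, and hence the
distribution, is unaffected by ordering). Draws are truncated at 60 µm —
beyond roughly the inter-vessel spacing a "nearest-vessel" distance is
geometrically unrealisable — removing ~0.6% of the upper tail and moving
the median by < 1% and the within-25 µm mass from 0.900 to ≈ 0.905.
A minimum 5 µm centre separation between iron objects (areas 5–15 µm²,
i.e. radii ≤ 2.2 µm) keeps rendered blobs disjoint by more than one pixel,
so segmentation is count-preserving by construction.

Rendering emulates Perls' Prussian blue with nuclear fast red and a
DAB-brown vessel stain: pink background, brown vessel-wall annuli, blue
iron discs (macrophage disc area = iron area; beads 1 µm). Segmentation
classifies a pixel as iron when blue dominates, $B - \max(R, G) > 0.12$
(on [0, 1]; configurable), labels 4-connected components, and classifies
blobs by area: `aggregation` when ≥ 2× the single-bead area π/4 µm²
(the smallest area inconsistent with one bead; ties go to `aggregation`),
else `single_mpio`. Distances are 2D centre-to-centre against lumen
centres — the lumen radius is not subtracted, matching how the published
distances were measured — with a 5 µm cumulative histogram bin width.
`positive_pixel_fraction()` applies the published intensity windows
verbatim (moderate [185, 202], strong < 10 on 0–255) to the luma
0.299R + 0.587G + 0.114B; the original slide-scanner algorithm's
hue/saturation logic is proprietary and only its intensity windows are
public.

## What the generators do and do not emulate

The synthetic data reproduce the *statistical* structure the analysis
assumes: focal signal dropout on a homogeneous background, per-scan
threshold calibration, endogenous foci present in both scans, Rician noise,
and a calibrated perivascular distance law with disjoint, colour-separable
histology objects. They do not emulate anatomy (striatum surrogates are
mirrored spheres), partial-volume decay at focus edges, field
inhomogeneity, motion, stain variability, overlapping or out-of-focus
blobs, or annotation ambiguity in locating lumen centres (the synthetic
pipeline uses centroids). Passing tests therefore certify the *operators* —
thresholding, differencing, segmentation, distance statistics — not
robustness to real-slide or real-scanner artefacts.

## Numerical choices and problem sizes

Desk-scale defaults keep every check cheap: phantoms 64³ (the
acquisition-faithful 256 × 192 × 192 grid is available via
`acq_params()$matrix_size`), cohorts of 20 subjects per preset for ordering
checks, and 500-macrophage scenes for distance recovery (3 seeds in the
test suite; 20 seeds, 10 000 distances, in `scripts/acceptance.R`). Under
those conditions the image-derived median lands in [9, 11] µm and the
within-25 µm fraction in [0.86, 0.94] seed-to-seed, consistent with the
calibration targets of 10 µm and 0.90. All generators are pure functions
of their arguments and a seed; per-subject and per-scan seeds are derived
deterministically from the cohort seed. Degenerate inputs fail loudly:
empty ROIs, overlapping hemisphere masks, mismatched grids, fields too
small for the requested geometry, and zero endothelial areas are errors,
not warnings.

## Known limitations

* The ΔR2\*-sphere model has no TE-dependent blooming radius; a focus
  covers the same voxels at every echo, whereas real blooming grows with
  TE. Echo choice therefore changes sensitivity only through noise, not
  through lesion size.
* Absolute simulated voxel counts are not comparable to in vivo counts;
  only within-simulation contrasts (scenario ordering, noise-floor
  behaviour) are meaningful.
* The blue/brown/pink colour classes are linearly separable by
  construction; real stains require deconvolution, which is out of scope.
* The positive-pixel implementation reproduces published intensity
  windows, not the proprietary hue/saturation preclassification, so
  absolute area fractions on real slides may differ from the original
  software's output.
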