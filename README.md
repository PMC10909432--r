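# mpioquant

Simulation and quantification of molecular MRI with micron-sized particles
of iron oxide (MPIO) in brain metastases, and of the matching ex vivo iron
histology.

MPIO conjugated to a targeting ligand (RGD peptide against integrin αvβ3,
or anti-VCAM-1 antibody) bind activated endothelium and each bound particle
"blooms" into a focal cluster of dark voxels on T2\*-weighted images. Two
confounds complicate reading target expression off a single scan: larger
metastases harbour endogenous iron-laden perivascular macrophages that are
dark *before* contrast, and peptide-targeted particles can be taken up
non-specifically by those same macrophages. The package implements the
quantification designed around these confounds, plus seed-controlled
synthetic generators so every operator can be validated against known
ground truth. It is aimed at preclinical imaging groups who want the voxel
statistic and the histology spatial statistics as tested, reusable code.

## The statistics at the core

**MRI.** Each echo follows the spoiled gradient-echo signal
S(TE) = PD · sinα · (1 − E₁)/(1 − E₁cosα) · exp(−TE·R2\*), E₁ = exp(−TR/T1),
with Rician magnitude noise (defaults: TR = 32.55 ms, TE = 2.5…22.5 ms in
6 echoes, α = 13°). On the analysis volume (last echo by default), a voxel
is **hypointense** when it lies more than k = 3 standard deviations below
the contralateral-striatum mean (strict `v < μ − 3σ`, each scan calibrated
against its own contralateral ROI). The MPIO-induced count is the
post-minus-pre difference per hemisphere, clipped at zero:
Δ_clipped = max(N_post − N_pre, 0). Raw control-cohort differences define
the technique's noise floor (`noise_floor()`).

**Histology.** Rendered (or real) Prussian-blue micrographs are segmented
by blue dominance into iron blobs; blobs ≥ 2× the single-bead area
(π/4 µm² for 1 µm MPIO) are `aggregation` (intracellular iron), smaller
ones `single_mpio` (endothelium-bound beads). Macrophage-to-vessel
proximity is the 2D centre-to-lumen-centre nearest distance, summarised as
the median, the fraction within 25 µm, and a cumulative histogram; the
synthetic scenes draw these distances from a lognormal calibrated to a
10 µm median and 90% within 25 µm. Positive-pixel staining fractions use
the published intensity windows (moderate [185, 202], strong < 10 on
0–255 luma).

## Worked example

Simulate a small RGD-targeted cohort and quantify it:

```r
library(mpioquant)
cfg <- run_config("RGD", n_subjects = 3, seed = 42, snr = 40)
rep <- run_pipeline(cfg)
rep$table
#>       id scenario hemisphere n_hypo_pre n_hypo_post diff_raw diff_clipped
#> 1 RGD_01      RGD       ipsi        116         151       35           35
#> 2 RGD_01      RGD     contra          3           3        0            0
#> 3 RGD_02      RGD       ipsi        133         169       36           36
#> 4 RGD_02      RGD     contra          0           2        2            2
#> 5 RGD_03      RGD       ipsi        144         179       35           35
#> 6 RGD_03      RGD     contra          3           4        1            1
```

Each simulated animal already has ~120–140 hypointense voxels in the
tumour-bearing (ipsi) striatum *before* contrast — the endogenous
iron-laden macrophages — which is exactly why the statistic is a post−pre
difference: the MPIO-induced signal is the ~35-voxel increment, while the
contralateral hemisphere sits at the noise floor (0–2 voxels). Swapping
`"RGD"` for `"RDG"` or `"IgG"` (non-binding controls) drives the ipsi
difference to the noise floor too; `"VCAM"` raises it several-fold.

Histology, end to end from scene to measured distance statistics:

```r
sc <- generate_histo_scene(n_vessels = 40, n_macrophages = 500, seed = 42)
blobs <- segment_iron(render_histo(sc))
agg <- blobs[blobs$class == "aggregation", c("x_um", "y_um")]
vessel_distance_stats(agg, sc$vessels[, c("x", "y")])
#> distance_stats: n = 500, median 9.53 um, 91.0% within 25 um
```

All 500 macrophages are recovered as aggregation-class blobs and the
measured centre-to-lumen distances reproduce the calibration: median
≈ 10 µm, ≈ 90% within 25 µm — perivascular macrophages.

See `vignettes/mpioquant-methods.Rmd` for the model assumptions, generator
design and numerical choices.

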