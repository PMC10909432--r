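Package: mpioquant
Title: Quantification of Iron-Oxide Microparticle Contrast in Brain MRI
    and Perivascular Iron Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and quantification pipeline for molecular MRI of
    brain metastases with micron-sized particles of iron oxide (MPIO).
    Provides seed-controlled generators for multi-gradient-echo T2*-weighted
    phantom acquisitions (spoiled gradient-echo signal model, Rician
    magnitude noise) and for two-dimensional histology scenes of vessels,
    iron-laden perivascular macrophages and single MPIO; square-root of
    sum-of-squares reconstruction with centred k-space zero-filling; the
    contralateral-ROI mean minus three standard deviations hypointense-voxel
    statistic with post-minus-pre differencing and zero-clipping; and
    histology quantification (blue-stain blob segmentation, single-MPIO
    versus iron-aggregation classification, macrophage-to-vessel-lumen
    distance statistics, endothelium-normalised MPIO density, and
    positive-pixel-count staining area fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    png,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
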