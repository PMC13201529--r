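Package: zapcest
Title: Combined CEST and Z-Spectrum Analysis Protons (ZAP) Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for wide-range Z-spectrum magnetization-transfer MRI:
    construction of centric saturation-offset schedules, a two-pool
    Lorentzian forward model with embedded chemical exchange saturation
    transfer (CEST) peaks, digital brain phantom and cohort simulation with
    Rician noise, per-ROI B0 correction, voxel-wise constrained
    three-parameter two-Lorentzian (ZAP) fitting of the free and restricted
    exchange-proton pools, Lorentzian-difference CEST quantification at the
    hydroxyl, amine and amide sites, and region-wise aging statistics
    (Spearman correlations with Fisher-z confidence intervals and
    normality-gated two-group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
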