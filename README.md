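# zapcest

Combined CEST / Z-spectrum analysis protons (ZAP) pipeline for wide-range
magnetization-transfer MRI of the brain, with a synthetic phantom and
cohort generator so every stage is testable without scanner data.

## The problem

Chemical exchange saturation transfer (CEST) MRI detects labile protons —
hydroxyl (~1.0 ppm), amine (~2.0 ppm), amide (~3.5 ppm) downfield of
water — through exchange-mediated water signal loss, but the conventional
asymmetry metric carries only a few percent of contrast. Sampling the
*entire* Z-spectrum out to ±800 ppm instead supports a two-pool Lorentzian
decomposition with just three free parameters,

    Z(Δf) = 1 − F_f·L(Δf; T2,f) − (1 − F_f)·L(Δf; T2,r) − Σ_k A_k·L_k(Δf),
    L(Δf; T2) = 1 / (1 + (2π·Δf·T2)²),

yielding the fraction `F_f` of relatively free exchangeable water protons
(`F_r = 1 − F_f`), the apparent relaxation times `T2,f` (free pool,
~0.6–2.3 ms) and `T2,r` (restricted pool, ~25–100 µs), plus the narrow
CEST dips `A_k` hiding under the spectrum. These metrics shift with brain
aging (free-water fraction rises; free-pool T2 lengthens), which is the
kind of region-wise cohort analysis the package automates end to end:

1. **schedule** — the 56-offset centric sampling table (dense 150 Hz CEST
   band, sparse ±100 kHz wings), ppm↔Hz conversion, timing;
2. **forward model** — two-pool spectra with embedded CEST peaks,
   MTR asymmetry;
3. **synthetic data** — digital three-tissue phantoms, Rician-noise 4D
   acquisitions, and aging cohorts with realistic region trends;
4. **B0 correction** — per-ROI water-line recentering from the CEST
   acquisition itself;
5. **ZAP fit** — constrained voxel-wise Levenberg–Marquardt fitting of
   `(F_f, T2,f, T2,r)` to parametric maps;
6. **CEST extraction** — Lorentzian-difference residual peaks with
   noise-calibrated detection, or a joint baseline+shift+peaks solve
   (`analyze_spectrum()`);
7. **statistics** — Spearman correlations with Fisher-z CIs,
   normality-gated t / Mann-Whitney group comparisons, report tables.

It is aimed at quantitative-MRI researchers prototyping ZAP/CEST analyses
or validating estimation machinery against known ground truth.

## Worked example

```r
library(zapcest)

sched <- build_offset_table()    # the 56-offset table
sched
#> Saturation-offset schedule: 56 offsets, 27 positive / 28 negative
#>   range -131950 .. +101950 Hz (-1033.1 .. 798.2 ppm) at 127.728 Hz/ppm
#>   TR 1500 ms -> 84.0 s per slice

# a gray-matter-like spectrum with a hydroxyl dip and a -25 Hz B0 shift
zs <- synth_zspectrum(two_pool_params(0.64, 1000, 38), sched,
                      list(cest_peak("hydroxyl", 0.06)), b0_shift_hz = -25)
ana <- analyze_spectrum(zs)      # joint shift + baseline + peaks
ana$fit
#> two-pool params: F_f = 0.6400 (F_r = 0.3600), T2f = 1000.0 us, T2r = 38.00 us
#>   SSR 6.654e-21, converged in 8 iterations
ana$peaks
#>       site nominal_ppm detected amplitude fitted_offset_ppm
#> 1 hydroxyl         1.0     TRUE      0.06                 1
#> 2    amine         2.0    FALSE      0.00                NA
#> 3    amide         3.5    FALSE      0.00                NA
```

The fit recovers the generating parameters exactly (SSR ~1e-21), the
hydroxyl amplitude reads 0.06 as injected, and the B0 estimate
(`ana$b0$shift_hz`) returns −25 Hz. On a simulated aging cohort the
white-matter free-pool fraction correlates with age:

```r
co <- simulate_cohort(cohort_spec(seed = 1))
wm <- subset(co, region == "wm" & metric == "f_f_pct")
spearman_ci(wm$age, wm$value)
#> Spearman rho = 0.658 (95% CI 0.445 to 0.800), p = 1.654e-06, n = 43
group_compare(wm$value, wm$group)
#> mann-whitney test: p = 2.996e-07 *
#>   older: 60.35 (60.02-61.18)
#>   younger: 58.53 (58.26-59.81)
```

`rho` is the rank correlation of the metric with age across the 43
simulated subjects (positive: F_f rises with age), and the group
comparison contrasts subjects under vs at-least 65 years with the
median (IQR) convention its normality gate selected. The full chain —
simulate, correct, fit, extract, report, with all artifacts on disk —
is one call:

```r
res <- run_pipeline(list(phantom = list(shape = c(16, 16, 1)), seed = 1),
                    out_dir = "run")
```

or from a shell, `Rscript inst/scripts/zapcest.R --seed 1 --out run/`.

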