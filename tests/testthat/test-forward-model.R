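test_that("lorentzian has unit peak, the stated FWHM, and rejects bad T2", {
  expect_equal(lorentzian(0, 50), 1)
  expect_equal(lorentzian(0, 5000), 1)
  # half maximum at 1/(2 pi T2)
  expect_equal(lorentzian(1 / (2 * pi * 1000e-6), 1000), 0.5)
  # FWHM = 1/(pi T2): 30 us -> 10610.3 Hz
  fwhm <- 1 / (pi * 30e-6)
  expect_equal(fwhm, 10610.33, tolerance = 1e-6)
  expect_equal(lorentzian(fwhm / 2, 30), 0.5)
  expect_error(lorentzian(100, 0), "positive")
  expect_error(lorentzian(100, -5), "positive")
})

test_that("two_pool_params enforces fraction and pool-identity invariants", {
  p <- two_pool_params(0.6, 800, 30)
  expect_equal(1 - p$f_f, 0.4)
  expect_error(two_pool_params(0, 800, 30), "f_f")
  expect_error(two_pool_params(1, 800, 30), "f_f")
  expect_error(two_pool_params(0.5, 30, 800), "t2f_us > t2r_us")
  expect_error(two_pool_params(0.5, 800, -1), "positive")
})

test_that("two-pool spectrum saturates fully at water and recovers in wings", {
  zs <- synth_zspectrum(two_pool_params(0.6, 800, 30), sched56)
  expect_equal(zs$z[zs$offsets_hz == 0], 0)
  expect_gt(min(zs$z[abs(zs$offsets_hz) >= 9e4]), 0.99)
  # closed-form value at 5000 Hz
  expected <- 1 - 0.6 / (1 + (2 * pi * 5000 * 800e-6)^2) -
    0.4 / (1 + (2 * pi * 5000 * 30e-6)^2)
  expect_equal(zs$z[zs$offsets_hz == 5950],
               1 - 0.6 / (1 + (2 * pi * 5950 * 800e-6)^2) -
                 0.4 / (1 + (2 * pi * 5950 * 30e-6)^2))
  expect_equal(synth_zspectrum(two_pool_params(0.6, 800, 30),
                               c(-5000, 0, 5000))$z[3], expected)
})

test_that("peak-free spectra are symmetric, bounded, monotone in |offset|", {
  for (p in list(gm_params, wm_params, csf_params)) {
    zs <- synth_zspectrum(p, sched56)
    expect_true(all(zs$z >= 0 & zs$z <= 1))
    pos <- zs$z[zs$offsets_hz > 0]
    neg <- rev(zs$z[zs$offsets_hz < 0])
    n <- min(length(pos), length(neg))
    expect_equal(pos[seq_len(n)], neg[seq_len(n)])   # exact symmetry
    expect_true(all(diff(pos) > 0))                   # monotone outward
  }
})

test_that("adding a CEST peak only lowers the spectrum", {
  base <- synth_zspectrum(gm_params, sched56)
  with_pk <- suppressWarnings(
    synth_zspectrum(gm_params, sched56, list(cest_peak("amide", 0.05))))
  expect_true(all(with_pk$z <= base$z + 1e-12))
  expect_lt(with_pk$z[with_pk$offsets_hz == 450],
            base$z[base$offsets_hz == 450])
})

test_that("mtr_asym vanishes on symmetric spectra and sees downfield dips", {
  base <- synth_zspectrum(gm_params, sched56)
  expect_equal(mtr_asym(base, c(1, 2, 3.5, 6)), rep(0, 4))
  # narrow dip at +3.5 ppm: asymmetry there is about its amplitude
  pk <- suppressWarnings(synth_zspectrum(
    gm_params, sched56, list(cest_peak("amide", 0.05, width_ppm = 0.3))))
  expect_equal(mtr_asym(pk, 3.52), 0.05 * 1 / (1 + (2 * 0.02 / 0.3)^2),
               tolerance = 0.05)
  expect_error(mtr_asym(base, 2000), "beyond")
})

test_that("typical cortical spectra give the conventional 2-4% asymmetry", {
  pk <- list(cest_peak("hydroxyl", 0.065), cest_peak("amine", 0.04))
  zs <- suppressWarnings(synth_zspectrum(gm_params, sched56, pk))
  asym <- mtr_asym(zs, c(1.17, 2.35))
  # peak asymmetry sits in the conventional few-percent range; the amine
  # sample lies 0.35 ppm off-apex and reads lower
  expect_gt(asym[1], 0.02); expect_lt(asym[1], 0.05)
  expect_gt(asym[2], 0.01); expect_lt(asym[2], 0.05)
})
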