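test_that("phantoms are deterministic and respect their region spec", {
  spec <- phantom_spec(shape = c(24, 24, 2), seed = 7)
  p1 <- make_phantom(spec)
  p2 <- make_phantom(spec)
  expect_identical(p1, p2)

  masks <- phantom_masks(p1)
  expect_named(masks, c("wm", "gm", "csf"))
  # masks disjoint and cover all labelled voxels
  expect_equal(sum(masks$wm & masks$gm), 0)
  expect_equal(sum(masks$gm & masks$csf), 0)
  # admissible parameters everywhere in-mask
  inm <- p1$labels > 0
  expect_true(all(p1$f_f[inm] > 0 & p1$f_f[inm] < 1))
  expect_true(all(p1$t2f_us[inm] > p1$t2r_us[inm]))
  # free-pool fraction ordering CSF > GM > WM
  means <- vapply(masks, function(m) mean(p1$f_f[m]), numeric(1))
  expect_true(means[["csf"]] > means[["gm"]])
  expect_true(means[["gm"]] > means[["wm"]])
})

test_that("zero-variance single-region phantom gives constant maps", {
  regions <- list(list(
    label = "uniform", r_band = c(0, 0.9),
    params_mean = c(f_f = 0.6, t2f_us = 900, t2r_us = 35),
    params_sd = c(f_f = 0, t2f_us = 0, t2r_us = 0),
    peaks_mean = c(hydroxyl = 0.05, amine = 0, amide = 0),
    peaks_sd = c(hydroxyl = 0, amine = 0, amide = 0)))
  ph <- make_phantom(phantom_spec(shape = c(10, 10, 1), regions = regions,
                                  seed = 3))
  inm <- ph$labels > 0
  expect_equal(unique(ph$f_f[inm]), 0.6)
  expect_equal(unique(ph$t2f_us[inm]), 900)
  expect_equal(unique(ph$peak_hydroxyl[inm]), 0.05)
  expect_error(
    phantom_spec(regions = list(regions[[1]],
                                modifyList(regions[[1]],
                                           list(label = "b",
                                                r_band = c(0.5, 1))))),
    "overlap")
})

test_that("noiseless acquisition equals the forward model exactly", {
  regions <- list(list(
    label = "uniform", r_band = c(0, 0.9),
    params_mean = c(f_f = 0.62, t2f_us = 850, t2r_us = 33),
    params_sd = c(f_f = 0, t2f_us = 0, t2r_us = 0),
    peaks_mean = c(hydroxyl = 0.04, amine = 0, amide = 0),
    peaks_sd = c(hydroxyl = 0, amine = 0, amide = 0)))
  ph <- make_phantom(phantom_spec(shape = c(6, 6, 1), regions = regions,
                                  b0_sd_hz = 0, seed = 2))
  st <- simulate_acquisition(ph, sched56, noise_sigma = 0)
  v <- which(ph$labels > 0)[1]
  nvol <- prod(dim(ph$labels))
  got <- st[v + nvol * (seq_len(56) - 1)]
  ref <- suppressWarnings(
    synth_zspectrum(two_pool_params(0.62, 850, 33), sched56,
                    list(cest_peak("hydroxyl", 0.04))))
  expect_equal(got, ref$z)
  # background voxels stay at the (zero) noise floor
  expect_equal(max(abs(st[ph$labels == 0])), 0)
})

test_that("Rician noise matches the analytic Rician mean", {
  # 10^4 replicate voxels of a single parameter set at sigma = 0.01
  regions <- list(list(
    label = "uniform", r_band = c(0, 2),   # covers the full grid
    params_mean = c(f_f = 0.6, t2f_us = 900, t2r_us = 35),
    params_sd = c(f_f = 0, t2f_us = 0, t2r_us = 0),
    peaks_mean = c(hydroxyl = 0, amine = 0, amide = 0),
    peaks_sd = c(hydroxyl = 0, amine = 0, amide = 0)))
  ph <- make_phantom(phantom_spec(shape = c(100, 100, 1), regions = regions,
                                  b0_sd_hz = 0, seed = 4))
  sigma <- 0.01
  st <- simulate_acquisition(ph, sched56, noise_sigma = sigma, seed = 11)
  nvol <- 100 * 100
  truth <- synth_zspectrum(two_pool_params(0.6, 900, 35), sched56)$z
  for (j in c(1, 28, 56)) {
    vals <- st[seq_len(nvol) + nvol * (j - 1)]
    mu <- rician_mean(truth[j], sigma)
    se <- sd(vals) / sqrt(nvol)
    expect_lt(abs(mean(vals) - mu), 3 * se + 1e-6)
  }
})

test_that("an injected B0 shift displaces the spectrum minimum", {
  regions <- list(list(
    label = "uniform", r_band = c(0, 0.9),
    params_mean = c(f_f = 0.6, t2f_us = 900, t2r_us = 35),
    params_sd = c(f_f = 0, t2f_us = 0, t2r_us = 0),
    peaks_mean = c(hydroxyl = 0, amine = 0, amide = 0),
    peaks_sd = c(hydroxyl = 0, amine = 0, amide = 0)))
  ph <- make_phantom(phantom_spec(shape = c(6, 6, 1), regions = regions,
                                  b0_sd_hz = 0, seed = 2))
  ph$b0_hz[] <- 150
  st <- simulate_acquisition(ph, sched56, noise_sigma = 0)
  v <- which(ph$labels > 0)[1]
  nvol <- prod(dim(ph$labels))
  zs <- zspectrum(sched56$offsets_hz, st[v + nvol * (seq_len(56) - 1)])
  sf <- splinefun(zs$offsets_hz[abs(zs$offsets_hz) <= 1650],
                  zs$z[abs(zs$offsets_hz) <= 1650], method = "natural")
  argmin <- optimize(sf, c(-650, 650))$minimum
  expect_equal(argmin, 150, tolerance = 0.05)
})

test_that("cohort simulation is deterministic, with the stated strata", {
  spec <- cohort_spec(seed = 9)
  co1 <- simulate_cohort(spec)
  co2 <- simulate_cohort(spec)
  expect_identical(co1, co2)
  subj <- unique(co1[, c("subject_id", "age", "group")])
  expect_equal(nrow(subj), 43)
  expect_equal(sum(subj$group == "younger"), 13)
  expect_equal(sum(subj$group == "older"), 30)
  expect_true(all(subj$age >= 23 & subj$age <= 86))
  expect_true(all((subj$age >= 65) == (subj$group == "older")))
  # one value per subject/region/metric
  expect_equal(nrow(co1), 43 * 9 * 3)
})

test_that("zero slopes remove the age trend; default slopes restore it", {
  eff0 <- default_age_effects()
  eff0$slope <- 0
  co0 <- simulate_cohort(cohort_spec(age_effects = eff0, seed = 21))
  wm0 <- co0[co0$region == "wm" & co0$metric == "f_f_pct", ]
  expect_lt(abs(spearman_ci(wm0$age, wm0$value)$rho), 0.3)

  co <- simulate_cohort(cohort_spec(seed = 21))
  wm <- co[co$region == "wm" & co$metric == "f_f_pct", ]
  expect_gt(spearman_ci(wm$age, wm$value)$rho, 0)
  # older group exceeds younger in every region's free-pool fraction
  ff <- co[co$metric == "f_f_pct", ]
  gaps <- tapply(ff$value, list(ff$region, ff$group), mean)
  expect_true(all(gaps[, "older"] > gaps[, "younger"]))
})

test_that("subject phantoms inherit the subject's tissue values", {
  co <- simulate_cohort(cohort_spec(seed = 3))
  ph <- subject_phantom(co, "S001", shape = c(16, 16, 1))
  masks <- phantom_masks(ph)
  want <- co$value[co$subject_id == "S001" & co$region == "wm" &
                     co$metric == "f_f_pct"] / 100
  expect_equal(mean(ph$f_f[masks$wm]), want, tolerance = 0.02)
  expect_error(subject_phantom(co, "nope"), "unknown")
})
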