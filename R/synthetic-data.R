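#' Default tissue regions of the digital phantom
#'
#' Three concentric tissue classes on an elliptical head-like layout: white
#' matter (outer annulus), cortical gray matter (middle annulus) and CSF
#' (central ventricle-like core). Two-pool means follow typical in-vivo
#' values: free-pool fractions ordered CSF > GM > WM (about 0.68 / 0.64 /
#' 0.59), free-pool T2 about 2100 / 1000 / 760 us and restricted-pool T2 in
#' the tens of microseconds. Hydroxyl peaks are present in all classes
#' (largest in CSF), amine peaks are small and sparse, amide absent by
#' default.
#'
#' @return A list of region specs, each with `label`, radial band `r_band`,
#'   `params_mean` / `params_sd` (f_f, t2f_us, t2r_us) and `peaks_mean` /
#'   `peaks_sd` (hydroxyl, amine, amide amplitudes in Z-units).
#' @export
default_phantom_regions <- function() {
  list(
    list(label = "wm", r_band = c(0.50, 0.90),
         params_mean = c(f_f = 0.59, t2f_us = 760, t2r_us = 30),
         params_sd   = c(f_f = 0.012, t2f_us = 45, t2r_us = 2.2),
         peaks_mean = c(hydroxyl = 0.045, amine = 0.005, amide = 0),
         peaks_sd   = c(hydroxyl = 0.012, amine = 0.004, amide = 0)),
    list(label = "gm", r_band = c(0.25, 0.50),
         params_mean = c(f_f = 0.64, t2f_us = 1000, t2r_us = 38),
         params_sd   = c(f_f = 0.011, t2f_us = 100, t2r_us = 4),
         peaks_mean = c(hydroxyl = 0.065, amine = 0.004, amide = 0),
         peaks_sd   = c(hydroxyl = 0.015, amine = 0.004, amide = 0)),
    list(label = "csf", r_band = c(0.00, 0.25),
         params_mean = c(f_f = 0.68, t2f_us = 2100, t2r_us = 95),
         params_sd   = c(f_f = 0.017, t2f_us = 300, t2r_us = 25),
         peaks_mean = c(hydroxyl = 0.16, amine = 0.01, amide = 0),
         peaks_sd   = c(hydroxyl = 0.03, amine = 0.008, amide = 0))
  )
}

#' Specification of a digital phantom
#'
#' @param shape 3D grid dimensions; the default 64 x 64 x 3 mirrors a
#'   three-slice axial acquisition at desk scale.
#' @param regions Region list as returned by [default_phantom_regions()];
#'   labels must be unique and radial bands disjoint.
#' @param b0_sd_hz Standard deviation of the phantom-level B0 offset (Hz); a
#'   smooth in-plane linear gradient of the same scale is superimposed.
#' @param noise_sigma Rician noise scale relative to S0 used by
#'   [simulate_acquisition()] unless overridden.
#' @param seed Integer seed; every stochastic draw is derived from it.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 3),
                         regions = default_phantom_regions(),
                         b0_sd_hz = 25, noise_sigma = 0.005, seed = 1) {
  labels <- vapply(regions, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("region labels must be unique")
  bands <- t(vapply(regions, `[[`, numeric(2), "r_band"))
  o <- order(bands[, 1])
  if (any(bands[o, 1][-1] < bands[o, 2][-nrow(bands)] - 1e-12))
    stop("region radial bands overlap; masks must be disjoint")
  stopifnot(noise_sigma >= 0, length(shape) == 3L)
  structure(list(shape = as.integer(shape), regions = regions,
                 b0_sd_hz = b0_sd_hz, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Truncated-normal draw by resampling out-of-range values.
.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Build a digital phantom
#'
#' Lays the regions out as concentric elliptical annuli, draws per-voxel
#' two-pool parameters and CEST peak amplitudes from truncated Gaussians
#' around the region means, and draws a smooth B0 field (constant offset
#' plus in-plane linear gradient). Fully deterministic given the spec seed.
#'
#' @param spec A `phantom_spec`.
#' @return A list of class `zap_phantom`: integer `labels` array (0 =
#'   background), `region_names`, parameter maps `f_f`, `t2f_us`, `t2r_us`,
#'   peak-amplitude maps `peak_hydroxyl`, `peak_amine`, `peak_amide`, the
#'   `b0_hz` map, and the `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  xg <- (seq_len(d[1]) - cx) / (d[1] / 2)
  yg <- (seq_len(d[2]) - cy) / (d[2] / 2)
  r2d <- sqrt(outer(xg^2, yg^2, `+`))
  labels <- array(0L, d)
  for (k in seq_len(d[3]))
    for (i in seq_along(spec$regions)) {
      b <- spec$regions[[i]]$r_band
      labels[, , k][r2d > b[1] & r2d <= b[2]] <- i
    }
  # central core: include r == 0 band start
  for (i in seq_along(spec$regions))
    if (spec$regions[[i]]$r_band[1] == 0)
      for (k in seq_len(d[3])) labels[, , k][r2d == 0] <- i

  mk <- function() array(NA_real_, d)
  maps <- list(f_f = mk(), t2f_us = mk(), t2r_us = mk(),
               peak_hydroxyl = mk(), peak_amine = mk(), peak_amide = mk())
  for (i in seq_along(spec$regions)) {
    reg <- spec$regions[[i]]
    idx <- which(labels == i)
    n <- length(idx)
    if (!n) next
    pm <- reg$params_mean; ps <- reg$params_sd
    maps$f_f[idx] <- .rnorm_trunc(n, pm[["f_f"]], ps[["f_f"]], 0.02, 0.98)
    maps$t2f_us[idx] <- .rnorm_trunc(n, pm[["t2f_us"]], ps[["t2f_us"]],
                                     120, 9500)
    maps$t2r_us[idx] <- .rnorm_trunc(n, pm[["t2r_us"]], ps[["t2r_us"]],
                                     6, 480)
    for (s in c("hydroxyl", "amine", "amide")) {
      mu <- reg$peaks_mean[[s]]; sd <- reg$peaks_sd[[s]]
      amp <- if (sd > 0) pmax(stats::rnorm(n, mu, sd), 0) else rep(mu, n)
      maps[[paste0("peak_", s)]][idx] <- amp
    }
  }
  b0 <- stats::rnorm(1, 0, spec$b0_sd_hz)
  gx <- stats::rnorm(1, 0, spec$b0_sd_hz / 2)
  gy <- stats::rnorm(1, 0, spec$b0_sd_hz / 2)
  b0_hz <- array(rep(b0 + outer(xg * gx, yg * gy, `+`), d[3]), d)
  structure(c(list(labels = labels,
                   region_names = vapply(spec$regions, `[[`, character(1),
                                         "label"),
                   b0_hz = b0_hz, spec = spec), maps),
            class = "zap_phantom")
}

#' Region masks of a phantom
#' @param phantom A `zap_phantom`.
#' @return Named list of logical 3D arrays, one per region.
#' @export
phantom_masks <- function(phantom) {
  stats::setNames(
    lapply(seq_along(phantom$region_names),
           function(i) phantom$labels == i),
    phantom$region_names)
}

#' Simulate a 4D Z-spectrum acquisition of a phantom
#'
#' Evaluates the two-pool forward model with each voxel's parameters, peaks
#' and B0 shift at every schedule offset, then adds Rician noise (the
#' magnitude of the noiseless signal plus complex Gaussian noise), the noise
#' distribution of magnitude MRI. Background voxels carry the pure noise
#' floor.
#'
#' @param phantom A `zap_phantom`.
#' @param schedule An `offset_schedule`.
#' @param noise_sigma Rician scale relative to S0; defaults to the phantom
#'   spec value.
#' @param seed Noise seed; defaults to `spec$seed + 1`.
#' @return A 4D array `[x, y, z, offset]` with attribute `"schedule"`.
#' @export
simulate_acquisition <- function(phantom, schedule,
                                 noise_sigma = NULL, seed = NULL) {
  stopifnot(inherits(phantom, "zap_phantom"),
            inherits(schedule, "offset_schedule"))
  if (is.null(noise_sigma)) noise_sigma <- phantom$spec$noise_sigma
  if (is.null(seed)) seed <- phantom$spec$seed + 1L
  d <- dim(phantom$labels)
  off <- schedule$offsets_hz
  nvox <- prod(d)
  inm <- phantom$labels > 0
  z <- matrix(0, nvox, length(off))
  ff <- phantom$f_f[inm]; t2f <- phantom$t2f_us[inm]
  t2r <- phantom$t2r_us[inm]; b0 <- phantom$b0_hz[inm]
  peaks <- lapply(c("hydroxyl", "amine", "amide"),
                  function(s) phantom[[paste0("peak_", s)]][inm])
  site_ppm <- cest_site_ppm()
  width <- 0.5
  for (j in seq_along(off)) {
    df <- off[j] - b0
    zj <- .zap_model(df, ff, t2f, t2r)
    xp <- hz_to_ppm(df, schedule$hz_per_ppm)
    for (s in 1:3)
      zj <- zj - peaks[[s]] * .lorentz_fwhm(xp, site_ppm[s], width)
    z[inm, j] <- pmax(zj, 0)
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    e1 <- matrix(stats::rnorm(nvox * length(off), 0, noise_sigma),
                 nvox, length(off))
    e2 <- matrix(stats::rnorm(nvox * length(off), 0, noise_sigma),
                 nvox, length(off))
    z <- sqrt((z + e1)^2 + e2^2)
  }
  stack <- array(z, c(d, length(off)))
  attr(stack, "schedule") <- schedule
  stack
}

#' Default per-region age-effect table for cohort simulation
#'
#' Baselines are the younger-group (< 65 years) regional means and the
#' slopes are the older/younger group gap divided by the 29.7-year gap
#' between the group mean ages, so group differences and rank correlations
#' with age emerge with the signs observed in vivo: the free-proton
#' fraction rises with age everywhere (strongly in WM and the deep gray
#' nuclei), free-pool T2 rises mainly in cortical GM, WM, CSF and thalamus,
#' and restricted-pool T2 is essentially flat. Subject scatter `sd` is the
#' pooled group SD (IQR/1.349 where only medians are reported).
#'
#' @return Data frame with columns `region`, `metric`, `base`, `slope`
#'   (units per year), `sd`.
#' @export
default_age_effects <- function() {
  gap_years <- 74.6 - 44.9
  tab <- rbind(
    # region, metric, younger mean, older mean, pooled sd
    data.frame(region = c("cortical_gm", "wm", "csf", "hippocampus",
                          "substantia_nigra", "globus_pallidus", "putamen",
                          "caudate", "thalamus"),
               metric = "f_f_pct",
               y = c(64.31, 58.73, 67.95, 61.52, 51.88, 57.68, 64.55,
                     65.88, 54.65),
               o = c(65.26, 60.53, 69.49, 62.65, 54.80, 61.76, 66.11,
                     67.76, 56.41),
               sd = c(1.10, 1.20, 1.87, 1.47, 1.45, 3.60, 1.45, 1.97, 2.39)),
    data.frame(region = c("cortical_gm", "wm", "csf", "hippocampus",
                          "substantia_nigra", "globus_pallidus", "putamen",
                          "caudate", "thalamus"),
               metric = "t2f_us",
               y = c(943.46, 738.23, 1944.42, 648.34, 570.30, 574.65,
                     659.37, 726.23, 583.38),
               o = c(1070.66, 790.04, 2292.13, 657.53, 563.41, 591.61,
                     674.52, 780.22, 621.18),
               sd = c(102.5, 47.1, 352.0, 34.0, 45.4, 64.3, 44.4, 89.3,
                      50.3)),
    data.frame(region = c("cortical_gm", "wm", "csf", "hippocampus",
                          "substantia_nigra", "globus_pallidus", "putamen",
                          "caudate", "thalamus"),
               metric = "t2r_us",
               y = c(37.60, 30.19, 87.18, 28.87, 25.75, 27.20, 30.82,
                     31.84, 27.87),
               o = c(39.95, 31.32, 101.94, 29.00, 25.21, 27.59, 30.73,
                     31.78, 28.33),
               sd = c(4.01, 2.46, 28.67, 2.21, 1.93, 1.60, 2.49, 3.06,
                      1.88))
  )
  data.frame(region = tab$region, metric = tab$metric, base = tab$y,
             slope = (tab$o - tab$y) / gap_years, sd = tab$sd)
}

#' Specification of a simulated aging cohort
#'
#' The default cohort emulates the study population: 43 adults aged 23-86,
#' 13 younger than 65 (mean about 45 +- 14 years) and 30 at least 65 (mean
#' about 75 +- 5 years).
#'
#' @param n_subjects Cohort size (>= 2).
#' @param age_range Two-element span of admissible ages (years).
#' @param age_effects Data frame as from [default_age_effects()].
#' @param group_cut Age (years) splitting younger from older.
#' @param n_younger Number of subjects drawn from the younger stratum;
#'   default scales the 13/43 split.
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 43, age_range = c(23, 86),
                        age_effects = default_age_effects(),
                        group_cut = 65, n_younger = NULL, seed = 1) {
  stopifnot(n_subjects >= 2, length(age_range) == 2L,
            age_range[1] < age_range[2])
  if (is.null(n_younger)) n_younger <- round(n_subjects * 13 / 43)
  structure(list(n_subjects = as.integer(n_subjects),
                 age_range = age_range,
                 age_effects = age_effects,
                 group_cut = group_cut,
                 n_younger = as.integer(n_younger),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of regional ground-truth metrics
#'
#' Ages are drawn stratified (younger stratum about N(44.9, 13.9), older
#' about N(74.6, 4.8), truncated to the cut and the admissible range). Each
#' region/metric value is linear in age plus Gaussian subject scatter:
#' `value = base + slope * (age - 44.9) + N(0, sd)`. This is the
#' ground-truth table feeding the statistics stage; matched per-subject
#' image phantoms are available via [subject_phantom()].
#'
#' @param spec A `cohort_spec`.
#' @return A `cohort_table` data frame with columns `subject_id`, `age`,
#'   `group` ("younger"/"older"), `region`, `metric`, `value`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n_y <- min(spec$n_younger, spec$n_subjects)
  n_o <- spec$n_subjects - n_y
  ages <- c(
    if (n_y) .rnorm_trunc(n_y, 44.9, 13.9, spec$age_range[1],
                          min(spec$group_cut - 0.01, spec$age_range[2])),
    if (n_o) .rnorm_trunc(n_o, 74.6, 4.8,
                          max(spec$group_cut, spec$age_range[1]),
                          spec$age_range[2]))
  eff <- spec$age_effects
  n <- spec$n_subjects
  rows <- do.call(rbind, lapply(seq_len(nrow(eff)), function(i) {
    data.frame(subject_id = sprintf("S%03d", seq_len(n)),
               age = ages,
               region = eff$region[i],
               metric = eff$metric[i],
               value = eff$base[i] + eff$slope[i] * (ages - 44.9) +
                 stats::rnorm(n, 0, eff$sd[i]))
  }))
  rows$group <- ifelse(rows$age >= spec$group_cut, "older", "younger")
  rows <- rows[, c("subject_id", "age", "group", "region", "metric", "value")]
  class(rows) <- c("cohort_table", "data.frame")
  attr(rows, "spec") <- spec
  rows
}

#' Build the image phantom of one simulated subject
#'
#' Maps the subject's cohort-table WM / cortical GM / CSF values onto the
#' three-region default phantom so that image-domain pipelines (fit,
#' CEST extraction) can be run for individual simulated subjects.
#'
#' @param cohort A `cohort_table`.
#' @param subject_id Subject to materialise.
#' @param shape Phantom grid.
#' @return A `zap_phantom`.
#' @export
subject_phantom <- function(cohort, subject_id, shape = c(64, 64, 3)) {
  rows <- cohort[cohort$subject_id == subject_id, ]
  if (!nrow(rows)) stop("unknown subject_id")
  regions <- default_phantom_regions()
  map <- c(wm = "wm", gm = "cortical_gm", csf = "csf")
  for (i in seq_along(regions)) {
    src <- map[[regions[[i]]$label]]
    get <- function(m) rows$value[rows$region == src & rows$metric == m]
    if (length(get("f_f_pct")))
      regions[[i]]$params_mean[["f_f"]] <- get("f_f_pct") / 100
    if (length(get("t2f_us")))
      regions[[i]]$params_mean[["t2f_us"]] <- get("t2f_us")
    if (length(get("t2r_us")))
      regions[[i]]$params_mean[["t2r_us"]] <- get("t2r_us")
  }
  subj_seed <- attr(cohort, "spec")$seed * 1000L +
    match(subject_id, unique(cohort$subject_id))
  make_phantom(phantom_spec(shape = shape, regions = regions,
                            seed = subj_seed %% .Machine$integer.max))
}
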