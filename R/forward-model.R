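#' Two-pool ZAP parameter triple
#'
#' The three independent variables of the two-Lorentzian Z-spectrum model:
#' the fraction `f_f` of relatively free exchange protons (the restricted
#' fraction is `1 - f_f`, never stored), and the apparent transverse
#' relaxation times of the free and restricted pools in microseconds. Pool
#' identity is fixed by convention `t2f_us > t2r_us`.
#'
#' @param f_f Free-pool fraction, strictly inside (0, 1).
#' @param t2f_us Apparent T2 of the free pool (us), typically 560-2300.
#' @param t2r_us Apparent T2 of the restricted pool (us), typically 25-102.
#' @return An object of class `two_pool_params`.
#' @export
two_pool_params <- function(f_f, t2f_us, t2r_us) {
  stopifnot(is.numeric(f_f), is.numeric(t2f_us), is.numeric(t2r_us))
  if (f_f <= 0 || f_f >= 1) stop("f_f must lie strictly in (0, 1)")
  if (t2r_us <= 0) stop("t2r_us must be positive")
  if (t2f_us <= t2r_us) stop("pool convention requires t2f_us > t2r_us")
  structure(list(f_f = f_f, t2f_us = t2f_us, t2r_us = t2r_us),
            class = "two_pool_params")
}

#' @export
print.two_pool_params <- function(x, ...) {
  cat(sprintf("two-pool params: F_f = %.4f (F_r = %.4f), T2f = %.1f us, T2r = %.2f us\n",
              x$f_f, 1 - x$f_f, x$t2f_us, x$t2r_us))
  invisible(x)
}

#' A CEST exchange-proton peak
#'
#' Labile-proton pools appear as narrow saturation dips downfield of water:
#' hydroxyl (-OH) near 1.0 ppm, amine (-NH2) near 2.0 ppm and amide (-NH)
#' near 3.5 ppm. A peak is an additive Lorentzian dip in Z-units.
#'
#' @param site One of `"hydroxyl"`, `"amine"`, `"amide"`.
#' @param amplitude Dip depth in Z-units (>= 0).
#' @param offset_ppm Center (downfield, > 0); defaults to the site's nominal
#'   position.
#' @param width_ppm Full width at half maximum in ppm.
#' @return An object of class `cest_peak`.
#' @export
cest_peak <- function(site = c("hydroxyl", "amine", "amide"),
                      amplitude, offset_ppm = NULL, width_ppm = 0.5) {
  site <- match.arg(site)
  if (is.null(offset_ppm)) offset_ppm <- cest_site_ppm()[[site]]
  stopifnot(amplitude >= 0, width_ppm > 0, offset_ppm > 0)
  structure(list(site = site, offset_ppm = offset_ppm,
                 amplitude = amplitude, width_ppm = width_ppm),
            class = "cest_peak")
}

#' Nominal CEST site positions (ppm downfield of water)
#' @return Named numeric vector.
#' @export
cest_site_ppm <- function() {
  c(hydroxyl = 1.0, amine = 2.0, amide = 3.5)
}

#' Lorentzian lineshape parameterised by T2
#'
#' `L(df; T2) = 1 / (1 + (2 * pi * df * T2)^2)` with T2 in seconds, so
#' `L(0) = 1` and the full width at half maximum is `1 / (pi * T2)`.
#'
#' @param delta_hz Offset from the line center (Hz).
#' @param t2_us Transverse relaxation time (us), > 0.
#' @return Amplitude in (0, 1].
#' @export
lorentzian <- function(delta_hz, t2_us) {
  if (any(t2_us <= 0)) stop("t2_us must be positive")
  t2 <- t2_us * 1e-6
  1 / (1 + (2 * pi * delta_hz * t2)^2)
}

# Lorentzian dip with explicit FWHM, used for the narrow CEST peaks on the
# ppm axis.
.lorentz_fwhm <- function(x, center, fwhm) {
  1 / (1 + (2 * (x - center) / fwhm)^2)
}

#' A Z-spectrum
#'
#' Normalised water signal `S/S0` against saturation offset, stored on the
#' canonical ascending frequency axis.
#'
#' @param offsets_hz Frequency axis (Hz); sorted ascending internally.
#' @param z Normalised signal, same length as the axis.
#' @param hz_per_ppm Hz-per-ppm scale (or an `offset_schedule`).
#' @return An object of class `zspectrum`.
#' @export
zspectrum <- function(offsets_hz, z, hz_per_ppm = GAMMA_MHZ_PER_T * 3) {
  stopifnot(length(offsets_hz) == length(z))
  o <- order(offsets_hz)
  offsets_hz <- offsets_hz[o]
  if (anyDuplicated(offsets_hz)) stop("offset axis must be strictly increasing")
  structure(list(offsets_hz = offsets_hz, z = z[o],
                 hz_per_ppm = .hz_per_ppm(hz_per_ppm)),
            class = "zspectrum")
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("Z-spectrum: %d offsets, %+.0f .. %+.0f Hz, Z in [%.3f, %.3f]\n",
              length(x$offsets_hz), min(x$offsets_hz), max(x$offsets_hz),
              min(x$z), max(x$z)))
  invisible(x)
}

#' Synthesize a two-pool Z-spectrum with optional CEST peaks
#'
#' The model is
#' `Z(df) = 1 - F_f L(df - d; T2f) - (1 - F_f) L(df - d; T2r)
#'          - sum_k A_k L_k(df - d)`,
#' where `d` is the static-field (B0) shift and each CEST term is a narrow
#' fixed-width Lorentzian dip on the ppm axis. Direct saturation at water is
#' complete (`Z(d) = 0` without peaks), which is what keeps the model at
#' exactly three free parameters.
#'
#' @param params A `two_pool_params`.
#' @param schedule An `offset_schedule`, or a numeric vector of offsets (Hz).
#' @param peaks List of `cest_peak` objects (may be empty).
#' @param b0_shift_hz Static-field shift of the water line (Hz).
#' @param hz_per_ppm Used only when `schedule` is a bare numeric axis.
#' @return A `zspectrum`. Values driven below 0 by peak amplitudes are
#'   clipped to 0 with a warning.
#' @export
synth_zspectrum <- function(params, schedule, peaks = list(),
                            b0_shift_hz = 0,
                            hz_per_ppm = GAMMA_MHZ_PER_T * 3) {
  stopifnot(inherits(params, "two_pool_params"))
  if (inherits(schedule, "offset_schedule")) {
    off <- schedule$offsets_hz
    hz_per_ppm <- schedule$hz_per_ppm
  } else {
    off <- sort(as.numeric(schedule))
  }
  z <- .zap_model(off - b0_shift_hz, params$f_f, params$t2f_us, params$t2r_us)
  if (length(peaks)) {
    x_ppm <- hz_to_ppm(off - b0_shift_hz, hz_per_ppm)
    for (p in peaks) {
      stopifnot(inherits(p, "cest_peak"))
      z <- z - p$amplitude * .lorentz_fwhm(x_ppm, p$offset_ppm, p$width_ppm)
    }
  }
  if (any(z < 0)) {
    warning("peak amplitudes drove Z below 0; clipping")
    z <- pmax(z, 0)
  }
  zspectrum(off, z, hz_per_ppm)
}

# Broad two-pool baseline on a delta-frequency axis (Hz).
.zap_model <- function(delta_hz, f_f, t2f_us, t2r_us) {
  1 - f_f * lorentzian(delta_hz, t2f_us) -
    (1 - f_f) * lorentzian(delta_hz, t2r_us)
}

# Linear interpolation of a zspectrum with flat end extrapolation.
.interp_z <- function(zspec, at_hz) {
  stats::approx(zspec$offsets_hz, zspec$z, xout = at_hz, rule = 2)$y
}

#' Magnetization-transfer ratio asymmetry
#'
#' `MTR_asym(x) = Z(-x) - Z(+x)`: the conventional CEST contrast, positive
#' where a downfield exchange dip breaks the spectrum's symmetry. Values at
#' non-sampled offsets are linearly interpolated.
#'
#' @param zspec A `zspectrum`.
#' @param offset_ppm Positive offset(s) at which to evaluate (ppm).
#' @return Numeric vector of asymmetries.
#' @export
mtr_asym <- function(zspec, offset_ppm) {
  stopifnot(inherits(zspec, "zspectrum"), all(offset_ppm > 0))
  x_hz <- ppm_to_hz(offset_ppm, zspec$hz_per_ppm)
  rng <- range(zspec$offsets_hz)
  if (any(x_hz > rng[2] | -x_hz < rng[1]))
    stop("offset beyond the sampled axis")
  .interp_z(zspec, -x_hz) - .interp_z(zspec, x_hz)
}
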