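#' Estimate the static-field (B0) frequency shift of a Z-spectrum
#'
#' The water line is the deep direct-saturation minimum at the center of the
#' spectrum; a static-field offset displaces it from 0 Hz. The shift is
#' located as the minimum of a cubic-spline interpolant of Z restricted to
#' the densely sampled band around water (WASSR-style localisation using
#' only the CEST acquisition itself).
#'
#' @param zspec A `zspectrum` covering the dense band.
#' @param band_hz Half-width of the dense band used for interpolation (Hz).
#' @param max_shift_hz Search bound for the shift magnitude.
#' @param method `"spline"` (default) locates the spline minimum directly.
#'   `"model"` fits the two-pool model plus a shift term to the points
#'   outside the downfield CEST windows (0.55-4.1 ppm); unlike the spline
#'   minimum it is not pulled toward the hydroxyl/amine/amide dips and is
#'   preferred when CEST peaks are expected.
#' @return A list of class `b0_estimate`: `shift_hz`, `method`, `residual`
#'   (interpolated Z, or SSR, at the solution) and `ok` (FALSE when no
#'   interior minimum was found, in which case `shift_hz` is 0).
#' @export
estimate_b0_shift <- function(zspec, band_hz = 1650, max_shift_hz = 650,
                              method = c("spline", "model")) {
  stopifnot(inherits(zspec, "zspectrum"))
  method <- match.arg(method)
  in_band <- abs(zspec$offsets_hz) <= band_hz
  if (sum(in_band) < 5L)
    stop("spectrum does not cover the dense band around water")
  sf <- stats::splinefun(zspec$offsets_hz[in_band], zspec$z[in_band],
                         method = "natural")
  lo <- max(-max_shift_hz, min(zspec$offsets_hz[in_band]))
  hi <- min(max_shift_hz, max(zspec$offsets_hz[in_band]))
  opt <- stats::optimize(sf, interval = c(lo, hi))
  shift <- opt$minimum
  # A minimum jammed against the search bound means localisation failed.
  ok <- shift > lo + 1e-6 && shift < hi - 1e-6
  if (method == "spline" || !ok)
    return(structure(list(shift_hz = if (ok) shift else 0,
                          method = "spline-minimum",
                          residual = opt$objective,
                          ok = ok),
                     class = "b0_estimate"))

  # CEST-blind refinement: two-pool + shift fit on points outside the
  # downfield exchange band, seeded at the spline estimate.
  x_ppm <- hz_to_ppm(zspec$offsets_hz, zspec$hz_per_ppm)
  use <- !(x_ppm > 0.55 & x_ppm < 4.1)
  off <- zspec$offsets_hz[use]
  zm <- zspec$z[use]
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(0.6, 1000, 40, shift),
      lower = c(0.01, 100, 5, lo), upper = c(0.99, 10000, 500, hi),
      fn = function(p) .zap_model(off - p[4], p[1], p[2], p[3]) - zm,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(shift_hz = shift, method = "spline-minimum",
                          residual = opt$objective, ok = ok),
                     class = "b0_estimate"))
  structure(list(shift_hz = fit$par[4], method = "model",
                 residual = sum(fit$fvec^2), ok = TRUE),
            class = "b0_estimate")
}

#' Apply a B0 correction to a Z-spectrum
#'
#' Shifts the frequency axis by `-shift_hz` and re-interpolates the signal
#' linearly back onto the original canonical axis, extrapolating flat at the
#' ends. The sample count and axis are unchanged.
#'
#' @param zspec A `zspectrum`.
#' @param est A `b0_estimate` (or a bare shift in Hz).
#' @param max_shift_hz Shifts larger than this are rejected.
#' @return The corrected `zspectrum` on the same axis.
#' @export
apply_b0_correction <- function(zspec, est, max_shift_hz = 650) {
  stopifnot(inherits(zspec, "zspectrum"))
  shift <- if (inherits(est, "b0_estimate")) est$shift_hz else as.numeric(est)
  if (abs(shift) > max_shift_hz)
    stop(sprintf("shift %.1f Hz exceeds the correctable band (+-%.0f Hz)",
                 shift, max_shift_hz))
  if (shift == 0) return(zspec)
  z_new <- stats::approx(zspec$offsets_hz - shift, zspec$z,
                         xout = zspec$offsets_hz, rule = 2)$y
  zspectrum(zspec$offsets_hz, z_new, zspec$hz_per_ppm)
}
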