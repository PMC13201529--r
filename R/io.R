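#' Write a 4D Z-stack and its offset table
#'
#' The stack goes to NIfTI and the schedule to a CSV sidecar
#' (see [write_offsets_csv()]).
#'
#' @param stack 4D array with (optionally) a `"schedule"` attribute.
#' @param path NIfTI path (`.nii` or `.nii.gz`).
#' @param offsets_path CSV sidecar path; default replaces the extension.
#' @param schedule Schedule to record; default taken from the attribute.
#' @export
write_zstack <- function(stack, path, offsets_path = NULL, schedule = NULL) {
  if (is.null(schedule)) schedule <- attr(stack, "schedule")
  stopifnot(!is.null(schedule), length(dim(stack)) == 4L)
  if (is.null(offsets_path))
    offsets_path <- sub("\\.nii(\\.gz)?$", "_offsets.csv", path)
  RNifti::writeNifti(RNifti::asNifti(unclass(array(stack, dim(stack)))),
                     path)
  write_offsets_csv(schedule, offsets_path)
  invisible(path)
}

#' Read a 4D Z-stack with its offset table
#'
#' @param path NIfTI path.
#' @param offsets_path Offset CSV sidecar.
#' @param tr_ms,field_tesla Metadata passed to [read_offsets_csv()].
#' @return The 4D array with attribute `"schedule"`. Errors when the volume
#'   count and offset count disagree, naming both.
#' @export
read_zstack <- function(path, offsets_path, tr_ms = 1500, field_tesla = 3) {
  img <- RNifti::readNifti(path)
  stack <- array(as.numeric(img), dim(img))
  schedule <- read_offsets_csv(offsets_path, tr_ms, field_tesla)
  if (length(dim(stack)) != 4L)
    stop("expected a 4D stack, got ", length(dim(stack)), " dimensions")
  if (dim(stack)[4] != length(schedule$offsets_hz))
    stop(sprintf("stack has %d volumes but offset table has %d offsets",
                 dim(stack)[4], length(schedule$offsets_hz)))
  attr(stack, "schedule") <- schedule
  stack
}

#' Write ZAP parameter maps as NIfTI volumes with a JSON sidecar
#'
#' One NIfTI per metric plus `maps.json` recording the fit configuration
#' and counts.
#'
#' @param maps A `zap_maps`.
#' @param dir Output directory (created if needed).
#' @export
write_param_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in c("f_f", "f_r", "t2f_us", "t2r_us", "ssr"))
    RNifti::writeNifti(RNifti::asNifti(maps[[m]]),
                       file.path(dir, paste0(m, ".nii.gz")))
  side <- list(n_fitted = maps$n_fitted, n_failed = maps$n_failed,
               config = list(f_f_bounds = maps$config$f_f_bounds,
                             t2f_bounds_us = maps$config$t2f_bounds_us,
                             t2r_bounds_us = maps$config$t2r_bounds_us,
                             n_starts = maps$config$n_starts))
  jsonlite::write_json(side, file.path(dir, "maps.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a run configuration from YAML
#'
#' Recognised keys: `blocks` (list of `[step_hz, n_pos, n_neg]`), `tr_ms`,
#' `field_tesla`, `phantom` (shape, b0_sd_hz, noise_sigma), `cohort`
#' (n_subjects, group_cut), `seed`, `cest` (k, window_ppm, width_ppm).
#' Missing keys take package defaults.
#'
#' @param path YAML file.
#' @return A list of class `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(run_config_defaults(cfg), class = "run_config")
}

#' Default run configuration
#' @param cfg Partial configuration list to merge over the defaults.
#' @return Completed configuration list.
#' @export
run_config_defaults <- function(cfg = list()) {
  def <- list(
    tr_ms = 1500, field_tesla = 3, seed = 1,
    blocks = NULL,
    phantom = list(shape = c(16, 16, 1), b0_sd_hz = 25,
                   noise_sigma = 0.005),
    cohort = list(n_subjects = 43, group_cut = 65),
    cest = list(k = 3, window_ppm = 0.4, width_ppm = 0.5)
  )
  for (k in names(cfg)) {
    if (is.list(def[[k]]) && is.list(cfg[[k]]))
      def[[k]][names(cfg[[k]])] <- cfg[[k]]
    else def[[k]] <- cfg[[k]]
  }
  def
}

.config_blocks <- function(config) {
  if (is.null(config$blocks)) return(default_offset_blocks())
  do.call(rbind, lapply(config$blocks, function(b)
    data.frame(step_hz = b[[1]], n_pos = b[[2]], n_neg = b[[3]])))
}

#' Run the full simulate / correct / fit / extract / stats pipeline
#'
#' Chains the package stages end to end on synthetic data: build the offset
#' schedule, generate a phantom and its noisy 4D acquisition, estimate and
#' apply per-ROI B0 correction, fit the two-pool model voxel-by-voxel,
#' extract CEST peaks from the per-ROI residuals, simulate an aging cohort
#' and produce the statistical report. All artifacts are written under
#' `out_dir` with a JSON sidecar recording the configuration hash and
#' seeds; rerunning with the same config reproduces them byte-for-byte.
#'
#' @param config A `run_config` list (see [read_config()]); missing entries
#'   take defaults.
#' @param out_dir Output directory; `NULL` keeps everything in memory.
#' @return Invisibly, a list with `schedule`, `phantom`, `stack`,
#'   `b0` (per-ROI estimates), `maps`, `roi_fits`, `cest`, `cohort`,
#'   `report`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  config <- run_config_defaults(config)
  schedule <- build_offset_table(.config_blocks(config),
                                 tr_ms = config$tr_ms,
                                 field_tesla = config$field_tesla)
  ph_spec <- phantom_spec(shape = config$phantom$shape,
                          b0_sd_hz = config$phantom$b0_sd_hz,
                          noise_sigma = config$phantom$noise_sigma,
                          seed = config$seed)
  phantom <- make_phantom(ph_spec)
  stack <- simulate_acquisition(phantom, schedule)
  masks <- phantom_masks(phantom)

  # Per-ROI B0 estimation on the mean ROI spectrum, then correction of the
  # voxel spectra by the ROI shift before fitting and CEST extraction.
  b0_tab <- list(); roi_fits <- list(); cest_rows <- list()
  corrected <- stack
  nvol <- prod(dim(stack)[1:3])
  for (rg in names(masks)) {
    idx <- which(masks[[rg]])
    roi_z <- vapply(seq_len(dim(stack)[4]), function(j)
      mean(stack[idx + nvol * (j - 1L)]), numeric(1))
    zs <- zspectrum(schedule$offsets_hz, roi_z, schedule$hz_per_ppm)
    ana <- analyze_spectrum(zs, k = config$cest$k,
                            window_ppm = config$cest$window_ppm,
                            width_ppm = config$cest$width_ppm)
    est <- ana$b0
    b0_tab[[rg]] <- data.frame(roi = rg, shift_hz = est$shift_hz,
                               method = est$method, residual = est$residual)
    roi_fits[[rg]] <- ana$fit
    peaks <- ana$peaks
    peaks$roi <- rg
    cest_rows[[rg]] <- peaks
    # voxel-level correction: shift the ROI's voxels by the ROI estimate
    sub <- matrix(stack[rep(idx, dim(stack)[4]) +
                          nvol * rep(seq_len(dim(stack)[4]) - 1L,
                                     each = length(idx))],
                  length(idx), dim(stack)[4])
    for (v in seq_along(idx)) {
      zc <- apply_b0_correction(zspectrum(schedule$offsets_hz, sub[v, ],
                                          schedule$hz_per_ppm), est)
      corrected[idx[v] + nvol * (seq_len(dim(stack)[4]) - 1L)] <- zc$z
    }
  }
  b0_tab <- do.call(rbind, b0_tab)
  cest_tab <- do.call(rbind, cest_rows)

  mask_all <- phantom$labels > 0
  maps <- fit_volume(corrected, mask_all, schedule)

  cohort <- simulate_cohort(cohort_spec(
    n_subjects = config$cohort$n_subjects,
    group_cut = config$cohort$group_cut, seed = config$seed))
  report <- build_report(cohort, group_cut = config$cohort$group_cut)

  res <- list(schedule = schedule, phantom = phantom, stack = stack,
              b0 = b0_tab, maps = maps, roi_fits = roi_fits,
              cest = cest_tab, cohort = cohort, report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_zstack(stack, file.path(out_dir, "zstack.nii.gz"),
                 file.path(out_dir, "offsets.csv"), schedule)
    utils::write.csv(b0_tab, file.path(out_dir, "b0_estimates.csv"),
                     row.names = FALSE)
    write_param_maps(maps, file.path(out_dir, "maps"))
    utils::write.csv(cest_tab, file.path(out_dir, "cest_peaks.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(report$correlations,
                     file.path(out_dir, "report_correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(report$comparisons,
                     file.path(out_dir, "report_comparisons.csv"),
                     row.names = FALSE)
    side <- list(seed = config$seed,
                 config_hash = config_hash(config),
                 n_offsets = length(schedule$offsets_hz),
                 package_version = as.character(utils::packageVersion("zapcest")))
    jsonlite::write_json(side, file.path(out_dir, "run.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}

#' Deterministic hash of a run configuration
#' @param config Configuration list.
#' @return Character scalar.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # small rolling hash; avoids a digest dependency
  v <- utf8ToInt(as.character(s))
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 2147483647
  sprintf("%x", h)
}
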