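#' Gyromagnetic ratio of the proton in MHz per tesla
#' @keywords internal
GAMMA_MHZ_PER_T <- 42.576

#' Default saturation-offset blocks
#'
#' The default acquisition samples 56 offsets: a single point at the water
#' resonance, a dense 150 Hz grid of 11 points per sign covering the CEST
#' band, one bridging point per sign at a 1300 Hz step, 13 points per sign
#' at a 3000 Hz step, and 2 positive / 3 negative far-wing points at a
#' 30 kHz step, reaching roughly +-100 kHz (+-800 ppm at 3 T).
#'
#' @return A data frame with columns `step_hz`, `n_pos`, `n_neg`.
#' @export
default_offset_blocks <- function() {
  data.frame(
    step_hz = c(0, 150, 1300, 3000, 30000),
    n_pos   = c(1, 11, 1, 13, 2),
    n_neg   = c(0, 11, 1, 13, 3)
  )
}

#' Build a saturation-offset schedule from step blocks
#'
#' Blocks are cumulative: each block appends `n_pos` (`n_neg`) points spaced
#' `step_hz` apart beyond the previous block's positive (negative) extreme,
#' so dense sampling near water gives way to sparse far wings. The first
#' block must be the single zero offset.
#'
#' @param blocks Data frame with columns `step_hz`, `n_pos`, `n_neg`; steps
#'   must be non-negative and strictly increasing, counts non-negative.
#'   Defaults to [default_offset_blocks()].
#' @param tr_ms Repetition time in milliseconds (one shot per offset).
#' @param field_tesla Static field strength; fixes the Hz-per-ppm scale via
#'   the proton gyromagnetic ratio (42.576 MHz/T).
#' @return An object of class `offset_schedule`: a list with the canonical
#'   ascending `offsets_hz`, the centric `acq_order` permutation,
#'   `hz_per_ppm`, `tr_ms`, `field_tesla` and the `blocks` used.
#' @examples
#' sched <- build_offset_table()
#' length(sched$offsets_hz)  # 56
#' @export
build_offset_table <- function(blocks = default_offset_blocks(),
                               tr_ms = 1500, field_tesla = 3) {
  stopifnot(is.data.frame(blocks),
            all(c("step_hz", "n_pos", "n_neg") %in% names(blocks)))
  if (nrow(blocks) == 0L) stop("empty block table")
  if (any(blocks$n_pos < 0) || any(blocks$n_neg < 0))
    stop("block point counts must be non-negative")
  if (nrow(blocks) > 1L) {
    steps <- blocks$step_hz[-1L]
    if (any(steps <= 0) || any(diff(steps) <= 0))
      stop("block steps must be positive and strictly increasing")
  }
  pos <- numeric(0)
  neg <- numeric(0)
  ext_pos <- 0
  ext_neg <- 0
  has_zero <- FALSE
  for (i in seq_len(nrow(blocks))) {
    step <- blocks$step_hz[i]
    if (step == 0) {
      if (blocks$n_pos[i] + blocks$n_neg[i] != 1L)
        stop("zero-step block must contribute exactly the single 0 Hz point")
      has_zero <- TRUE
      next
    }
    if (blocks$n_pos[i] > 0) {
      pos <- c(pos, ext_pos + step * seq_len(blocks$n_pos[i]))
      ext_pos <- pos[length(pos)]
    }
    if (blocks$n_neg[i] > 0) {
      neg <- c(neg, ext_neg - step * seq_len(blocks$n_neg[i]))
      ext_neg <- neg[length(neg)]
    }
  }
  if (!has_zero) stop("schedule must contain the 0 Hz water-resonance point")
  offsets <- sort(c(neg, 0, pos))
  if (anyDuplicated(offsets)) stop("duplicate offsets produced by blocks")
  sched <- structure(
    list(offsets_hz = offsets,
         acq_order = integer(0),
         hz_per_ppm = GAMMA_MHZ_PER_T * field_tesla,
         tr_ms = tr_ms,
         field_tesla = field_tesla,
         blocks = blocks),
    class = "offset_schedule")
  sched$acq_order <- centric_order(sched)
  sched
}

#' Centric acquisition order of a schedule
#'
#' Acquisition starts at the water resonance (0 Hz) and extends symmetrically
#' outward, alternating positive then negative at each magnitude. Offsets of
#' whichever sign has surplus points are appended last, ascending in
#' magnitude.
#'
#' @param schedule An `offset_schedule`.
#' @return An integer permutation of `seq_along(schedule$offsets_hz)` into
#'   acquisition order, beginning at the zero offset.
#' @export
centric_order <- function(schedule) {
  off <- schedule$offsets_hz
  i0 <- which(off == 0)
  if (length(i0) != 1L) stop("schedule must contain exactly one zero offset")
  ipos <- which(off > 0)[order(off[off > 0])]
  ineg <- which(off < 0)[order(-off[off < 0])]    # ascending magnitude
  npair <- min(length(ipos), length(ineg))
  inter <- integer(0)
  if (npair > 0)
    inter <- as.vector(rbind(ipos[seq_len(npair)], ineg[seq_len(npair)]))
  surplus <- if (length(ipos) > npair) ipos[-seq_len(npair)]
             else if (length(ineg) > npair) ineg[-seq_len(npair)]
             else integer(0)
  c(i0, inter, surplus)
}

#' Convert chemical-shift offsets between ppm and Hz
#'
#' Linear scaling about the water resonance (0 ppm = 0 Hz) using the
#' schedule's Hz-per-ppm factor (127.728 Hz/ppm at 3 T).
#'
#' @param x Offsets to convert (ppm or Hz).
#' @param hz_per_ppm Scale factor; an `offset_schedule` may be passed
#'   instead.
#' @return Converted offsets.
#' @export
ppm_to_hz <- function(x, hz_per_ppm = GAMMA_MHZ_PER_T * 3) {
  s <- .hz_per_ppm(hz_per_ppm)
  x * s
}

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(x, hz_per_ppm = GAMMA_MHZ_PER_T * 3) {
  s <- .hz_per_ppm(hz_per_ppm)
  x / s
}

.hz_per_ppm <- function(hz_per_ppm) {
  if (inherits(hz_per_ppm, "offset_schedule")) hz_per_ppm <- hz_per_ppm$hz_per_ppm
  stopifnot(is.numeric(hz_per_ppm), hz_per_ppm > 0)
  hz_per_ppm
}

#' Acquisition time per slice
#'
#' One single-shot readout per offset, so time is simply the offset count
#' times the repetition time. The 56-offset schedule at TR 1500 ms takes
#' 84 s per slice.
#'
#' @param schedule An `offset_schedule` with `tr_ms` set.
#' @return Seconds per slice.
#' @export
acquisition_time <- function(schedule) {
  stopifnot(is.numeric(schedule$tr_ms), schedule$tr_ms > 0)
  length(schedule$offsets_hz) * schedule$tr_ms / 1000
}

#' @export
print.offset_schedule <- function(x, ...) {
  cat("Saturation-offset schedule:", length(x$offsets_hz), "offsets,",
      sum(x$offsets_hz > 0), "positive /", sum(x$offsets_hz < 0), "negative\n")
  cat(sprintf("  range %+.0f .. %+.0f Hz (%.1f .. %.1f ppm) at %.3f Hz/ppm\n",
              min(x$offsets_hz), max(x$offsets_hz),
              hz_to_ppm(min(x$offsets_hz), x$hz_per_ppm),
              hz_to_ppm(max(x$offsets_hz), x$hz_per_ppm), x$hz_per_ppm))
  cat(sprintf("  TR %.0f ms -> %.1f s per slice\n", x$tr_ms,
              acquisition_time(x)))
  invisible(x)
}

#' Write / read an offset schedule as CSV
#'
#' Columns are `index`, `offset_hz`, `offset_ppm`, `acq_order` (the rank of
#' each canonical offset in acquisition order).
#'
#' @param schedule An `offset_schedule`.
#' @param path CSV file path.
#' @export
write_offsets_csv <- function(schedule, path) {
  ord <- match(seq_along(schedule$offsets_hz), schedule$acq_order)
  df <- data.frame(index = seq_along(schedule$offsets_hz),
                   offset_hz = schedule$offsets_hz,
                   offset_ppm = hz_to_ppm(schedule$offsets_hz,
                                          schedule$hz_per_ppm),
                   acq_order = ord)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_offsets_csv
#' @param tr_ms,field_tesla Acquisition metadata not stored in the CSV.
#' @export
read_offsets_csv <- function(path, tr_ms = 1500, field_tesla = 3) {
  df <- utils::read.csv(path)
  stopifnot(all(c("offset_hz", "acq_order") %in% names(df)))
  off <- sort(as.numeric(df$offset_hz))
  sched <- structure(
    list(offsets_hz = off,
         acq_order = order(df$acq_order[order(df$offset_hz)]),
         hz_per_ppm = GAMMA_MHZ_PER_T * field_tesla,
         tr_ms = tr_ms,
         field_tesla = field_tesla,
         blocks = NULL),
    class = "offset_schedule")
  sched
}
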