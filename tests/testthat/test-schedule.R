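test_that("default blocks build the 56-offset cumulative schedule", {
  s <- sched56
  expect_s3_class(s, "offset_schedule")
  expect_length(s$offsets_hz, 56)
  expect_equal(sum(s$offsets_hz == 0), 1)

  # independent enumeration oracle: build each sign cumulatively by hand
  blocks <- default_offset_blocks()
  pos <- neg <- numeric(0)
  for (i in 2:nrow(blocks)) {
    pos <- c(pos, (if (length(pos)) max(pos) else 0) +
               blocks$step_hz[i] * seq_len(blocks$n_pos[i]))
    neg <- c(neg, (if (length(neg)) min(neg) else 0) -
               blocks$step_hz[i] * seq_len(blocks$n_neg[i]))
  }
  expect_equal(s$offsets_hz, sort(c(neg, 0, pos)))
  expect_equal(sum(s$offsets_hz > 0), length(pos))   # 27
  expect_equal(sum(s$offsets_hz < 0), length(neg))   # 28

  # dense 150 Hz band reaches +-1650 Hz
  dense <- s$offsets_hz[abs(s$offsets_hz) <= 1650 & s$offsets_hz != 0]
  expect_true(all(diff(sort(dense[dense > 0])) == 150))
  expect_equal(range(dense), c(-1650, 1650))
})

test_that("degenerate and invalid block tables are handled", {
  one <- build_offset_table(data.frame(step_hz = 0, n_pos = 1, n_neg = 0))
  expect_equal(one$offsets_hz, 0)
  expect_error(build_offset_table(data.frame(step_hz = numeric(0),
                                             n_pos = integer(0),
                                             n_neg = integer(0))),
               "empty")
  expect_error(build_offset_table(data.frame(step_hz = c(0, 300, 150),
                                             n_pos = c(1, 2, 2),
                                             n_neg = c(0, 2, 2))),
               "increasing")
  expect_error(build_offset_table(data.frame(step_hz = c(0, 150),
                                             n_pos = c(1, -1),
                                             n_neg = c(0, 1))),
               "non-negative")
})

test_that("centric order starts at water and alternates symmetrically", {
  mk <- function(off) {
    structure(list(offsets_hz = sort(off)), class = "offset_schedule")
  }
  s1 <- mk(c(0, 150, -150))
  expect_equal(s1$offsets_hz[centric_order(s1)], c(0, 150, -150))
  s2 <- mk(c(0, 150, -150, -300))
  expect_equal(s2$offsets_hz[centric_order(s2)], c(0, 150, -150, -300))

  ord <- sched56$acq_order
  expect_setequal(ord, seq_along(sched56$offsets_hz))
  visited <- sched56$offsets_hz[ord]
  expect_equal(visited[1], 0)
  # alternation: +f, -f pairs for the matched magnitudes
  npair <- sum(sched56$offsets_hz > 0)
  pares <- matrix(visited[2:(2 * npair + 1)], nrow = 2)
  expect_true(all(pares[1, ] > 0 & pares[2, ] < 0))
  expect_true(all(diff(pares[1, ]) > 0))
  # one surplus negative offset, the largest in magnitude, comes last
  surplus <- visited[-(1:(2 * npair + 1))]
  expect_equal(surplus, min(sched56$offsets_hz))
})

test_that("ppm/Hz conversion is linear and self-inverse", {
  expect_equal(ppm_to_hz(0), 0)
  expect_equal(ppm_to_hz(1), 127.728)           # 42.576 MHz/T x 3 T x 1e-6
  expect_equal(ppm_to_hz(800), 102182.4)        # ~100 kHz at 800 ppm
  x <- seq(-800, 800, length.out = 41)
  expect_equal(hz_to_ppm(ppm_to_hz(x)), x)
  expect_equal(hz_to_ppm(255.456, sched56), 2)  # schedule carries the scale
})

test_that("acquisition time is offsets x TR", {
  expect_equal(acquisition_time(sched56), 84)   # 56 x 1.5 s
  one <- build_offset_table(data.frame(step_hz = 0, n_pos = 1, n_neg = 0))
  expect_equal(acquisition_time(one), 1.5)
  slow <- build_offset_table(tr_ms = 10000)
  expect_equal(acquisition_time(slow), 560)     # the >9 min regime
})

test_that("offset CSV round-trips the schedule", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_offsets_csv(sched56, path)
  s2 <- read_offsets_csv(path)
  expect_equal(s2$offsets_hz, sched56$offsets_hz)
  expect_equal(s2$acq_order, sched56$acq_order)
})
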