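test_that("windows are the half-open [p - 200, p + 200) around each peak", {
  # signal value == its own 0-based index, so windows are directly readable
  rec <- ecg_record(matrix(0:4999, ncol = 1), 500)
  cm <- extract_cycles(rec, peaks = 300L, config = extraction_config())
  expect_equal(dim(cm$values), c(1L, 400L))
  expect_identical(cm$values[1, ], as.numeric(100:499))
  expect_equal(cm$metadata$dropped, 0L)
})

test_that("peaks violating the margins are dropped and counted, not fatal", {
  rec <- ecg_record(matrix(0:4999, ncol = 1), 500)
  cm <- extract_cycles(rec, peaks = 100L, config = extraction_config())
  expect_equal(nrow(cm$values), 0L)
  expect_equal(cm$metadata$dropped, 1L)
  # mixed: edge peaks dropped, interior kept; row + dropped == peak count
  peaks <- c(50L, 300L, 2500L, 4900L)
  cm <- extract_cycles(rec, peaks = peaks, config = extraction_config())
  expect_equal(nrow(cm$values) + cm$metadata$dropped, length(peaks))
  expect_equal(nrow(cm$values), 2L)
})

test_that("extraction on simulator records matches a brute-force margin scan", {
  rec <- generate_record(cycle_spec(noise_sd = 0.02), n_beats = 12, rr_ms = 800,
                         jitter = 0.05, seed = 31)
  cfg <- extraction_config(detector = "annotations")
  cm <- extract_cycles(rec, config = cfg)
  n <- nrow(rec$signal)
  keep <- sum(rec$r_peaks - 200L >= 0L & rec$r_peaks + 200L <= n)
  expect_equal(nrow(cm$values), keep)
  expect_equal(nrow(cm$values) + cm$metadata$dropped, length(rec$r_peaks))
  # only the two edge beats can violate the margins
  expect_gte(nrow(cm$values), 10L)
})

test_that("extraction is idempotent", {
  rec <- generate_record(cycle_spec(noise_sd = 0.02), n_beats = 6, rr_ms = 850,
                         jitter = 0.05, seed = 32)
  cfg <- extraction_config(detector = "annotations")
  a <- extract_cycles(rec, config = cfg)
  b <- extract_cycles(rec, config = cfg)
  expect_identical(a$values, b$values)
})

test_that("noise-free extraction recovers the generating template exactly", {
  spec <- cycle_spec(noise_sd = 0)
  rec <- generate_record(spec, n_beats = 5, rr_ms = 800, jitter = 0, seed = 1)
  cm <- extract_cycles(rec, config = extraction_config(detector = "annotations"))
  template <- generate_cycle(spec)
  expect_equal(nrow(cm$values), 5L)
  for (i in seq_len(nrow(cm$values))) {
    expect_identical(cm$values[i, ], template)
  }
})

test_that("the annotation detector is a verbatim pass-through", {
  rec <- generate_record(cycle_spec(noise_sd = 0.02), n_beats = 4, rr_ms = 800,
                         jitter = 0.03, seed = 2)
  expect_identical(detect_r_peaks(rec, extraction_config(detector = "annotations")),
                   rec$r_peaks)
  rec$r_peaks <- NULL
  expect_error(detect_r_peaks(rec, extraction_config(detector = "annotations")),
               "annotations")
})

test_that("the built-in detector finds simulator peaks within 5 samples", {
  rec <- generate_record(cycle_spec(noise_sd = 0.02), n_beats = 12, rr_ms = 800,
                         jitter = 0.05, seed = 41)
  found <- detect_r_peaks(rec, extraction_config(detector = "builtin"))
  expect_length(found, 12)
  expect_true(all(diff(found) >= 200))
  expect_true(all(abs(found - rec$r_peaks) <= 5))
})

test_that("the built-in detector returns nothing on a flat signal", {
  rec <- ecg_record(matrix(0, 5000, 1), 500)
  expect_identical(detect_r_peaks(rec, extraction_config(detector = "builtin")),
                   integer(0))
})

test_that("lead selection works by label and by index", {
  sig <- cbind(rnorm(1000), 0:999)
  rec <- ecg_record(sig, 500, lead_labels = c("I", "II"))
  cm1 <- extract_cycles(rec, peaks = 500L,
                        config = extraction_config(lead = "II",
                                                   detector = "annotations"))
  cm2 <- extract_cycles(rec, peaks = 500L,
                        config = extraction_config(lead = 2L,
                                                   detector = "annotations"))
  expect_identical(cm1$values, cm2$values)
  expect_identical(cm1$values[1, ], as.numeric(300:699))
  expect_error(extract_cycles(rec, peaks = 500L,
                              config = extraction_config(lead = "V1")), "lead")
})

test_that("normalization mode none is the identity", {
  cm <- generate_dataset(cycle_spec(noise_sd = 0.01), 5, jitter = 0.02, seed = 3)
  out <- normalize_cycles(cm, mode = "none")
  expect_identical(out$cycles$values, cm$values)
})

test_that("per-cycle z-scoring inverts exactly and flags constant rows", {
  cm <- generate_dataset(cycle_spec(noise_sd = 0.01), 8, jitter = 0.02, seed = 4)
  out <- normalize_cycles(cm, mode = "per_cycle_zscore")
  expect_equal(unname(rowMeans(out$cycles$values)), rep(0, 8), tolerance = 1e-12)
  back <- denormalize_cycles(out$cycles, out$params)
  expect_equal(back$values, cm$values, tolerance = 1e-12)
  bad <- cycle_matrix(rbind(rnorm(400), rep(1, 400)))
  expect_error(normalize_cycles(bad, mode = "per_cycle_zscore"), "row 2")
})

test_that("global z-scoring of the two-level matrix {0, 2} gives {-1, +1}", {
  cm <- cycle_matrix(rbind(rep(0, 400), rep(2, 400)))
  out <- normalize_cycles(cm, mode = "global_zscore")
  expect_identical(sort(unique(as.vector(out$cycles$values))), c(-1, 1))
  back <- denormalize_cycles(out$cycles, out$params)
  expect_equal(back$values, cm$values, tolerance = 1e-12)
})

test_that("extraction config validates its fields", {
  expect_error(extraction_config(half_width = 0), "half_width")
  expect_error(extraction_config(min_peak_distance = 0), "min_peak_distance")
  expect_error(extraction_config(detection_threshold = 0), "detection_threshold")
  expect_error(extraction_config(detection_threshold = 1.5), "detection_threshold")
})
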