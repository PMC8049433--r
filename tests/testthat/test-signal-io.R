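make_record <- function(n = 1000, leads = 2, fs = 500, r_peaks = c(100L, 500L, 900L)) {
  set.seed(11)
  ecg_record(matrix(rnorm(n * leads), n, leads), sampling_rate = fs,
             lead_labels = paste0("CH", seq_len(leads)), r_peaks = r_peaks)
}

test_that("a delimited single-lead file with a declared rate reads back", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# sampling_rate: 500", sprintf("%.4f", rnorm(5000))), path)
  rec <- read_record(path, format = "delimited")
  expect_s3_class(rec, "ecg_record")
  expect_equal(dim(rec$signal), c(5000L, 1L))
  expect_equal(rec$sampling_rate, 500)
})

test_that("a delimited file without a rate needs an override", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("%.4f", rnorm(100)), path)
  expect_error(read_record(path, format = "delimited"), "sampling_rate")
  rec <- read_record(path, format = "delimited", sampling_rate = 250)
  expect_equal(rec$sampling_rate, 250)
  expect_true(isTRUE(rec$metadata$nonstandard_rate))
})

test_that("array round-trips are lossless and preserve lead order and annotations", {
  rec <- make_record(leads = 12)
  rec$lead_labels <- c("I", "II", "III", "aVR", "aVL", "aVF",
                       "V1", "V2", "V3", "V4", "V5", "V6")
  path <- withr::local_tempfile(fileext = ".rds")
  write_record(rec, path, format = "array")
  back <- read_record(path, format = "array")
  expect_identical(back$signal, rec$signal)
  expect_identical(back$lead_labels, rec$lead_labels)
  expect_identical(back$r_peaks, rec$r_peaks)
  expect_identical(back$sampling_rate, rec$sampling_rate)
})

test_that("empty annotations stay empty, absent annotations stay absent", {
  for (fmt in c("array", "delimited")) {
    path <- withr::local_tempfile()
    rec <- make_record(r_peaks = integer(0))
    write_record(rec, path, format = fmt)
    expect_identical(read_record(path, format = fmt)$r_peaks, integer(0))
    rec$r_peaks <- NULL
    write_record(rec, path, format = fmt)
    expect_null(read_record(path, format = fmt)$r_peaks)
  }
})

test_that("delimited round-trip is exact to the documented 6 decimals", {
  rec <- make_record(n = 200, leads = 3, r_peaks = c(10L, 90L, 180L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_record(rec, path, format = "delimited")
  back <- read_record(path, format = "delimited")
  expect_lt(max(abs(back$signal - rec$signal)), 5e-7)
  expect_identical(back$r_peaks, rec$r_peaks)
  expect_identical(back$lead_labels, rec$lead_labels)
})

test_that("a simulator wfdb fixture reads back with its 3 annotated peaks", {
  rec <- generate_record(cycle_spec(noise_sd = 0.01), n_beats = 3, rr_ms = 800,
                         jitter = 0.02, seed = 21)
  base <- file.path(withr::local_tempdir(), "rec03")
  write_record(rec, base, format = "wfdb")
  expect_true(file.exists(paste0(base, ".hea")))
  expect_true(file.exists(paste0(base, ".dat")))
  expect_true(file.exists(paste0(base, ".atr")))
  back <- read_record(base, format = "wfdb")
  expect_length(back$r_peaks, 3)
  expect_identical(back$r_peaks, rec$r_peaks)
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_identical(back$lead_labels, rec$lead_labels)
  # format-16 with gain 1000 quantizes to 1 uV
  expect_lt(max(abs(back$signal - rec$signal)), 5.01e-4)
})

test_that("wfdb annotations survive long inter-beat gaps (SKIP escape)", {
  rec <- ecg_record(matrix(0, 80000, 1), 500,
                    r_peaks = c(100L, 900L, 5000L, 70000L))
  base <- file.path(withr::local_tempdir(), "sparse")
  write_record(rec, base, format = "wfdb")
  back <- read_record(base, format = "wfdb")
  expect_identical(back$r_peaks, rec$r_peaks)
})

test_that("a 12-lead wfdb record preserves lead order", {
  rec <- make_record(n = 300, leads = 12, r_peaks = NULL)
  rec$lead_labels <- paste0("V", 1:12)
  base <- file.path(withr::local_tempdir(), "multi")
  write_record(rec, base, format = "wfdb")
  back <- read_record(base, format = "wfdb")
  expect_identical(back$lead_labels, rec$lead_labels)
  expect_equal(dim(back$signal), dim(rec$signal))
  expect_lt(max(abs(back$signal - rec$signal)), 5.01e-4)
})

test_that("a record with a non-500 Hz rate is flagged, never resampled", {
  rec <- make_record(fs = 250)
  path <- withr::local_tempfile()
  write_record(rec, path, format = "array")
  back <- read_record(path, format = "array")
  expect_true(isTRUE(back$metadata$nonstandard_rate))
  expect_identical(back$signal, rec$signal)
})

test_that("cycle matrices round-trip bit-exactly with their metadata", {
  set.seed(3)
  cm <- cycle_matrix(matrix(rnorm(252 * 400), 252, 400),
                     metadata = list(source = "test", lead = "II", dropped = 2L))
  path <- withr::local_tempfile(fileext = ".rds")
  write_cycles(cm, path, format = "array")
  back <- read_cycles(path, format = "array")
  expect_identical(back$values, cm$values)
  expect_identical(back$metadata, cm$metadata)
})

test_that("an empty cycle matrix is representable on disk", {
  cm <- cycle_matrix(matrix(0, 0, 400))
  for (fmt in c("array", "csv")) {
    path <- withr::local_tempfile()
    write_cycles(cm, path, format = fmt)
    back <- read_cycles(path, format = fmt)
    expect_equal(dim(back$values), c(0L, 400L))
  }
})

test_that("csv cycles round-trip within text precision and reject ragged rows", {
  set.seed(4)
  cm <- cycle_matrix(matrix(rnorm(10 * 50), 10, 50))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cycles(cm, path, format = "csv")
  back <- read_cycles(path, format = "csv")
  expect_equal(back$values, cm$values, tolerance = 1e-12)
  writeLines(c("V1,V2,V3", "1,2,3", "1,2"), path)
  expect_error(read_cycles(path, format = "csv"), "ragged")
})

test_that("reading a missing file is an I/O error", {
  expect_error(read_record("/nonexistent/r.rds", format = "array"), "no such file")
  expect_error(read_cycles("/nonexistent/c.rds"), "no such file")
})
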