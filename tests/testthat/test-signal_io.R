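test_that("read_rr accumulates beat times and round-trips losslessly", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1000", "", "1000", "1000"), f)
  rr <- read_rr(f)
  expect_s3_class(rr, "rr_series")
  expect_length(rr$rr_ms, 3)
  expect_equal(rr$beat_times, c(0, 1, 2, 3))

  set.seed(1)
  vals <- runif(200, 600, 1100)
  rr2 <- rr_series(rr_ms = vals)
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_rr(rr2, f2)
  expect_identical(read_rr(f2)$rr_ms, vals)

  fs <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.8", "0.9"), fs)
  expect_equal(read_rr(fs, unit = "s")$rr_ms, c(800, 900))
})

test_that("read_rr rejects malformed input with line numbers", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1000", "abc", "900"), f)
  expect_error(read_rr(f), "line 2")
  writeLines(c("1000", "-5"), f)
  expect_error(read_rr(f), "non-positive")
})

test_that("read_ecg handles CSV input with sidecar or inferred fs", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(sprintf("%d", rep(0L, 10)), f)
  writeLines("fs: 100", paste0(f, ".yaml"))
  ecg <- read_ecg(f)
  expect_s3_class(ecg, "ecg_signal")
  expect_length(ecg$samples, 10)
  expect_equal(ecg$fs, 100)
  expect_identical(read_ecg(f)$samples, ecg$samples) # deterministic reread

  writeLines("fs: 0", paste0(f, ".yaml"))
  expect_error(read_ecg(f), "fs")

  f2 <- withr::local_tempfile(fileext = ".csv")
  t <- seq(0, 1, by = 1 / 128)
  writeLines(sprintf("%.10f,%.6f", t, sin(t)), f2)
  ecg2 <- read_ecg(f2)
  expect_equal(ecg2$fs, 128, tolerance = 1e-9)
  expect_equal(ecg2$samples, sin(t), tolerance = 1e-6)
})

test_that("read_ecg parses WFDB format 16 and 212 records", {
  dir <- withr::local_tempdir()
  # format 16, two channels, gain 200, fs 128
  hea <- file.path(dir, "rec16.hea")
  writeLines(c("rec16 2 128 6",
               "rec16.dat 16 200 12 0 0 0 0 I",
               "rec16.dat 16 200 12 0 0 0 0 II"), hea)
  ch1 <- c(100L, -50L, 400L)
  ch2 <- c(7L, 8L, 9L)
  writeBin(as.integer(rbind(ch1, ch2)), file.path(dir, "rec16.dat"),
           size = 2L, endian = "little")
  ecg <- read_ecg(hea)
  expect_equal(ecg$fs, 128)
  expect_equal(ecg$samples, ch1 / 200)
  expect_equal(read_ecg(hea, channel = 2)$samples, ch2 / 200)
  expect_error(read_ecg(hea, channel = 3), "out of range")

  # format 212, single channel
  hea2 <- file.path(dir, "rec212.hea")
  writeLines(c("rec212 1 250 4", "rec212.dat 212 100 12 0 0 0 0 MLII"), hea2)
  v <- c(10L, -5L, 2047L, -2048L)
  pack212 <- function(v) {
    u <- ifelse(v < 0, v + 4096L, v)
    b <- integer(0)
    for (i in seq(1, length(u), by = 2)) {
      a <- u[i]; bb <- if (i + 1 <= length(u)) u[i + 1] else 0L
      b <- c(b, a %% 256L, (a %/% 256L) + 16L * (bb %/% 256L), bb %% 256L)
    }
    as.raw(b)
  }
  writeBin(pack212(v), file.path(dir, "rec212.dat"))
  ecg2 <- read_ecg(hea2)
  expect_equal(ecg2$fs, 250)
  expect_equal(ecg2$samples, v / 100)
})

test_that("garbled WFDB headers raise named format errors", {
  dir <- withr::local_tempdir()
  hea <- file.path(dir, "bad.hea")
  writeLines("bad 2", hea)
  expect_error(read_ecg(hea), "sampling-rate")
  writeLines(c("bad 1 0 10", "bad.dat 16 200"), hea)
  expect_error(read_ecg(hea), "> 0")
  writeLines(c("bad 1 xx 10", "bad.dat 16 200"), hea)
  expect_error(read_ecg(hea), "garbled")
})

test_that("feature tables round-trip bitwise with fixed column order", {
  set.seed(2)
  row <- data.frame(subject_id = "s1", label = "mild",
                    as.list(setNames(rnorm(18), hrv_feature_names)))
  # shuffle columns: writer must restore canonical order
  row <- row[, sample(ncol(row))]
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(row, f)
  back <- read_feature_table(f)
  expect_identical(names(back), c("subject_id", "label", hrv_feature_names))
  expect_equal(ncol(back), 20)
  for (nm in hrv_feature_names)
    expect_identical(back[[nm]], row[[nm]])

  bad <- row[, -which(names(row) == "SDNN")]
  expect_error(write_feature_table(bad, f), "ragged|SDNN")
})
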