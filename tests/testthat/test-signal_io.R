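test_that("csv records read back identically", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0.0", "1,1.0", "2,0.0"), path)
  rec <- read_record(path, format = "csv", fs = 360)
  expect_s3_class(rec, "ecg_record")
  expect_length(rec$samples, 3L)
  expect_equal(rec$fs, 360)
  expect_equal(rec$samples, c(0, 1, 0))

  # round trip through the writer, header included
  rec2 <- ecg_record(sin(seq(0, 6, length.out = 500)), fs = 250, record_id = "rt")
  out <- withr::local_tempfile(fileext = ".csv")
  write_record_csv(rec2, out)
  back <- read_record(out, format = "csv", fs = 250)
  expect_lt(max(abs(back$samples - rec2$samples)), 1e-9)

  expect_error(read_record(path, format = "csv"), "fs")
})

test_that("ecg_record validates its invariants", {
  expect_error(ecg_record(1, 360), "2 samples")
  expect_error(ecg_record(c(0, NA), 360), "finite")
  expect_error(ecg_record(c(0, 1), -5), "positive")
})

test_that("wfdb round trip converts adu to mV via gain and baseline", {
  dir <- withr::local_tempdir()
  x <- c(0, 2.0, -1.5, 0.25, 0)
  rec <- ecg_record(x, fs = 360, record_id = "w1")
  write_record_wfdb(rec, dir, gain = 200, baseline = 0)
  back <- read_record(file.path(dir, "w1"), format = "wfdb")
  expect_equal(back$fs, 360)
  expect_equal(back$samples, x)   # 400 adu at gain 200 -> 2.0 mV, etc.

  # doubling the declared gain halves the read samples (same .dat bytes)
  hea <- readLines(file.path(dir, "w1.hea"))
  hea[2] <- sub(" 200\\(0\\) ", " 400(0) ", hea[2])
  writeLines(hea, file.path(dir, "w1.hea"))
  halved <- read_record(file.path(dir, "w1"), format = "wfdb")
  nz <- x != 0
  expect_equal((back$samples / halved$samples)[nz], rep(2, sum(nz)))
})

test_that("wfdb format 212 decoding matches an independent byte encoder", {
  # independent packing of 12-bit two's-complement pairs, written from the
  # format description rather than the package decoder
  pack212 <- function(vals) {
    stopifnot(length(vals) %% 2 == 0)
    out <- raw(0)
    for (i in seq(1, length(vals), by = 2)) {
      a <- vals[i] %% 4096L
      b <- vals[i + 1L] %% 4096L
      out <- c(out,
               as.raw(a %% 256L),
               as.raw((a %/% 256L) + 16L * (b %/% 256L)),
               as.raw(b %% 256L))
    }
    out
  }
  dir <- withr::local_tempdir()
  adus <- c(0L, 1L, -1L, 100L, -100L, 2047L, -2048L, 7L)
  writeBin(pack212(adus), file.path(dir, "r212.dat"))
  writeLines(c("r212 1 360 8", "r212.dat 212 100(0) 12 0 0 0 0 MLII"),
             file.path(dir, "r212.hea"))
  rec <- read_record(file.path(dir, "r212"), format = "wfdb")
  expect_equal(rec$samples, adus / 100)
})

test_that("wfdb multiplexed channels are separated", {
  dir <- withr::local_tempdir()
  ch1 <- c(10L, 20L, 30L, 40L)
  ch2 <- c(-1L, -2L, -3L, -4L)
  writeBin(as.vector(rbind(ch1, ch2)), file.path(dir, "mx.dat"),
           size = 2L, endian = "little")
  writeLines(c("mx 2 360 4",
               "mx.dat 16 100(0) 16 0 0 0 0 lead1",
               "mx.dat 16 100(0) 16 0 0 0 0 lead2"),
             file.path(dir, "mx.hea"))
  expect_equal(read_record(file.path(dir, "mx"), "wfdb", channel = 1)$samples,
               ch1 / 100)
  expect_equal(read_record(file.path(dir, "mx"), "wfdb", channel = 2)$samples,
               ch2 / 100)
  expect_error(read_record(file.path(dir, "mx"), "wfdb", channel = 3),
               "out of range")
})

test_that("text annotations round trip, validate ordering, allow labels", {
  path <- withr::local_tempfile()
  writeLines(c("10", "50", "90"), path)
  ann <- read_annotations(path, format = "text")
  expect_equal(ann$indices, c(10, 50, 90))

  # empty file -> empty annotations
  writeLines(character(0), path)
  expect_length(read_annotations(path, format = "text"), 0L)

  # unsorted input is a validation error
  writeLines(c("50", "10"), path)
  expect_error(read_annotations(path, format = "text"), "increasing")

  # write/read inversion with labels
  ann2 <- beat_annotations(c(3, 7, 11), labels = c("N", "V", "N"))
  write_annotations(ann2, path)
  expect_equal(readLines(path), c("3\tN", "7\tV", "11\tN"))
  back <- read_annotations(path, format = "text")
  expect_equal(back$indices, ann2$indices)
  expect_equal(back$labels, ann2$labels)

  # empty annotations -> empty file -> round trip
  write_annotations(beat_annotations(numeric(0)), path)
  expect_length(read_annotations(path, format = "text"), 0L)
})

test_that("wfdb annotation reader keeps beats, drops non-beats, handles SKIP", {
  # independent encoding of the MIT annotation byte stream: each event is a
  # 16-bit little-endian word, type in the top 6 bits, time delta in the low
  # 10; SKIP (59) carries a 4-byte interval; EOF is a zero word.
  word <- function(code, delta) {
    a <- code * 1024L + delta
    as.raw(c(a %% 256L, a %/% 256L))
  }
  bytes <- c(
    word(1L, 100L),                       # NORMAL at 100
    word(28L, 50L),                       # RHYTHM (non-beat) at 150
    word(5L, 150L),                       # PVC at 300
    word(59L, 0L),                        # SKIP +1000 (high word first)
    as.raw(c(0L, 0L)), as.raw(c(1000L %% 256L, 1000L %/% 256L)),
    word(1L, 24L),                        # NORMAL at 1324
    word(0L, 0L))                         # EOF
  path <- withr::local_tempfile(fileext = ".atr")
  writeBin(bytes, path)
  ann <- read_annotations(path, format = "wfdb")
  expect_equal(ann$indices, c(100, 300, 1324))
  expect_equal(ann$labels, c("N", "V", "N"))
})
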