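# Record reading, segmentation and wavelet denoising.

write_wfdb16 <- function(dir, name, ch1, ch2, fs = 128, gain = 200) {
  hea <- file.path(dir, paste0(name, ".hea"))
  writeLines(c(
    sprintf("%s 2 %d %d", name, fs, length(ch1)),
    sprintf("%s.dat 16 %d(0)/mV 16 0 0 0 0 ECG1", name, gain),
    sprintf("%s.dat 16 %d(0)/mV 16 0 0 0 0 ECG2", name, gain)
  ), hea)
  interleaved <- as.integer(rbind(ch1, ch2))
  writeBin(interleaved, file.path(dir, paste0(name, ".dat")), size = 2,
           endian = "little")
  hea
}

test_that("WFDB format-16 records read with channel selection and gain", {
  dir <- withr::local_tempdir()
  ch1 <- as.integer(round(200 * sin(seq(0, 10, length.out = 500))))
  ch2 <- as.integer(seq(-250, 249))
  write_wfdb16(dir, "rec1", ch1, ch2)
  r1 <- read_ecg(file.path(dir, "rec1"), "wfdb", channel = 1, label = "NSR")
  expect_equal(r1$fs, 128)
  expect_equal(r1$samples, ch1 / 200, tolerance = 1e-12)
  expect_equal(r1$label, "NSR")
  r2 <- read_ecg(file.path(dir, "rec1"), "wfdb", channel = 2)
  expect_equal(r2$samples, ch2 / 200, tolerance = 1e-12)
  expect_error(read_ecg(file.path(dir, "rec1"), "wfdb", channel = 3),
               class = "mfecg_invalid_argument")
  expect_error(read_ecg(file.path(dir, "missing"), "wfdb"),
               class = "mfecg_format_error")
})

test_that("CSV without a sampling-rate header is a format error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.1", "0.2", "0.3"), path)
  expect_error(read_ecg(path, "csv"), class = "mfecg_format_error")
})

test_that("segmentation cuts floor(N / (t fs)) windows and drops the tail", {
  rec <- mfecg:::new_ecg_record(rnorm(3 * 8192), 128, "NSR", "r1")
  segs <- segment_record(rec, 64)
  expect_length(segs, 3)
  expect_true(all(vapply(segs, function(s) length(s$samples), integer(1)) ==
                    8192))
  expect_equal(vapply(segs, function(s) s$start, integer(1)),
               c(0L, 8192L, 16384L))
  # no samples lost except the remainder
  rec2 <- mfecg:::new_ecg_record(rnorm(2 * 8192 + 100), 128, "NSR", "r2")
  segs2 <- segment_record(rec2, 64)
  expect_equal(sum(lengths(lapply(segs2, `[[`, "samples"))), 2 * 8192)
  # 250 Hz at 64 s gives 16000-sample segments
  rec250 <- mfecg:::new_ecg_record(rnorm(16000), 250, "CHF", "r3")
  expect_length(segment_record(rec250, 64)[[1]]$samples, 16000)
  expect_warning(
    none <- segment_record(mfecg:::new_ecg_record(rnorm(8191), 128,
                                                  "NSR", "r4"), 64))
  expect_length(none, 0)
  expect_error(segment_record(rec, 0), class = "mfecg_invalid_argument")
})

test_that("minimal segment time is n_min / fs", {
  expect_equal(minimal_segment_time(256, 128), 2)
  expect_equal(minimal_segment_time(256, 250), 1.024)
  expect_equal(minimal_segment_time(0, 128), 0)
  expect_error(minimal_segment_time(256, 0), class = "mfecg_invalid_argument")
})

test_that("denoising removes constants, baseline drift and is near-idempotent", {
  const <- mfecg:::new_ecg_segment(rep(3, 512), 128, "NSR", "c", 0)
  expect_lt(max(abs(denoise(const)$samples)), 1e-6)

  tt <- (0:8191) / 128
  template <- rowSums(vapply(seq(0.5, 63.5, by = 0.85), function(b) {
    mfecg:::ecg_beat_template(tt - b)
  }, numeric(length(tt))))
  drift <- 0.8 * sin(2 * pi * tt / 40)
  seg <- mfecg:::new_ecg_segment(template + drift, 128, "NSR", "d", 0)
  dn <- denoise(seg)
  expect_length(dn$samples, 8192)
  expect_gt(cor(dn$samples, template), 0.9)
  expect_lt(abs(mean(dn$samples)), 0.05 * sd(seg$samples))
  dn2 <- denoise(dn)
  rms_change <- sqrt(mean((dn2$samples - dn$samples)^2)) /
    sqrt(mean(dn$samples^2))
  expect_lt(rms_change, 0.05)

  short <- mfecg:::new_ecg_segment(rnorm(256), 128, "NSR", "s", 0)
  expect_error(denoise(short), class = "mfecg_invalid_argument")
})
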