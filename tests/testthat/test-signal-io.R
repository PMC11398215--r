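test_that("read_raw_eeg parses one sample per line and round-trips", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0", "0", "0"), path)
  sig <- read_raw_eeg(path, fs = 128)
  expect_s3_class(sig, "eeg_signal")
  expect_equal(sig$value, c(0, 0, 0))
  expect_equal(signal_fs(sig), 128)

  x <- withr::with_seed(7, stats::rnorm(1024))
  write_raw_eeg(eeg_signal(x, 128), path)
  back <- read_raw_eeg(path, fs = 128)
  expect_identical(back$value, x)
})

test_that("read_raw_eeg reports the offending line and rejects empty files", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1.5", "abc", "2.5"), path)
  expect_error(read_raw_eeg(path), "line 2")

  writeLines(c("# only comments", ""), path)
  expect_error(read_raw_eeg(path), "no samples")
})

test_that("comment and blank lines are skipped without shifting data", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "1", "", "2", "# mid", "3"), path)
  expect_equal(read_raw_eeg(path)$value, c(1, 2, 3))
})

test_that("epoch_signal cuts non-overlapping full windows and drops the tail", {
  sig <- eeg_signal(seq_len(3 * 1024), fs = 128)
  ep <- epoch_signal(sig, 8)
  expect_equal(nrow(ep), 3)
  expect_equal(ep$epoch_index, 0:2)
  expect_equal(ep$t0, c(0, 8, 16))
  expect_true(all(lengths(ep$samples) == 1024))

  ep2 <- epoch_signal(eeg_signal(seq_len(1100), fs = 128), 8)
  expect_equal(nrow(ep2), 1)

  # a 10-minute recording at 128 Hz yields 73 complete 8-s epochs
  ep3 <- epoch_signal(eeg_signal(numeric(73 * 1024), fs = 128), 8)
  expect_equal(nrow(ep3), 73)

  # shorter than one epoch: empty table, not an error
  expect_equal(nrow(epoch_signal(eeg_signal(numeric(100), fs = 128), 8)), 0)
})

test_that("epoching partitions the record exactly", {
  x <- withr::with_seed(11, stats::rnorm(2500))
  ep <- epoch_signal(eeg_signal(x, fs = 128), 8)
  expect_identical(unlist(ep$samples), x[seq_len(nrow(ep) * 1024)])
})

test_that("synth_multitone matches its closed form", {
  sig <- synth_multitone()
  expect_equal(nrow(sig), 1024)
  # at k = n the time grid hits t = 1 exactly, where all cosines are 1
  expect_equal(sig$value[1024], 1 + 0.5 + 0.25)
  single <- synth_multitone(freqs = 12, amps = 1, n = 512, fs = 512)
  expect_equal(single$value, cos(2 * pi * 12 * (1:512) / 512))
  # whole cycles: sample variance = sum(amps^2)/2 within 1%
  v <- var(sig$value) * (1023 / 1024)
  expect_lt(abs(v - (1 + 0.25 + 0.0625) / 2) / v, 0.01)
  expect_error(synth_multitone(freqs = 600, amps = 1, n = 64, fs = 1024),
               "Nyquist")
})

test_that("synth_anesthesia_eeg shapes its spectrum as requested", {
  # delta only: at least 99% of variance below 6 Hz
  d <- synth_anesthesia_eeg(duration = 16, alpha_power = 0, noise_power = 0,
                            seed = 3)
  p <- Mod(fft(d$value))^2
  freq <- (seq_along(p) - 1) * 128 / length(p)
  freq <- pmin(freq, 128 - freq)
  expect_gt(sum(p[freq < 6]) / sum(p), 0.99)

  # band peaks land where asked
  del <- synth_anesthesia_eeg(duration = 16, alpha_power = 0, noise_power = 0,
                              seed = 5)
  expect_true(periodogram_peak(del$value, 128) >= 0.5 &&
                periodogram_peak(del$value, 128) <= 4)
  al <- synth_anesthesia_eeg(duration = 16, delta_power = 0, noise_power = 0,
                             seed = 5)
  expect_lt(abs(periodogram_peak(al$value, 128) - 11), 1)

  # component variances match the requested powers
  expect_equal(var(d$value), 1, tolerance = 0.05)

  # bit-stable under a fixed seed
  a <- synth_anesthesia_eeg(duration = 4, seed = 99)
  b <- synth_anesthesia_eeg(duration = 4, seed = 99)
  expect_identical(a$value, b$value)
  expect_error(synth_anesthesia_eeg(duration = 4, alpha_center = 70, seed = 1),
               "Nyquist")
})
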