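test_that("notch filter suppresses the line tone and passes nearby EEG bands", {
  spec <- filter_spec()
  # steady-state attenuation of a 50 Hz tone (central region, clear of the
  # onset transient of the finite tone) is at least 30 dB
  out <- notch_filter(tone_recording(50), spec)
  mid <- out$signals[1, (2 * 128):(8 * 128)]
  expect_lt(20 * log10(rms(mid) / sqrt(0.5)), -30)
  # a 10 Hz tone is preserved within 1 dB
  out10 <- notch_filter(tone_recording(10), spec)
  expect_gt(20 * log10(rms(out10$signals[1, ]) / sqrt(0.5)), -1)
  # zero in, zero out
  z <- eeg_recording(matrix(0, 1, 1280), 128)
  expect_equal(notch_filter(z, spec)$signals, z$signals,
               ignore_attr = TRUE)
  expect_error(notch_filter(tone_recording(10, fs = 90), spec), "Nyquist")
})

test_that("bandpass filter meets its corner specifications", {
  spec <- filter_spec()
  # DC offset removed
  dc <- eeg_recording(matrix(100, 1, 1280), 128)
  expect_lt(abs(mean(bandpass_filter(dc, spec)$signals)), 1)
  # 10 Hz preserved within 3 dB
  out10 <- bandpass_filter(tone_recording(10), spec)
  expect_gt(20 * log10(rms(out10$signals[1, ]) / sqrt(0.5)), -3)
  # 55 Hz attenuated by at least 20 dB
  out55 <- bandpass_filter(tone_recording(55), spec)
  expect_lt(20 * log10(rms(out55$signals[1, ]) / sqrt(0.5)), -20)
  expect_error(
    bandpass_filter(tone_recording(10, fs = 64),
                    filter_spec(bp_high = 40)), "Nyquist")
})

test_that("filtering is channel-wise: permuting channels commutes", {
  rec <- generate_background(synth_config(5, n_channels = 4, seed = 31))
  perm <- c(3, 1, 4, 2)
  a <- bandpass_filter(rec)$signals[perm, ]
  permuted <- eeg_recording(rec$signals[perm, ], rec$fs,
                            rec$channel_names[perm])
  b <- bandpass_filter(permuted)$signals
  expect_equal(a, b, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-phase filtering keeps a symmetric pulse symmetric", {
  n <- 1281
  x <- exp(-((seq_len(n) - 641) / 20)^2)   # symmetric Gaussian pulse
  rec <- eeg_recording(matrix(x, 1), 128)
  y <- bandpass_filter(rec, filter_spec(zero_phase = TRUE))$signals[1, ]
  # mirror symmetry around the centre: asymmetry below 1% of the peak
  # (boundary truncation of the slow highpass tail sets the floor; a causal
  # filter would shift the whole pulse and fail by orders of magnitude)
  asym <- max(abs(y - rev(y))) / max(abs(y))
  expect_lt(asym, 0.01)
  expect_equal(which.max(y), 641L)
  # the causal version distorts: its output is visibly asymmetric
  yc <- bandpass_filter(rec, filter_spec(zero_phase = FALSE))$signals[1, ]
  expect_gt(max(abs(yc - rev(yc))) / max(abs(yc)), 0.1)
})

test_that("ICA with a never-firing rule reconstructs the input", {
  rec <- generate_background(synth_config(20, n_channels = 6, seed = 17))
  out <- remove_artifacts(rec, rule = rejection_rule(Inf, 1.1))
  rel <- max(abs(out$recording$signals - rec$signals)) /
    max(abs(rec$signals))
  expect_lt(rel, 1e-6)
  expect_false(any(out$report$rejected))
})

test_that("ICA rejection removes a high-kurtosis spike-train artifact source", {
  set.seed(5)
  n <- 4000
  s_eeg <- as.numeric(stats::arima.sim(list(ar = c(0.6, -0.2)), n))
  s_alpha <- sin(2 * pi * 6 * (seq_len(n)) / 128)
  s_noise <- stats::rnorm(n)
  s_art <- rep(0, n); s_art[sample.int(n, 30)] <- 40
  S <- rbind(s_eeg, s_alpha, s_noise, s_art)
  A <- matrix(stats::rnorm(16), 4, 4)
  rec <- eeg_recording(A %*% S, 128)
  out <- remove_artifacts(rec, rule = rejection_rule(50, 0.9))
  expect_true(any(out$report$rejected & out$report$rule == "kurtosis"))
  contrib <- A[, 4, drop = FALSE] %*% S[4, , drop = FALSE]
  resid <- out$recording$signals - (A %*% S - contrib)
  reduction <- 1 - sum(resid^2) / sum(contrib^2)
  expect_gt(reduction, 0.8)
})

test_that("ICA preconditions and degenerate inputs error out", {
  one <- eeg_recording(matrix(rnorm(100), 1), 128)
  expect_error(remove_artifacts(one), "2 channels")
  short <- eeg_recording(matrix(rnorm(6), 3, 2), 128)
  expect_error(remove_artifacts(short), "longer")
  # rank-deficient: all channels identical
  x <- rnorm(500)
  dup <- eeg_recording(rbind(x, x, x), 128)
  expect_error(remove_artifacts(dup), "rank-deficient")
})

test_that("artifact rejection is idempotent within tolerance", {
  set.seed(6)
  n <- 3000
  S <- rbind(as.numeric(stats::arima.sim(list(ar = 0.5), n)),
             sin(2 * pi * 9 * seq_len(n) / 128),
             stats::rnorm(n),
             { a <- rep(0, n); a[sample.int(n, 20)] <- 60; a })
  A <- matrix(stats::rnorm(16), 4, 4)
  rec <- eeg_recording(A %*% S, 128)
  once <- remove_artifacts(rec, rule = rejection_rule(50, 0.9))
  twice <- remove_artifacts(once$recording, rule = rejection_rule(50, 0.9))
  scale <- max(abs(once$recording$signals))
  expect_lt(max(abs(twice$recording$signals - once$recording$signals)) /
              scale, 0.05)
})
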