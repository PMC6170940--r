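test_that("segmentation yields floor(samples/N) full windows", {
  g <- segment_grid(1280, 128, 0.5)
  expect_equal(g$n_segments, 20L)
  expect_equal(g$n_per_segment, 64L)
  g2 <- segment_grid(100, 128, 0.5)
  expect_equal(g2$n_segments, 1L)          # 36 trailing samples discarded
  expect_error(segment_grid(63, 128, 0.5), "empty segment grid")
})

test_that("Levinson-Durbin equals the direct Toeplitz solve on random segments", {
  set.seed(101)
  for (trial in 1:200) {
    x <- rnorm(64)
    r <- eegseizer:::autocorr_biased(x, 4)
    fit <- levinson_durbin(r)
    direct <- solve(stats::toeplitz(r[1:4]), r[2:5])
    expect_lt(max(abs(fit$phi - direct)), 1e-10)
    # innovation variance matches r0 - phi . r
    expect_lt(abs(fit$sigma2 - (r[1] - sum(direct * r[2:5]))), 1e-10)
  }
})

test_that("AR spectral peak localizes the known AR(2) pole frequency", {
  set.seed(3)
  fs <- 128
  x <- as.numeric(stats::arima.sim(list(ar = c(1.5, -0.9)), 8192))
  fit <- yule_walker_ar(x, 4)
  g <- eegseizer:::yw_psd_grid(fit$phi, fit$sigma2, fs, 256)
  f_peak <- g$freq[which.max(g$psd)]
  f_true <- acos(1.5 * (1 + 0.9) / (4 * 0.9)) / (2 * pi) * fs
  bin <- (fs / 2) / 255
  expect_lt(abs(f_peak - f_true), 2 * bin)
})

test_that("white-noise spectra are flat: max/median PSD ratio stays small", {
  set.seed(55)
  ratios <- replicate(30, {
    x <- rnorm(4096)
    fit <- yule_walker_ar(x, 4)
    g <- eegseizer:::yw_psd_grid(fit$phi, fit$sigma2, 128, 256)
    max(g$psd) / stats::median(g$psd)
  })
  expect_gte(mean(ratios < 3), 0.95)
})

test_that("degenerate PSD inputs are handled", {
  expect_warning(p <- yule_walker_psd_max(rep(0, 64), fs = 128),
                 "zero-variance")
  expect_equal(p, 0)
  expect_error(yule_walker_psd_max(rnorm(4), fs = 128, order = 4), "longer")
})

test_that("entropies match closed forms", {
  # 64 samples spread evenly over 8 bins -> 3 bits for both entropies
  x <- rep(seq(0.5, 7.5), each = 8) / 8
  expect_equal(shannon_entropy(x, n_bins = 8), 3)
  expect_equal(renyi_entropy(x, alpha = 2, n_bins = 8), 3)
  # constant segment -> 0 bits
  expect_equal(shannon_entropy(rep(2.5, 64)), 0)
  expect_equal(renyi_entropy(rep(2.5, 64)), 0)
  # probabilities (0.5, 0.25, 0.25) -> 1.5 bits (Shannon)
  x2 <- c(rep(0.1, 2), rep(1.1, 1), rep(2.1, 1))
  expect_equal(shannon_entropy(x2, n_bins = 3), 1.5)
  # probabilities (0.8, 0.2) at alpha = 2 -> -log2(0.68)
  x3 <- c(rep(0.1, 8), rep(1.9, 2))
  expect_equal(renyi_entropy(x3, alpha = 2, n_bins = 2), -log2(0.68),
               tolerance = 1e-12)
  expect_error(renyi_entropy(rnorm(10), alpha = 1), "shannon_entropy")
  expect_error(renyi_entropy(rnorm(10), alpha = -1), "alpha")
})

test_that("Renyi entropy tends to Shannon entropy as alpha -> 1", {
  set.seed(12)
  for (trial in 1:20) {
    x <- rnorm(64)
    h <- shannon_entropy(x)
    expect_lt(abs(renyi_entropy(x, alpha = 1 + 1e-4) - h), 1e-3)
    expect_lt(abs(renyi_entropy(x, alpha = 1 - 1e-4) - h), 1e-3)
  }
})

test_that("Renyi order-2 entropy never exceeds Shannon on the same histogram", {
  set.seed(13)
  for (trial in 1:50) {
    x <- rnorm(64)
    expect_lte(renyi_entropy(x, alpha = 2), shannon_entropy(x) + 1e-12)
  }
})

test_that("Teager energy matches its closed form and a loop oracle", {
  expect_equal(teager_energy(rep(3.7, 64)), 0)
  # quarter-period sinusoid: per-term operator value A^2 sin^2(pi/2) = A^2
  A <- 2.5; N <- 4096
  x <- A * cos(pi / 2 * seq_len(N))
  expect_equal(teager_energy(x), A^2 * (N - 2) / (N - 1),
               tolerance = 1e-12)
  # brute-force loop oracle on random segments
  set.seed(77)
  for (trial in 1:20) {
    z <- rnorm(64)
    acc <- 0
    for (n in 2:63) acc <- acc + z[n]^2 - z[n - 1] * z[n + 1]
    expect_equal(teager_energy(z), acc / 63, tolerance = 1e-12)
  }
  expect_error(teager_energy(c(1, 2)), "3 samples")
})

test_that("quadratic features scale as k^2; entropies are affine-invariant", {
  set.seed(14)
  x <- rnorm(64)
  k <- 3.7; b <- 11
  expect_equal(teager_energy(k * x), k^2 * teager_energy(x),
               tolerance = 1e-10)
  expect_equal(yule_walker_psd_max(k * x, fs = 128),
               k^2 * yule_walker_psd_max(x, fs = 128),
               tolerance = 1e-8)
  expect_equal(shannon_entropy(k * x + b), shannon_entropy(x))
  expect_equal(renyi_entropy(k * x + b), renyi_entropy(x))
  expect_equal(shannon_entropy(-k * x + b), shannon_entropy(x))
})

test_that("entropy bounds hold", {
  set.seed(15)
  for (trial in 1:30) {
    x <- rnorm(64)
    h <- shannon_entropy(x, n_bins = 16)
    expect_gte(h, 0)
    expect_lte(h, 4)
    expect_gte(renyi_entropy(x, alpha = 2, n_bins = 16), 0)
  }
})

test_that("extract_features agrees with the scalar feature functions", {
  rec <- small_seizure_recording(seed = 19)
  fm <- extract_features(rec)
  grid <- attr(fm, "grid")
  set.seed(20)
  for (row in sample(nrow(fm), 25)) {
    ch <- fm$channel[row]; si <- fm$segment_index[row]
    seg <- rec$signals[ch, grid$starts[si]:(grid$starts[si] + 63)]
    expect_equal(fm$psd_max[row], yule_walker_psd_max(seg, fs = 128),
                 tolerance = 1e-10)
    expect_equal(fm$shannon_H[row], shannon_entropy(seg),
                 tolerance = 1e-12)
    expect_equal(fm$renyi_H[row], renyi_entropy(seg), tolerance = 1e-12)
    expect_equal(fm$teager[row], teager_energy(seg), tolerance = 1e-12)
  }
})

test_that("feature rows, labels and overlap rule are correct", {
  cfg <- synth_config(10, n_channels = 19, seed = 23)
  rec <- generate_background(cfg)
  fm <- extract_features(rec)
  expect_equal(nrow(fm), 19L * 20L)
  expect_true(all(fm$label == 0L))
  # a seizure covering windows 5..9 labels those rows 1 on every channel
  rec2 <- inject_seizure(rec, onset_s = 2.0, duration_s = 2.5, gain = 5)
  fm2 <- extract_features(rec2)
  lab_by_seg <- tapply(fm2$label, fm2$segment_index, unique)
  expect_true(all(vapply(lab_by_seg, length, 1L) == 1L))
  expect_equal(which(vapply(lab_by_seg, `[`, 1L, 1) == 1L),
               c(`5` = 5L, `6` = 6L, `7` = 7L, `8` = 8L, `9` = 9L))
  g <- segment_grid(1280, 128, 0.5)
  labs <- segment_labels(g, data.frame(onset_s = 2.0, duration_s = 2.5,
                                       label = "epileptic"))
  expect_equal(labs[4], 0L)   # window [1.5, 2.0): zero overlap
  expect_equal(which(labs == 1L), 5:9)
  # exactly half a window overlapping counts as ictal (>= 50% rule)
  labs2 <- segment_labels(g, data.frame(onset_s = 2.25, duration_s = 2.25,
                                        label = "epileptic"))
  expect_equal(labs2[5], 1L)  # window [2.0, 2.5): 0.25 s overlap = 50%
  # just under half does not
  labs3 <- segment_labels(g, data.frame(onset_s = 2.26, duration_s = 2.24,
                                        label = "epileptic"))
  expect_equal(labs3[5], 0L)
})
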