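# shared fixtures, built in code at test time

tone_recording <- function(freq, fs = 128, dur_s = 10, amp = 1,
                           n_channels = 1) {
  t <- (seq_len(dur_s * fs) - 1) / fs
  x <- amp * sin(2 * pi * freq * t)
  eeg_recording(matrix(rep(x, n_channels), nrow = n_channels,
                       byrow = TRUE), fs)
}

band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  sum(p[f >= lo & f <= hi])
}

rms <- function(x) sqrt(mean(x^2))

# small seeded seizure fixture shared across files
small_seizure_recording <- function(seed = 11, gain = 5) {
  cfg <- synth_config(duration_s = 60, n_channels = 4, seed = seed,
                      seizure_events = data.frame(
                        onset_s = c(15, 40), duration_s = c(6, 8),
                        spike_rate = 3, gain = gain))
  simulate_recording(cfg)
}
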