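#' Standard 10-20 scalp montage (19 channels)
#'
#' Electrode labels of the international 10-20 placement used as the default
#' channel set for simulated recordings.
#'
#' @return Character vector of 19 electrode names.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Configuration for the synthetic EEG generator
#'
#' Describes a simulated scalp recording: a pink-noise (1/f) background with
#' a per-channel alpha rhythm, optional 3 Hz spike-and-slow-wave seizures,
#' power-line interference and low-frequency motion artifacts.
#'
#' @param duration_s Total length in seconds.
#' @param fs Sampling rate in Hz (default 128).
#' @param n_channels Number of channels (default 19, the 10-20 montage).
#' @param background_amp Background RMS amplitude in µV (default 20).
#' @param alpha_band Two-element Hz range for the alpha rhythm (default 8-12).
#' @param alpha_amp Peak amplitude of the alpha sinusoid in µV
#'   (default `0.7 * background_amp`).
#' @param seizure_events `NULL` or a data frame with columns `onset_s`,
#'   `duration_s` and optionally `spike_rate` (Hz, default 3) and `gain`
#'   (>= 1, default 5). `gain` scales the ictal peak relative to the local
#'   background RMS; `gain = 1` adds nothing.
#' @param line_freq Power-line frequency in Hz (default 50).
#' @param line_amp Line interference amplitude in µV (default 0 = off).
#' @param artifact_events `NULL` or a data frame with columns `onset_s`,
#'   `duration_s`, `amplitude` (µV) and optionally `n_affected` (channels,
#'   default 3).
#' @param focal_channels `NULL` to inject seizures on all channels
#'   simultaneously (generalized-seizure model, the default), or an integer
#'   vector of channel indices for focal injection.
#' @param seed Integer seed; identical configurations give bit-identical
#'   recordings.
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(duration_s, fs = 128, n_channels = 19,
                         background_amp = 20, alpha_band = c(8, 12),
                         alpha_amp = 0.7 * background_amp,
                         seizure_events = NULL,
                         line_freq = 50, line_amp = 0,
                         artifact_events = NULL,
                         focal_channels = NULL, seed = 1L) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("invalid synth config: duration_s must be positive")
  if (!is.numeric(fs) || fs <= 0)
    stop("invalid synth config: fs must be positive")
  if (length(alpha_band) != 2L || alpha_band[1] >= alpha_band[2])
    stop("invalid synth config: alpha_band must be an increasing Hz pair")
  if (fs <= 2 * alpha_band[2])
    stop("invalid synth config: fs must exceed twice the alpha upper edge")
  if (n_channels < 1) stop("invalid synth config: n_channels must be >= 1")
  if (background_amp < 0 || alpha_amp < 0 || line_amp < 0)
    stop("invalid synth config: amplitudes must be >= 0")
  sz <- NULL
  if (!is.null(seizure_events) && nrow(as.data.frame(seizure_events)) > 0) {
    sz <- as.data.frame(seizure_events)
    if (!all(c("onset_s", "duration_s") %in% names(sz)))
      stop("seizure_events needs onset_s and duration_s columns")
    if (is.null(sz$spike_rate)) sz$spike_rate <- 3
    if (is.null(sz$gain)) sz$gain <- 5
    if (any(sz$onset_s < 0) ||
        any(sz$onset_s + sz$duration_s > duration_s + 1e-9))
      stop("invalid synth config: seizure events must lie inside the record")
    if (any(sz$gain < 1))
      stop("invalid synth config: seizure gain must be >= 1")
  }
  af <- NULL
  if (!is.null(artifact_events) && nrow(as.data.frame(artifact_events)) > 0) {
    af <- as.data.frame(artifact_events)
    if (!all(c("onset_s", "duration_s", "amplitude") %in% names(af)))
      stop("artifact_events needs onset_s, duration_s, amplitude columns")
    if (is.null(af$n_affected)) af$n_affected <- 3L
    if (any(af$onset_s < 0) ||
        any(af$onset_s + af$duration_s > duration_s + 1e-9))
      stop("invalid synth config: artifact events must lie inside the record")
    if (any(af$amplitude < 0))
      stop("invalid synth config: artifact amplitude must be >= 0")
  }
  structure(list(
    duration_s = duration_s, fs = fs, n_channels = as.integer(n_channels),
    background_amp = background_amp, alpha_band = alpha_band,
    alpha_amp = alpha_amp, seizure_events = sz,
    line_freq = line_freq, line_amp = line_amp, artifact_events = af,
    focal_channels = focal_channels, seed = as.integer(seed)
  ), class = "synth_config")
}

# One global seed fans out to independent per-channel / per-purpose streams,
# so changing the channel count never reshuffles earlier channels.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 1009 * as.double(stream)) %%
               2147483647)
}

# Pink (1/f power) noise of length n with unit RMS, via spectral shaping.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  k <- seq_len(n) - 1L
  k <- pmin(k, n - k)                 # two-sided frequency index
  amp <- ifelse(k == 0, 0, 1 / sqrt(k))
  x <- Re(stats::fft(sp * amp, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate background EEG
#'
#' Pink-noise (spectral power slope -1) background scaled to
#' `background_amp` RMS, plus one alpha-band sinusoid per channel with a
#' seeded random frequency (uniform in `alpha_band`) and phase. Annotations
#' are empty.
#'
#' @param config A [synth_config()].
#' @return An [eeg_recording()] with `n_channels x duration_s*fs` samples.
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- as.integer(round(config$duration_s * config$fs))
  sig <- matrix(0, config$n_channels, n)
  t <- (seq_len(n) - 1L) / config$fs
  for (ch in seq_len(config$n_channels)) {
    set.seed(derive_seed(config$seed, ch))
    x <- pink_noise(n) * config$background_amp
    f_alpha <- stats::runif(1, config$alpha_band[1], config$alpha_band[2])
    phase <- stats::runif(1, 0, 2 * pi)
    sig[ch, ] <- x + config$alpha_amp * sin(2 * pi * f_alpha * t + phase)
  }
  names_ <- if (config$n_channels == 19L) default_montage() else
    paste0("CH", seq_len(config$n_channels))
  eeg_recording(sig, fs = config$fs, channel_names = names_)
}

# One spike-and-slow-wave cycle, peak-normalised to 1: a sharp biphasic
# spike (~70 ms) followed by a half-sine slow wave filling the period.
spike_wave_unit <- function(fs, spike_rate) {
  period <- as.integer(round(fs / spike_rate))
  spike_len <- max(4L, as.integer(round(0.07 * fs)))
  spike_len <- min(spike_len, period - 2L)
  n_pos <- as.integer(ceiling(spike_len * 0.6))
  n_neg <- spike_len - n_pos
  spike <- c(sin(pi * seq_len(n_pos) / (n_pos + 1)),
             -0.5 * sin(pi * seq_len(n_neg) / (n_neg + 1)))
  slow_len <- period - spike_len
  slow <- 0.6 * sin(pi * seq_len(slow_len) / (slow_len + 1))
  unit <- c(spike, slow)
  unit / max(abs(unit))
}

#' Inject a spike-and-slow-wave seizure
#'
#' Within the event window a spike-and-slow-wave train at `spike_rate` is
#' added, scaled so the ictal peak equals `(gain - 1)` times the per-channel
#' background RMS inside the window (so `gain = 1` leaves the signal
#' untouched and larger gains scale the discharge up). A ramp of half a
#' cycle at each edge avoids step discontinuities. One annotation with the
#' exact onset/offset and label `"epileptic"` is appended.
#'
#' @param recording An [eeg_recording()].
#' @param onset_s,duration_s Event window in seconds.
#' @param spike_rate Spike-wave repetition rate in Hz (default 3).
#' @param gain Amplitude factor >= 1 relative to background RMS (default 5).
#' @param channels Channel indices to inject on; `NULL` = all channels
#'   (generalized-seizure model).
#' @return The modified [eeg_recording()].
#' @export
inject_seizure <- function(recording, onset_s, duration_s, spike_rate = 3,
                           gain = 5, channels = NULL) {
  fs <- recording$fs
  n <- ncol(recording$signals)
  i0 <- as.integer(round(onset_s * fs)) + 1L
  i1 <- as.integer(round((onset_s + duration_s) * fs))
  if (onset_s < 0 || i1 > n)
    stop("seizure window lies outside the recording")
  if (gain < 1) stop("seizure gain must be >= 1")
  if (is.null(channels)) channels <- seq_len(nrow(recording$signals))
  len <- i1 - i0 + 1L
  unit <- spike_wave_unit(fs, spike_rate)
  train <- rep_len(unit, len)
  ramp_n <- min(length(unit), floor(len / 2))
  if (ramp_n > 0) {
    ramp <- seq(0, 1, length.out = ramp_n)
    train[seq_len(ramp_n)] <- train[seq_len(ramp_n)] * ramp
    train[(len - ramp_n + 1L):len] <- train[(len - ramp_n + 1L):len] *
      rev(ramp)
  }
  for (ch in channels) {
    rms <- sqrt(mean(recording$signals[ch, i0:i1]^2))
    recording$signals[ch, i0:i1] <- recording$signals[ch, i0:i1] +
      (gain - 1) * rms * train
  }
  ann <- rbind(recording$annotations,
               data.frame(onset_s = onset_s, duration_s = duration_s,
                          label = "epileptic", stringsAsFactors = FALSE))
  recording$annotations <- merge_annotations(ann)
  recording
}

#' Inject power-line interference
#'
#' Adds a common-mode pure sinusoid at `line_freq` to every channel.
#'
#' @param recording An [eeg_recording()].
#' @param line_freq Line frequency in Hz (default 50).
#' @param line_amp Amplitude in µV; 0 returns the input unchanged.
#' @param phase Phase in radians (default 0).
#' @return The modified [eeg_recording()].
#' @export
inject_line_noise <- function(recording, line_freq = 50, line_amp,
                              phase = 0) {
  if (line_amp < 0) stop("line_amp must be >= 0")
  if (line_amp == 0) return(recording)
  t <- (seq_len(ncol(recording$signals)) - 1L) / recording$fs
  tone <- line_amp * sin(2 * pi * line_freq * t + phase)
  recording$signals <- sweep(recording$signals, 2, tone, "+")
  recording
}

#' Inject a motion artifact
#'
#' Adds a low-frequency (~0.7 Hz), high-amplitude Hann-windowed transient to
#' a seeded random subset of channels, mimicking electrode/cable movement.
#'
#' @param recording An [eeg_recording()].
#' @param onset_s,duration_s Artifact window in seconds.
#' @param amplitude Peak amplitude in µV.
#' @param n_affected Number of affected channels (default 3).
#' @param seed Integer seed for the channel draw.
#' @return The modified [eeg_recording()] with an `"artifact"` annotation.
#' @export
inject_motion_artifact <- function(recording, onset_s, duration_s, amplitude,
                                   n_affected = 3L, seed = 1L) {
  fs <- recording$fs
  n <- ncol(recording$signals)
  i0 <- as.integer(round(onset_s * fs)) + 1L
  i1 <- as.integer(round((onset_s + duration_s) * fs))
  if (onset_s < 0 || i1 > n)
    stop("artifact window lies outside the recording")
  if (amplitude < 0) stop("artifact amplitude must be >= 0")
  n_ch <- nrow(recording$signals)
  set.seed(derive_seed(seed, 104729L))
  chans <- sample.int(n_ch, min(n_affected, n_ch))
  len <- i1 - i0 + 1L
  t <- (seq_len(len) - 1L) / fs
  hann <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = len)))
  wav <- amplitude * hann * sin(2 * pi * 0.7 * t)
  for (ch in chans) {
    recording$signals[ch, i0:i1] <- recording$signals[ch, i0:i1] + wav
  }
  ann <- rbind(recording$annotations,
               data.frame(onset_s = onset_s, duration_s = duration_s,
                          label = "artifact", stringsAsFactors = FALSE))
  recording$annotations <- merge_annotations(ann)
  attr(recording, "last_artifact_channels") <- chans
  recording
}

#' Simulate a complete annotated recording
#'
#' Runs the generator end to end: background, then every configured seizure,
#' line interference and motion artifact, in that order. Identical configs
#' (including seed) give bit-identical output.
#'
#' @param config A [synth_config()].
#' @return An annotated [eeg_recording()].
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  rec <- generate_background(config)
  if (!is.null(config$seizure_events)) {
    for (i in seq_len(nrow(config$seizure_events))) {
      ev <- config$seizure_events[i, ]
      rec <- inject_seizure(rec, ev$onset_s, ev$duration_s,
                            spike_rate = ev$spike_rate, gain = ev$gain,
                            channels = config$focal_channels)
    }
  }
  if (config$line_amp > 0) {
    set.seed(derive_seed(config$seed, 7L))
    rec <- inject_line_noise(rec, config$line_freq, config$line_amp,
                             phase = stats::runif(1, 0, 2 * pi))
  }
  if (!is.null(config$artifact_events)) {
    for (i in seq_len(nrow(config$artifact_events))) {
      ev <- config$artifact_events[i, ]
      rec <- inject_motion_artifact(rec, ev$onset_s, ev$duration_s,
                                    ev$amplitude, ev$n_affected,
                                    seed = derive_seed(config$seed, 100L + i))
    }
  }
  rec
}

#' Default synthetic study fixture
#'
#' The reference simulation used by the package's worked examples: a 20-min,
#' 19-channel, 128 Hz recording with ten generalized 3 Hz spike-and-wave
#' seizures (gain 5, 10-25 s long, evenly spaced onset slots with seeded
#' jitter), 50 Hz line interference and five short motion artifacts.
#'
#' @param seed Integer seed.
#' @param duration_s Total length in seconds (default 1200).
#' @param n_seizures Number of injected seizures (default 10).
#' @param gain Seizure amplitude gain (default 5).
#' @param n_channels Channels (default 19).
#' @return A [synth_config()].
#' @export
default_study_config <- function(seed = 1L, duration_s = 1200,
                                 n_seizures = 10, gain = 5,
                                 n_channels = 19) {
  set.seed(derive_seed(seed, 999L))
  if (n_seizures > 0) {
    slot <- duration_s / n_seizures
    durs <- stats::runif(n_seizures, 10, 25)
    onsets <- (seq_len(n_seizures) - 1) * slot +
      stats::runif(n_seizures, 5, pmax(5.5, slot - durs - 5))
    sz <- data.frame(onset_s = onsets, duration_s = durs,
                     spike_rate = 3, gain = gain)
  } else {
    sz <- NULL
  }
  n_art <- 5L
  art_on <- stats::runif(n_art, 0, duration_s - 3)
  # keep artifacts clear of seizures so event labels stay unambiguous
  if (is.null(sz)) sz <- data.frame(onset_s = numeric(0),
                                    duration_s = numeric(0))
  for (k in seq_len(n_art)) {
    bad <- any(art_on[k] + 2.5 > sz$onset_s - 2 &
                 art_on[k] < sz$onset_s + sz$duration_s + 2)
    tries <- 0L
    while (bad && tries < 50L) {
      art_on[k] <- stats::runif(1, 0, duration_s - 3)
      bad <- any(art_on[k] + 2.5 > sz$onset_s - 2 &
                   art_on[k] < sz$onset_s + sz$duration_s + 2)
      tries <- tries + 1L
    }
  }
  af <- data.frame(onset_s = art_on, duration_s = 2.5, amplitude = 150,
                   n_affected = 3L)
  synth_config(duration_s = duration_s, fs = 128, n_channels = n_channels,
               background_amp = 20, seizure_events = sz,
               line_freq = 50, line_amp = 15, artifact_events = af,
               seed = seed)
}
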