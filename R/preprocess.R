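#' Filter specification for EEG preprocessing
#'
#' Parameters of the two-stage cleaning filter: a second-order IIR notch at
#' the power-line frequency and an order-5 elliptic bandpass restricting
#' the record to the clinically relevant 0.5-40 Hz range.
#'
#' @param notch_freq Notch centre frequency in Hz (default 50).
#' @param notch_q Notch quality factor; 35 gives a -3 dB width of about
#'   1.4 Hz at 50 Hz.
#' @param bp_low,bp_high Bandpass corner frequencies in Hz (defaults 0.5
#'   and 40).
#' @param bp_order Elliptic prototype order of each bandpass half (default
#'   5); the band limits are realised as an order-`bp_order` highpass
#'   cascaded with an order-`bp_order` lowpass for numerical robustness at
#'   the very low lower edge.
#' @param passband_ripple Passband ripple in dB (default 3).
#' @param stopband_atten Stopband attenuation in dB (default 40).
#' @param zero_phase Apply each filter forward and backward (default TRUE),
#'   doubling the effective attenuation but removing phase distortion that
#'   would shift spike timing.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(notch_freq = 50, notch_q = 35,
                        bp_low = 0.5, bp_high = 40, bp_order = 5,
                        passband_ripple = 3, stopband_atten = 40,
                        zero_phase = TRUE) {
  if (bp_low <= 0 || bp_low >= bp_high)
    stop("invalid filter spec: need 0 < bp_low < bp_high")
  if (bp_order < 1 || notch_q <= 0)
    stop("invalid filter spec: orders and Q must be positive")
  if (passband_ripple <= 0 || stopband_atten <= 0)
    stop("invalid filter spec: ripple/attenuation must be positive")
  structure(list(notch_freq = notch_freq, notch_q = notch_q,
                 bp_low = bp_low, bp_high = bp_high, bp_order = bp_order,
                 passband_ripple = passband_ripple,
                 stopband_atten = stopband_atten, zero_phase = zero_phase),
            class = "filter_spec")
}

# length of the impulse response, to size the reflection padding
impulse_length <- function(b, a, cap = 4096L) {
  h <- as.numeric(signal::filter(b, a, c(1, rep(0, cap - 1L))))
  th <- 1e-6 * max(abs(h))
  idx <- which(abs(h) > th)
  if (length(idx) == 0L) 1L else max(idx)
}

# channel-wise IIR filtering with odd reflection padding (3x the impulse
# response length); forward-backward when zero_phase
apply_iir <- function(signals, b, a, zero_phase = TRUE) {
  n <- ncol(signals)
  pad <- min(n - 1L, 3L * impulse_length(b, a))
  run <- function(x) {
    left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
    right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    y <- as.numeric(signal::filter(b, a, c(left, x, right)))
    if (zero_phase) {
      y <- rev(as.numeric(signal::filter(b, a, rev(y))))
    }
    y[(pad + 1L):(pad + n)]
  }
  t(apply(signals, 1, run))
}

# RBJ-style second-order IIR notch biquad
notch_coefficients <- function(freq, fs, q) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Notch-filter a recording
#'
#' Second-order IIR notch removing the power-line component; DC and
#' frequencies away from the notch are preserved within a fraction of a dB.
#'
#' @param recording An [eeg_recording()].
#' @param spec A [filter_spec()].
#' @return The filtered [eeg_recording()].
#' @export
notch_filter <- function(recording, spec = filter_spec()) {
  if (spec$notch_freq >= recording$fs / 2)
    stop("invalid filter spec: notch frequency at or above Nyquist")
  co <- notch_coefficients(spec$notch_freq, recording$fs, spec$notch_q)
  recording$signals <- apply_iir(recording$signals, co$b, co$a,
                                 spec$zero_phase)
  rownames(recording$signals) <- recording$channel_names
  recording
}

#' Bandpass-filter a recording
#'
#' Elliptic IIR design meeting the configured passband ripple and stopband
#' attenuation, realised as an order-`bp_order` highpass at `bp_low`
#' cascaded with an order-`bp_order` lowpass at `bp_high`.
#'
#' @param recording An [eeg_recording()].
#' @param spec A [filter_spec()].
#' @return The filtered [eeg_recording()].
#' @export
bandpass_filter <- function(recording, spec = filter_spec()) {
  nyq <- recording$fs / 2
  if (spec$bp_high >= nyq)
    stop("invalid filter spec: bp_high at or above Nyquist")
  hp <- signal::ellip(spec$bp_order, spec$passband_ripple,
                      spec$stopband_atten, spec$bp_low / nyq,
                      type = "high")
  lp <- signal::ellip(spec$bp_order, spec$passband_ripple,
                      spec$stopband_atten, spec$bp_high / nyq,
                      type = "low")
  x <- apply_iir(recording$signals, hp$b, hp$a, spec$zero_phase)
  x <- apply_iir(x, lp$b, lp$a, spec$zero_phase)
  recording$signals <- x
  rownames(recording$signals) <- recording$channel_names
  recording
}

# ---------------------------------------------------------------------------
# ICA-based artifact rejection. The unmixing backend is pluggable; the
# default is a deterministic symmetric fixed-point ICA (tanh contrast) on
# whitened data, estimated on a subsample for speed and applied to the full
# record.
# ---------------------------------------------------------------------------

#' Default ICA backend: symmetric fixed-point ICA
#'
#' Centers and whitens the data (PCA, dropping near-null eigendirections),
#' then runs a symmetric fixed-point iteration with the tanh contrast from
#' a deterministic seeded start. Returns sources plus exact mixing/unmixing
#' maps so that `mixing %*% sources + center` reconstructs the input up to
#' the discarded null space.
#'
#' @param x Channels x samples numeric matrix.
#' @param max_iter Maximum fixed-point iterations (default 200).
#' @param tol Convergence tolerance on the unmixing rotation (default 1e-6).
#' @param max_cols Subsample size (columns) used to estimate the rotation
#'   (default 20000); sources are computed on the full data.
#' @param seed Seed for the initial rotation (default 42).
#' @return List with `sources` (k x samples), `mixing` (channels x k),
#'   `unmixing` (k x channels), `center` (channel means).
#' @export
fastica_backend <- function(x, max_iter = 200L, tol = 1e-6,
                            max_cols = 20000L, seed = 42L) {
  n_ch <- nrow(x); n <- ncol(x)
  if (n_ch < 2L) stop("ICA decomposition needs at least 2 channels")
  if (n <= n_ch) stop("ICA decomposition needs more samples than channels")
  center <- rowMeans(x)
  xc <- x - center
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  k <- sum(keep)
  if (k < 2L)
    stop(paste("rank-deficient data: fewer than two independent directions;",
               "drop duplicate or constant channels"))
  E <- eg$vectors[, keep, drop = FALSE]
  d <- eg$values[keep]
  K <- diag(1 / sqrt(d), k) %*% t(E)          # whitening: k x channels
  cols <- if (n > max_cols)
    as.integer(round(seq(1, n, length.out = max_cols))) else seq_len(n)
  z <- K %*% xc[, cols, drop = FALSE]
  m <- ncol(z)

  sym_decorrelate <- function(w) {
    s <- eigen(tcrossprod(w), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-300)), k) %*%
      t(s$vectors) %*% w
  }
  set.seed(seed)
  w <- sym_decorrelate(matrix(stats::rnorm(k * k), k, k))
  for (it in seq_len(max_iter)) {
    y <- w %*% z
    g <- tanh(y)
    w1 <- (g %*% t(z)) / m - diag(rowMeans(1 - g^2), k) %*% w
    w1 <- sym_decorrelate(w1)
    conv <- max(abs(1 - abs(rowSums(w1 * w))))
    w <- w1
    if (conv < tol) break
  }
  unmixing <- w %*% K                          # k x channels
  mixing <- E %*% diag(sqrt(d), k) %*% t(w)    # channels x k
  list(sources = unmixing %*% xc, mixing = mixing, unmixing = unmixing,
       center = center)
}

#' Component rejection rule
#'
#' A component is rejected when its absolute excess kurtosis exceeds
#' `kurtosis_threshold` (sparse transients such as electrode pops) or when
#' more than `lowfreq_fraction` of its power lies below `lowfreq_hz`
#' (slow movement/sweat drifts).
#'
#' @param kurtosis_threshold Absolute excess-kurtosis cutoff (default 50).
#' @param lowfreq_fraction Maximum tolerated low-frequency power fraction
#'   (default 0.5).
#' @param lowfreq_hz Low-frequency band edge in Hz (default 1).
#' @return A `rejection_rule` list.
#' @export
rejection_rule <- function(kurtosis_threshold = 50, lowfreq_fraction = 0.5,
                           lowfreq_hz = 1) {
  structure(list(kurtosis_threshold = kurtosis_threshold,
                 lowfreq_fraction = lowfreq_fraction,
                 lowfreq_hz = lowfreq_hz),
            class = "rejection_rule")
}

excess_kurtosis <- function(x) {
  x <- x - mean(x)
  s2 <- mean(x^2)
  if (s2 <= 0) return(0)
  mean(x^4) / s2^2 - 3
}

lowfreq_power_fraction <- function(x, fs, edge_hz) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  half <- p[2:(floor(n / 2) + 1L)]
  f <- (seq_along(half)) * fs / n
  tot <- sum(half)
  if (tot <= 0) return(0)
  sum(half[f <= edge_hz]) / tot
}

#' Remove artifacts via ICA component rejection
#'
#' Decomposes the recording into independent components using the supplied
#' backend, zeroes the components matched by the rejection rule and
#' reconstructs the channels.
#'
#' @param recording An [eeg_recording()] with >= 2 channels.
#' @param backend Decomposition function with the contract of
#'   [fastica_backend()].
#' @param rule A [rejection_rule()].
#' @return List with `recording` (cleaned) and `report`, a data frame of
#'   per-component kurtosis, low-frequency power fraction, rejection flag
#'   and the rule that fired.
#' @export
remove_artifacts <- function(recording, backend = fastica_backend,
                             rule = rejection_rule()) {
  if (nrow(recording$signals) < 2L)
    stop("ICA decomposition needs at least 2 channels")
  if (ncol(recording$signals) <= nrow(recording$signals))
    stop("recording must be longer than its channel count")
  dec <- backend(recording$signals)
  k <- nrow(dec$sources)
  kurt <- apply(dec$sources, 1, excess_kurtosis)
  lff <- apply(dec$sources, 1, lowfreq_power_fraction, fs = recording$fs,
               edge_hz = rule$lowfreq_hz)
  by_kurt <- abs(kurt) > rule$kurtosis_threshold
  by_lf <- lff > rule$lowfreq_fraction
  rejected <- by_kurt | by_lf
  fired <- ifelse(by_kurt & by_lf, "kurtosis+lowfreq",
                  ifelse(by_kurt, "kurtosis",
                         ifelse(by_lf, "lowfreq", "")))
  keep <- which(!rejected)
  clean <- dec$mixing[, keep, drop = FALSE] %*%
    dec$sources[keep, , drop = FALSE] + dec$center
  rownames(clean) <- recording$channel_names
  recording$signals <- clean
  list(recording = recording,
       report = data.frame(component = seq_len(k), kurtosis = kurt,
                           lowfreq_fraction = lff, rejected = rejected,
                           rule = fired, stringsAsFactors = FALSE))
}

#' Run the full preprocessing chain
#'
#' Notch filter, bandpass filter, then (optionally) ICA artifact rejection,
#' in that order.
#'
#' @param recording An [eeg_recording()].
#' @param spec A [filter_spec()].
#' @param ica Apply ICA artifact rejection (default TRUE).
#' @param rule A [rejection_rule()].
#' @param backend ICA backend (default [fastica_backend()]).
#' @return List with `recording` and the ICA `report` (`NULL` when
#'   `ica = FALSE`).
#' @export
preprocess_recording <- function(recording, spec = filter_spec(),
                                 ica = TRUE, rule = rejection_rule(),
                                 backend = fastica_backend) {
  rec <- notch_filter(recording, spec)
  rec <- bandpass_filter(rec, spec)
  if (!ica) return(list(recording = rec, report = NULL))
  remove_artifacts(rec, backend = backend, rule = rule)
}
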