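#' Non-overlapping segmentation grid
#'
#' Splits a recording into fixed-length windows (default 0.5 s, i.e. 64
#' samples at 128 Hz). The trailing partial window is discarded.
#'
#' @param n_samples Number of samples per channel.
#' @param fs Sampling rate in Hz.
#' @param win_s Window length in seconds (default 0.5).
#' @return A `segment_grid` list with fields `n_per_segment`, `n_segments`,
#'   `starts` (1-based sample index of each window), `t_start_s`, `win_s`,
#'   `fs`.
#' @export
segment_grid <- function(n_samples, fs, win_s = 0.5) {
  n_per <- as.integer(round(win_s * fs))
  if (n_per < 4L)
    stop("window too short: need at least 4 samples per segment")
  n_seg <- n_samples %/% n_per
  if (n_seg < 1L)
    stop("empty segment grid: recording shorter than one window")
  starts <- (seq_len(n_seg) - 1L) * n_per + 1L
  structure(list(n_per_segment = n_per, n_segments = n_seg, starts = starts,
                 t_start_s = (starts - 1L) / fs, win_s = win_s, fs = fs),
            class = "segment_grid")
}

# channel vector -> n_per x n_segments matrix of windows
segment_matrix <- function(x, grid) {
  used <- grid$n_per_segment * grid$n_segments
  matrix(x[seq_len(used)], nrow = grid$n_per_segment)
}

#' Levinson-Durbin recursion
#'
#' Solves the Yule-Walker (Toeplitz) normal equations for the
#' autoregressive predictor coefficients from autocorrelation lags.
#'
#' @param r Autocorrelation values at lags `0..p` (length `p + 1`).
#' @return List with `phi` (predictor coefficients, model
#'   `x_n = sum(phi_k x_{n-k}) + e_n`), `sigma2` (innovation variance) and
#'   `reflection` (reflection coefficients).
#' @export
levinson_durbin <- function(r) {
  p <- length(r) - 1L
  if (p < 1L) stop("need at least lags 0 and 1")
  if (r[1] <= .Machine$double.eps)
    return(list(phi = rep(0, p), sigma2 = 0, reflection = rep(0, p)))
  phi <- numeric(p); refl <- numeric(p)
  e <- r[1]
  for (m in seq_len(p)) {
    acc <- if (m > 1L) sum(phi[1:(m - 1L)] * r[m:2]) else 0
    k <- (r[m + 1L] - acc) / e
    refl[m] <- k
    if (m > 1L) {
      old <- phi[1:(m - 1L)]
      phi[1:(m - 1L)] <- old - k * rev(old)
    }
    phi[m] <- k
    e <- e * (1 - k^2)
    if (e <= 0) { e <- 0; break }
  }
  list(phi = phi, sigma2 = e, reflection = refl)
}

# biased autocorrelation (divide by N): positive semi-definite by
# construction, which keeps the Yule-Walker system solvable
autocorr_biased <- function(x, max_lag) {
  n <- length(x)
  vapply(0:max_lag, function(k)
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / n, 0)
}

#' Fit an autoregressive model by the Yule-Walker method
#'
#' @param x Numeric segment.
#' @param order AR model order (default 4).
#' @return List with `phi`, `sigma2` (see [levinson_durbin()]).
#' @export
yule_walker_ar <- function(x, order = 4) {
  if (length(x) <= order)
    stop("segment must be longer than the AR order")
  levinson_durbin(autocorr_biased(x, order))
}

#' Maximum of the Yule-Walker AR power spectral density
#'
#' Fits an AR(`order`) model by the Yule-Walker equations (biased
#' autocorrelation, Levinson-Durbin solve) and evaluates the one-sided PSD
#' `sigma2 / (fs |A(e^{i omega})|^2)` on a uniform grid of `n_freq` points
#' over `[0, fs/2]`, returning the grid maximum.
#'
#' @param x Numeric segment (length > `order`).
#' @param fs Sampling rate in Hz.
#' @param order AR order (default 4).
#' @param n_freq Number of frequency grid points (default 256).
#' @return Maximum PSD value (power per Hz). A zero-variance segment gives 0
#'   with a warning.
#' @export
yule_walker_psd_max <- function(x, fs, order = 4, n_freq = 256) {
  fit <- yule_walker_ar(x, order)
  if (fit$sigma2 <= 0 && all(fit$phi == 0)) {
    warning("zero-variance segment: flat zero spectrum")
    return(0)
  }
  max(yw_psd_grid(fit$phi, fit$sigma2, fs, n_freq)$psd)
}

# PSD on the one-sided grid for a fitted AR model
yw_psd_grid <- function(phi, sigma2, fs, n_freq) {
  f <- seq(0, fs / 2, length.out = n_freq)
  omega <- 2 * pi * f / fs
  p <- length(phi)
  k <- seq_len(p)
  re <- 1 - vapply(omega, function(w) sum(phi * cos(w * k)), 0)
  im <- vapply(omega, function(w) sum(phi * sin(w * k)), 0)
  scale <- c(1, rep(2, max(0, n_freq - 2L)), 1) / fs
  list(freq = f, psd = sigma2 * scale / (re^2 + im^2))
}

# histogram bin probabilities over the per-segment [min, max] range
hist_probs <- function(x, n_bins) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("segment contains non-finite values")
  if (rng[2] - rng[1] <= 0) return(1)
  idx <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  counts[counts > 0] / length(x)
}

#' Shannon entropy of a segment (histogram method)
#'
#' Bin probabilities come from a uniform-width histogram over the segment's
#' own `[min, max]` range; empty bins contribute zero
#' (`0 log 0 := 0`). A constant segment has zero entropy.
#'
#' @param x Numeric segment.
#' @param n_bins Number of histogram bins (default 16).
#' @return Entropy in bits, in `[0, log2(n_bins)]`.
#' @export
shannon_entropy <- function(x, n_bins = 16) {
  if (length(x) < 1L) stop("segment is empty")
  if (n_bins < 1L) stop("n_bins must be >= 1")
  p <- hist_probs(x, n_bins)
  -sum(p * log2(p))
}

#' Renyi entropy of a segment (histogram method)
#'
#' Order-`alpha` generalisation of Shannon entropy,
#' `E = log2(sum(p_i^alpha)) / (1 - alpha)`; the order-2 ("quadratic")
#' entropy used throughout this package is `-log2(sum(p_i^2))`.
#'
#' @param x Numeric segment.
#' @param alpha Entropy order, `alpha >= 0`, `alpha != 1` (default 2). As
#'   `alpha -> 1` the value tends to the Shannon entropy; request that
#'   limit via [shannon_entropy()].
#' @param n_bins Number of histogram bins (default 16).
#' @return Entropy in bits.
#' @export
renyi_entropy <- function(x, alpha = 2, n_bins = 16) {
  if (length(x) < 1L) stop("segment is empty")
  if (n_bins < 1L) stop("n_bins must be >= 1")
  if (!is.numeric(alpha) || alpha < 0)
    stop("alpha must be >= 0")
  if (alpha == 1)
    stop("alpha = 1 is the Shannon limit; call shannon_entropy() instead")
  p <- hist_probs(x, n_bins)
  log2(sum(p^alpha)) / (1 - alpha)
}

#' Averaged Teager energy of a segment
#'
#' The discrete Teager energy operator `x_n^2 - x_{n-1} x_{n+1}` summed over
#' the interior samples `n = 2 .. N-1` and normalised by `N - 1`. The
#' operator responds to both amplitude and instantaneous frequency; for a
#' sinusoid `A cos(Omega n)` each interior term equals
#' `A^2 sin^2(Omega)`.
#'
#' @param x Numeric segment, length >= 3.
#' @return Averaged Teager energy (amplitude-squared units).
#' @export
teager_energy <- function(x) {
  n <- length(x)
  if (n < 3L) stop("Teager energy needs at least 3 samples")
  i <- 2:(n - 1L)
  sum(x[i]^2 - x[i - 1L] * x[i + 1L]) / (n - 1L)
}

# ---------------------------------------------------------------------------
# batched per-segment extraction (same definitions as the scalar functions,
# vectorised across the windows of one channel)
# ---------------------------------------------------------------------------

batch_teager <- function(segs) {
  n <- nrow(segs)
  i <- 2:(n - 1L)
  colSums(segs[i, , drop = FALSE]^2 -
            segs[i - 1L, , drop = FALSE] * segs[i + 1L, , drop = FALSE]) /
    (n - 1L)
}

batch_entropies <- function(segs, n_bins, alpha) {
  n <- nrow(segs); m <- ncol(segs)
  mn <- apply(segs, 2, min)
  rng <- apply(segs, 2, max) - mn
  flat <- rng <= 0
  rng[flat] <- 1
  idx <- pmin(floor(sweep(sweep(segs, 2, mn), 2, rng, "/") * n_bins) + 1L,
              n_bins)
  idx[, flat] <- 1L
  flatidx <- idx + matrix((seq_len(m) - 1L) * n_bins, n, m, byrow = TRUE)
  counts <- matrix(tabulate(flatidx, nbins = n_bins * m), n_bins, m)
  p <- counts / n
  plogp <- p * log2(p)
  plogp[counts == 0] <- 0
  list(shannon = -colSums(plogp),
       renyi = log2(colSums(p^alpha)) / (1 - alpha))
}

batch_levinson <- function(r) {
  # r: (p+1) x m matrix of autocorrelation lags; vectorised recursion
  p <- nrow(r) - 1L; m <- ncol(r)
  phi <- matrix(0, p, m)
  e <- r[1, ]
  ok <- e > .Machine$double.eps
  e[!ok] <- 1                                  # dummy, zeroed at the end
  for (mm in seq_len(p)) {
    acc <- if (mm > 1L)
      colSums(phi[1:(mm - 1L), , drop = FALSE] * r[mm:2, , drop = FALSE])
    else 0
    k <- (r[mm + 1L, ] - acc) / e
    if (mm > 1L) {
      old <- phi[1:(mm - 1L), , drop = FALSE]
      phi[1:(mm - 1L), ] <- old - rep(k, each = mm - 1L) *
        old[rev(seq_len(mm - 1L)), , drop = FALSE]
    }
    phi[mm, ] <- k
    e <- e * (1 - k^2)
  }
  e[e < 0] <- 0
  phi[, !ok] <- 0
  e[!ok] <- 0
  list(phi = phi, sigma2 = e)
}

batch_psd_max <- function(segs, fs, order, n_freq) {
  n <- nrow(segs); m <- ncol(segs)
  r <- matrix(0, order + 1L, m)
  for (k in 0:order) {
    r[k + 1L, ] <- colSums(segs[seq_len(n - k), , drop = FALSE] *
                             segs[seq_len(n - k) + k, , drop = FALSE]) / n
  }
  fit <- batch_levinson(r)
  f <- seq(0, fs / 2, length.out = n_freq)
  omega <- 2 * pi * f / fs
  k <- seq_len(order)
  C <- cos(outer(k, omega)); S <- sin(outer(k, omega))   # order x n_freq
  re <- 1 - crossprod(fit$phi, C)                        # m x n_freq
  im <- crossprod(fit$phi, S)
  a2 <- re^2 + im^2
  scale <- c(1, rep(2, max(0, n_freq - 2L)), 1) / fs
  psd <- sweep(1 / a2, 2, scale, "*") * fit$sigma2
  apply(psd, 1, max)
}

#' Segment labels from annotations
#'
#' A window is ictal (label 1) iff at least `min_overlap` of it overlaps an
#' annotation carrying `label`.
#'
#' @param grid A [segment_grid()].
#' @param annotations Annotation data frame.
#' @param label Annotation label that counts as ictal (default
#'   `"epileptic"`).
#' @param min_overlap Minimum overlapping fraction of the window
#'   (default 0.5).
#' @return Integer vector of 0/1 labels, one per segment.
#' @export
segment_labels <- function(grid, annotations, label = "epileptic",
                           min_overlap = 0.5) {
  ann <- annotations_df(annotations)
  ann <- ann[ann$label == label, , drop = FALSE]
  out <- integer(grid$n_segments)
  if (nrow(ann) == 0L) return(out)
  w0 <- grid$t_start_s
  w1 <- w0 + grid$win_s
  ov <- numeric(grid$n_segments)
  for (i in seq_len(nrow(ann))) {
    a0 <- ann$onset_s[i]; a1 <- a0 + ann$duration_s[i]
    ov <- ov + pmax(0, pmin(w1, a1) - pmax(w0, a0))
  }
  as.integer(ov / grid$win_s >= min_overlap)
}

#' Extract the four-feature matrix from a recording
#'
#' Segments every channel into `win_s` windows and computes, per (channel,
#' window): the maximum Yule-Walker AR PSD, Shannon entropy, Renyi entropy
#' of order `alpha`, and averaged Teager energy. Rows are labelled 1 when at
#' least half the window overlaps an `"epileptic"` annotation.
#'
#' @param recording An [eeg_recording()] (typically preprocessed).
#' @param win_s Window length in seconds (default 0.5).
#' @param n_bins Histogram bins for the entropies (default 16).
#' @param alpha Renyi order (default 2).
#' @param ar_order Yule-Walker AR order (default 4).
#' @param n_freq PSD frequency grid size (default 256).
#' @param annotations Annotation data frame; defaults to the recording's
#'   own annotations (pass the pre-cleaning annotations when features are
#'   computed on a filtered copy).
#' @return Data frame with columns `channel`, `channel_name`,
#'   `segment_index`, `t_start_s`, `psd_max`, `shannon_H`, `renyi_H`,
#'   `teager`, `label`.
#' @export
extract_features <- function(recording, win_s = 0.5, n_bins = 16, alpha = 2,
                             ar_order = 4, n_freq = 256,
                             annotations = recording$annotations) {
  grid <- segment_grid(ncol(recording$signals), recording$fs, win_s)
  if (grid$n_per_segment <= ar_order + 1L)
    stop("window too short for the AR order")
  labs <- segment_labels(grid, annotations)
  n_ch <- nrow(recording$signals)
  per_channel <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    segs <- segment_matrix(recording$signals[ch, ], grid)
    ent <- batch_entropies(segs, n_bins, alpha)
    per_channel[[ch]] <- data.frame(
      channel = ch,
      channel_name = recording$channel_names[ch],
      segment_index = seq_len(grid$n_segments),
      t_start_s = grid$t_start_s,
      psd_max = batch_psd_max(segs, recording$fs, ar_order, n_freq),
      shannon_H = ent$shannon,
      renyi_H = ent$renyi,
      teager = batch_teager(segs),
      label = labs,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, per_channel)
  rownames(out) <- NULL
  attr(out, "grid") <- grid
  out
}

#' Write / read a feature matrix CSV
#'
#' @param features Feature data frame from [extract_features()].
#' @param path CSV path.
#' @return `path` invisibly / the feature data frame.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
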