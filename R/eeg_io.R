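#' Construct a multi-channel EEG recording
#'
#' The canonical in-memory container used throughout the package: a channels
#' x samples matrix of physical amplitudes (microvolts), a sampling rate,
#' ordered channel labels, and an event-level annotation table.
#'
#' @param signals Numeric matrix, channels in rows, samples in columns (µV).
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector of unique channel labels, one per
#'   row of `signals`. Defaults to `"CH1"`, `"CH2"`, ...
#' @param annotations Data frame with columns `onset_s`, `duration_s`,
#'   `label` (see [annotations_df()]), or `NULL` for none. Overlapping or
#'   touching events that share a label are merged on construction.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signals, fs, channel_names = NULL,
                          annotations = NULL) {
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("`signals` must be a numeric matrix (channels x samples)")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  n_ch <- nrow(signals)
  if (is.null(channel_names))
    channel_names <- paste0("CH", seq_len(n_ch))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != n_ch)
    stop("`channel_names` must have one entry per channel")
  if (anyDuplicated(channel_names))
    stop("`channel_names` must be unique")
  ann <- annotations_df(annotations)
  ann <- merge_annotations(ann)
  rownames(signals) <- channel_names
  structure(
    list(signals = signals, fs = fs, channel_names = channel_names,
         annotations = ann),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signals), ncol(x$signals), x$fs,
              ncol(x$signals) / x$fs))
  cat(sprintf("  channels: %s\n",
              paste(utils::head(x$channel_names, 8), collapse = ", ")))
  cat(sprintf("  annotations: %d event(s)\n", nrow(x$annotations)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording An [eeg_recording()].
#' @return Length in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$signals) / recording$fs
}

#' Normalise an annotation table
#'
#' @param x `NULL`, or a data frame with columns `onset_s`, `duration_s`,
#'   `label` (extra columns dropped). Onsets are seconds from record start.
#' @return A validated data frame with those three columns.
#' @export
annotations_df <- function(x = NULL) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L)) {
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  if (!is.data.frame(x) ||
      !all(c("onset_s", "duration_s", "label") %in% names(x)))
    stop("annotations need columns onset_s, duration_s, label")
  out <- data.frame(onset_s = as.numeric(x$onset_s),
                    duration_s = as.numeric(x$duration_s),
                    label = as.character(x$label),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$onset_s)) || any(out$onset_s < 0))
    stop("annotation onsets must be finite and >= 0")
  if (any(!is.finite(out$duration_s)) || any(out$duration_s <= 0))
    stop("annotation durations must be finite and > 0")
  out
}

#' Merge overlapping same-label annotations
#'
#' Events are treated as closed intervals; events of the same label that
#' overlap or touch (zero gap) are merged into their union. Distinct labels
#' never merge.
#'
#' @param ann Annotation data frame (see [annotations_df()]).
#' @return Merged annotation data frame, sorted by onset.
#' @export
merge_annotations <- function(ann) {
  ann <- annotations_df(ann)
  if (nrow(ann) < 2L) return(ann)
  pieces <- lapply(split(ann, ann$label), function(d) {
    d <- d[order(d$onset_s), , drop = FALSE]
    start <- d$onset_s[1]
    end <- start + d$duration_s[1]
    out_s <- numeric(0); out_e <- numeric(0)
    for (i in seq_len(nrow(d))[-1]) {
      s <- d$onset_s[i]; e <- s + d$duration_s[i]
      if (s <= end) {            # closed intervals: touching intervals merge
        end <- max(end, e)
      } else {
        out_s <- c(out_s, start); out_e <- c(out_e, end)
        start <- s; end <- e
      }
    }
    out_s <- c(out_s, start); out_e <- c(out_e, end)
    data.frame(onset_s = out_s, duration_s = out_e - out_s,
               label = d$label[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$onset_s, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# EDF (European Data Format, 16-bit)
#
# No EDF codec ships with this R installation, so a minimal EDF implementation
# lives here: fixed-width ASCII header, one 256-byte signal header block per
# channel, little-endian int16 data records. Only continuous equal-rate
# signals are handled; annotations travel in a sidecar CSV (see
# read_annotations_csv / write_annotations_csv) because plain EDF has no
# annotation container.
# ---------------------------------------------------------------------------

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Signals are quantised to 16-bit integers over each channel's physical
#' range, the usual EDF precision. Annotations are not embedded; write them
#' with [write_annotations_csv()].
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path.
#' @param record_duration_s Length of one EDF data record in seconds
#'   (default 1). `fs * record_duration_s` must be a whole number.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, record_duration_s = 1) {
  sig <- recording$signals
  fs <- recording$fs
  spr <- fs * record_duration_s            # samples per record per channel
  if (abs(spr - round(spr)) > 1e-9)
    stop("fs * record_duration_s must be an integer")
  spr <- as.integer(round(spr))
  n_ch <- nrow(sig)
  n_rec <- ceiling(ncol(sig) / spr)
  total <- n_rec * spr
  if (total > ncol(sig)) {                 # zero-pad the trailing record
    sig <- cbind(sig, matrix(0, n_ch, total - ncol(sig)))
  }
  phys_min <- apply(sig, 1, min)
  phys_max <- apply(sig, 1, max)
  flat <- phys_max - phys_min < .Machine$double.eps
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                       # version
    edf_pad("X X X X", 80),                # patient id (anonymous)
    edf_pad("Startdate X X X X", 80),      # recording id
    edf_pad("01.01.00", 8),                # start date
    edf_pad("00.00.00", 8),                # start time
    edf_pad(256L * (1L + n_ch), 8),        # header bytes
    edf_pad("", 44),                       # reserved
    edf_pad(n_rec, 8),
    edf_pad(format(record_duration_s, trim = TRUE), 8),
    edf_pad(n_ch, 4)
  )
  field <- function(vals, width)
    paste(vapply(vals, edf_pad, "", width = width), collapse = "")
  hdr <- paste0(
    hdr,
    field(recording$channel_names, 16),
    field(rep("AgAgCl electrode", n_ch), 80),
    field(rep("uV", n_ch), 8),
    field(formatC(phys_min, format = "g", digits = 7), 8),
    field(formatC(phys_max, format = "g", digits = 7), 8),
    field(rep(dig_min, n_ch), 8),
    field(rep(dig_max, n_ch), 8),
    field(rep("", n_ch), 80),              # prefilter
    field(rep(spr, n_ch), 8),
    field(rep("", n_ch), 32)               # reserved
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(n_ch)) {
      d <- round((sig[ch, cols] - phys_min[ch]) * scale[ch]) + dig_min
      writeBin(as.integer(d), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

edf_read_field <- function(con, width) {
  trimws(readChar(con, width, useBytes = TRUE))
}

edf_num <- function(x, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v)))
    stop(sprintf("malformed EDF header: field '%s' is not numeric ('%s')",
                 what, paste(x, collapse = ",")))
  v
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @param annotations_path Optional sidecar annotation CSV read with
#'   [read_annotations_csv()].
#' @return An [eeg_recording()]. Amplitudes are converted to each channel's
#'   physical units as declared in the header (µV for files written by
#'   [write_edf()]).
#' @export
read_edf <- function(path, annotations_path = NULL) {
  info <- file.info(path)
  if (is.na(info$size) || info$size < 256)
    stop("malformed EDF header: file shorter than the 256-byte fixed header")
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8, useBytes = TRUE)                    # version
  readChar(con, 80 + 80 + 8 + 8, useBytes = TRUE)      # ids, date, time
  hdr_bytes <- edf_num(edf_read_field(con, 8), "header bytes")
  readChar(con, 44, useBytes = TRUE)
  n_rec <- edf_num(edf_read_field(con, 8), "number of records")
  rec_dur <- edf_num(edf_read_field(con, 8), "record duration")
  n_ch <- edf_num(edf_read_field(con, 4), "number of signals")
  if (n_ch < 1 || n_ch != round(n_ch))
    stop("malformed EDF header: number of signals must be a positive integer")
  n_ch <- as.integer(n_ch)
  if (hdr_bytes != 256 * (1 + n_ch))
    stop(sprintf(
      "malformed EDF header: header bytes (%d) disagree with signal count (%d)",
      hdr_bytes, n_ch))

  labels <- vapply(seq_len(n_ch), function(i) edf_read_field(con, 16), "")
  readChar(con, 80L * n_ch, useBytes = TRUE)           # transducer
  readChar(con, 8L * n_ch, useBytes = TRUE)            # physical dimension
  phys_min <- edf_num(vapply(seq_len(n_ch), function(i)
    edf_read_field(con, 8), ""), "physical minimum")
  phys_max <- edf_num(vapply(seq_len(n_ch), function(i)
    edf_read_field(con, 8), ""), "physical maximum")
  dig_min <- edf_num(vapply(seq_len(n_ch), function(i)
    edf_read_field(con, 8), ""), "digital minimum")
  dig_max <- edf_num(vapply(seq_len(n_ch), function(i)
    edf_read_field(con, 8), ""), "digital maximum")
  readChar(con, 80L * n_ch, useBytes = TRUE)           # prefilter
  spr <- edf_num(vapply(seq_len(n_ch), function(i)
    edf_read_field(con, 8), ""), "samples per record")
  readChar(con, 32L * n_ch, useBytes = TRUE)
  if (length(unique(spr)) != 1L)
    stop("unsupported EDF: channels have differing sampling rates")
  spr <- as.integer(spr[1])

  expected <- n_rec * n_ch * spr
  payload <- info$size - hdr_bytes
  if (payload < 2 * expected)
    stop(sprintf(
      "malformed EDF: data area holds %d samples but header promises %d",
      floor(payload / 2), expected))

  sig <- matrix(0, n_ch, n_rec * spr)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(n_ch)) {
      d <- readBin(con, "integer", n = spr, size = 2L, signed = TRUE,
                   endian = "little")
      if (length(d) < spr)
        stop("malformed EDF: truncated data record")
      cols <- ((r - 1L) * spr + 1L):(r * spr)
      sig[ch, cols] <- phys_min[ch] + (d - dig_min[ch]) * scale[ch]
    }
  }
  ann <- NULL
  if (!is.null(annotations_path)) ann <- read_annotations_csv(annotations_path)
  eeg_recording(sig, fs = spr / rec_dur, channel_names = labels,
                annotations = ann)
}

#' Read a signal CSV as a recording
#'
#' Expects one column per channel with a header row of channel names and one
#' sample per row; the sampling rate is supplied by the caller since CSV
#' carries none.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz.
#' @param annotations Optional annotation data frame attached to the result.
#' @return An [eeg_recording()].
#' @export
read_signals_csv <- function(path, fs, annotations = NULL) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (ncol(d) < 1L || nrow(d) < 1L) stop("signal CSV is empty")
  if (!all(vapply(d, is.numeric, TRUE)))
    stop("signal CSV has non-numeric columns")
  eeg_recording(t(as.matrix(d)), fs = fs, channel_names = names(d),
                annotations = annotations)
}

#' Write a recording's signals to CSV
#'
#' @param recording An [eeg_recording()].
#' @param path Output CSV path (one column per channel, header row).
#' @return `path`, invisibly.
#' @export
write_signals_csv <- function(recording, path) {
  d <- as.data.frame(t(recording$signals))
  names(d) <- recording$channel_names
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read annotations from CSV
#'
#' The file must have columns `onset_s`, `duration_s`, `label`. Rows are
#' parsed in order; overlapping events of the same label are merged.
#'
#' @param path CSV file path.
#' @return Annotation data frame.
#' @export
read_annotations_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  merge_annotations(annotations_df(d))
}

#' Write annotations to CSV
#' @param annotations Annotation data frame (see [annotations_df()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations_csv <- function(annotations, path) {
  utils::write.csv(annotations_df(annotations), path, row.names = FALSE)
  invisible(path)
}
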