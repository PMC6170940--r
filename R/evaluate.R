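#' Merge per-window decisions into seizure events
#'
#' Consecutive positive windows form an event; runs separated by a gap no
#' longer than `gap_tolerance_s` are bridged, and events shorter than
#' `min_event_s` are discarded — turning 0.5 s epoch decisions into
#' clinically meaningful seizure events.
#'
#' @param labels Integer 0/1 vector, one decision per window.
#' @param t_start_s Window start times in seconds (regular grid).
#' @param win_s Window length in seconds.
#' @param min_event_s Minimum event duration kept (default 1.0).
#' @param gap_tolerance_s Maximum bridged gap between positive runs
#'   (default 0.5).
#' @return Annotation data frame (`onset_s`, `duration_s`,
#'   `label = "epileptic"`).
#' @export
merge_segments_to_events <- function(labels, t_start_s, win_s,
                                     min_event_s = 1.0,
                                     gap_tolerance_s = 0.5) {
  stopifnot(length(labels) == length(t_start_s))
  pos <- which(labels == 1L)
  if (length(pos) == 0L) return(annotations_df(NULL))
  starts <- t_start_s[pos]
  ends <- starts + win_s
  ev_on <- starts[1]; ev_off <- ends[1]
  out_on <- numeric(0); out_off <- numeric(0)
  for (i in seq_along(pos)[-1]) {
    if (starts[i] - ev_off <= gap_tolerance_s + 1e-9) {
      ev_off <- ends[i]
    } else {
      out_on <- c(out_on, ev_on); out_off <- c(out_off, ev_off)
      ev_on <- starts[i]; ev_off <- ends[i]
    }
  }
  out_on <- c(out_on, ev_on); out_off <- c(out_off, ev_off)
  keep <- (out_off - out_on) >= min_event_s - 1e-9
  if (!any(keep)) return(annotations_df(NULL))
  annotations_df(data.frame(onset_s = out_on[keep],
                            duration_s = (out_off - out_on)[keep],
                            label = "epileptic"))
}

events_overlap <- function(on1, off1, on2, off2) {
  on1 < off2 & on2 < off1            # any strictly positive overlap
}

#' Event-level sensitivity and false detection rate
#'
#' A true seizure counts as detected iff it overlaps at least one predicted
#' event; sensitivity is the detected percentage. A predicted event
#' overlapping no true seizure is a false detection; the false detection
#' rate is false detections per hour of recording.
#'
#' @param predicted_events,true_events Annotation data frames.
#' @param total_duration_s Record length in seconds.
#' @return List with `sensitivity_pct` (`NA` when there are no true
#'   events), `fdr_per_hour`, `n_detected`, `n_true`, `n_false`, and the
#'   `detected_events` / `missed_events` / `false_events` tables.
#' @export
score_events <- function(predicted_events, true_events, total_duration_s) {
  pe <- annotations_df(predicted_events)
  te <- annotations_df(true_events)
  if (nrow(pe) > 0 &&
      any(pe$onset_s + pe$duration_s > total_duration_s + 1e-6))
    stop("predicted events extend past the recording")
  p_on <- pe$onset_s; p_off <- pe$onset_s + pe$duration_s
  t_on <- te$onset_s; t_off <- te$onset_s + te$duration_s
  detected <- vapply(seq_len(nrow(te)), function(i)
    any(events_overlap(t_on[i], t_off[i], p_on, p_off)), TRUE)
  false_pred <- vapply(seq_len(nrow(pe)), function(j)
    !any(events_overlap(p_on[j], p_off[j], t_on, t_off)), TRUE)
  n_true <- nrow(te)
  sens <- if (n_true == 0L) NA_real_ else 100 * sum(detected) / n_true
  n_false <- sum(false_pred)
  list(sensitivity_pct = sens,
       fdr_per_hour = n_false / (total_duration_s / 3600),
       n_detected = sum(detected), n_true = n_true, n_false = n_false,
       detected_events = te[detected, , drop = FALSE],
       missed_events = te[!detected, , drop = FALSE],
       false_events = pe[false_pred, , drop = FALSE])
}

#' Segment-level specificity and confusion counts
#'
#' Specificity is the percentage of truly normal windows labelled normal
#' (i.e. `TN / (TN + FP) * 100`).
#'
#' @param predicted_labels,true_labels Equal-length 0/1 vectors.
#' @return List with `specificity_pct` (`NA` when there are no normal
#'   windows), `sensitivity_pct` (segment level), `accuracy_pct`, and
#'   counts `tn`, `fp`, `fn`, `tp`.
#' @export
score_segments <- function(predicted_labels, true_labels) {
  if (length(predicted_labels) != length(true_labels))
    stop("label vectors must have equal length")
  tn <- sum(predicted_labels == 0 & true_labels == 0)
  fp <- sum(predicted_labels == 1 & true_labels == 0)
  fn <- sum(predicted_labels == 0 & true_labels == 1)
  tp <- sum(predicted_labels == 1 & true_labels == 1)
  spec <- if (tn + fp == 0L) NA_real_ else 100 * tn / (tn + fp)
  sens <- if (tp + fn == 0L) NA_real_ else 100 * tp / (tp + fn)
  list(specificity_pct = spec, sensitivity_pct = sens,
       accuracy_pct = 100 * (tp + tn) / length(true_labels),
       tn = tn, fp = fp, fn = fn, tp = tp)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores; AUC by the trapezoid rule, which
#' with tied scores grouped equals the Mann-Whitney concordance probability.
#'
#' @param scores Numeric classifier scores (higher = more ictal).
#' @param true_labels 0/1 truth, both classes present.
#' @return List with `curve` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, true_labels) {
  if (length(scores) != length(true_labels))
    stop("scores and labels must have equal length")
  npos <- sum(true_labels == 1); nneg <- sum(true_labels == 0)
  if (npos == 0L || nneg == 0L)
    stop("ROC needs both classes in the truth labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- true_labels[ord]
  block_end <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l == 1)[block_end]
  fp <- cumsum(l == 0)[block_end]
  tpr <- c(0, tp / npos); fpr <- c(0, fp / nneg)
  thr <- c(Inf, s[block_end])
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
       auc = auc)
}
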