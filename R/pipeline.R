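#' Default pipeline configuration
#'
#' Nested parameter list mirroring the pipeline stages; unknown keys are
#' rejected on load so typos fail fast.
#'
#' @return Named list with sections `synth`, `preprocess`, `features`,
#'   `classifier`, `evaluate`, plus `seed`.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    synth = list(duration_s = 1200, fs = 128, n_channels = 19,
                 background_amp = 20, n_seizures = 10, gain = 5,
                 line_amp = 15),
    preprocess = list(notch_freq = 50, notch_q = 35, bp_low = 0.5,
                      bp_high = 40, bp_order = 5, passband_ripple = 3,
                      stopband_atten = 40, zero_phase = TRUE, ica = TRUE,
                      kurtosis_threshold = 50, lowfreq_fraction = 0.5,
                      lowfreq_hz = 1),
    features = list(win_s = 0.5, n_bins = 16, alpha = 2, ar_order = 4,
                    n_freq = 256),
    classifier = list(hidden = 10, max_epochs = 200, val_fraction = 0.15,
                      patience = 6, train_fraction = 0.7,
                      stratified = TRUE),
    evaluate = list(min_event_s = 1.0, gap_tolerance_s = 0.5,
                    channel_vote = 0.5)
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(base))
      stop(sprintf("unknown config key: %s%s", path, k))
    if (is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]],
                                paste0(path, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated configuration list.
#' @export
load_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname load_pipeline_config
#' @param cfg Configuration list to validate.
#' @export
validate_pipeline_config <- function(cfg) {
  fs <- cfg$synth$fs
  pp <- cfg$preprocess
  if (pp$bp_high >= fs / 2)
    stop("invalid config: preprocess.bp_high must be below fs/2")
  if (pp$bp_low <= 0 || pp$bp_low >= pp$bp_high)
    stop("invalid config: need 0 < bp_low < bp_high")
  if (pp$notch_freq >= fs / 2)
    stop("invalid config: notch frequency at or above Nyquist")
  if (cfg$features$win_s * fs < cfg$features$ar_order + 2)
    stop("invalid config: window too short for the AR order")
  if (cfg$classifier$train_fraction <= 0 ||
      cfg$classifier$train_fraction >= 1)
    stop("invalid config: train_fraction must be in (0, 1)")
  invisible(cfg)
}

# FNV-1a hash of the serialized config, recorded in every output for
# provenance
config_hash <- function(cfg) {
  bytes <- utf8ToInt(yaml::as.yaml(cfg))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

filter_spec_from_config <- function(pp) {
  filter_spec(notch_freq = pp$notch_freq, notch_q = pp$notch_q,
              bp_low = pp$bp_low, bp_high = pp$bp_high,
              bp_order = pp$bp_order,
              passband_ripple = pp$passband_ripple,
              stopband_atten = pp$stopband_atten,
              zero_phase = pp$zero_phase)
}

#' Channel-consensus window labels
#'
#' Collapses per-(channel, window) predictions to one decision per window:
#' positive when at least `vote` of the channels agree — the generalized-
#' seizure assumption that an ictal discharge appears on most channels,
#' which suppresses single-channel artifacts.
#'
#' @param features Feature data frame (needs `segment_index`).
#' @param predicted_labels 0/1 predictions aligned with `features` rows.
#' @param vote Minimum agreeing channel fraction (default 0.5).
#' @return Integer 0/1 vector indexed by segment.
#' @export
channel_consensus <- function(features, predicted_labels, vote = 0.5) {
  frac <- tapply(predicted_labels, features$segment_index, mean)
  as.integer(frac[order(as.integer(names(frac)))] >= vote)
}

#' Run the full synthetic desk experiment
#'
#' Simulates the default study fixture (20 min of 19-channel, 128 Hz EEG
#' with ten gain-5 spike-and-wave seizures, 50 Hz line interference and
#' motion artifacts), preprocesses it, extracts the four features, trains
#' the perceptron on a stratified 70/30 row holdout, and reports
#' segment-level specificity and AUC on the held-out rows plus event-level
#' sensitivity and false detection rate from whole-record consensus
#' detections. Optionally trains the four single-feature reference models
#' on the same split.
#'
#' @param seed Integer seed driving every random stage.
#' @param config Pipeline configuration (default
#'   [default_pipeline_config()]).
#' @param single_features Also fit one model per individual feature
#'   (default TRUE).
#' @return List with `report` (sensitivity_pct, specificity_pct,
#'   fdr_per_hour, auc, accuracy_pct, confusion), `single_feature` results,
#'   `model`, `features`, `events` (predicted and true), `ica_report` and
#'   `config_hash`.
#' @export
run_synthetic_experiment <- function(seed = 1L,
                                     config = default_pipeline_config(),
                                     single_features = TRUE) {
  config$seed <- as.integer(seed)
  validate_pipeline_config(config)
  sy <- config$synth
  scfg <- default_study_config(seed = config$seed,
                               duration_s = sy$duration_s,
                               n_seizures = sy$n_seizures, gain = sy$gain,
                               n_channels = sy$n_channels)
  rec <- simulate_recording(scfg)
  total_s <- recording_duration(rec)
  true_events <- rec$annotations[rec$annotations$label == "epileptic", ,
                                 drop = FALSE]

  pp <- config$preprocess
  pr <- preprocess_recording(
    rec, spec = filter_spec_from_config(pp), ica = pp$ica,
    rule = rejection_rule(pp$kurtosis_threshold, pp$lowfreq_fraction,
                          pp$lowfreq_hz))
  clean <- pr$recording

  fe <- config$features
  fm <- extract_features(clean, win_s = fe$win_s, n_bins = fe$n_bins,
                         alpha = fe$alpha, ar_order = fe$ar_order,
                         n_freq = fe$n_freq,
                         annotations = rec$annotations)
  feat_cols <- c("psd_max", "shannon_H", "renyi_H", "teager")
  X <- as.matrix(fm[, feat_cols])
  y <- fm$label

  cl <- config$classifier
  sp <- holdout_split(y, train_fraction = cl$train_fraction,
                      stratified = cl$stratified,
                      seed = derive_seed(config$seed, 11L))
  model <- train_scg(X[sp$train, , drop = FALSE], y[sp$train],
                     hidden = cl$hidden, max_epochs = cl$max_epochs,
                     val_fraction = cl$val_fraction, patience = cl$patience,
                     seed = derive_seed(config$seed, 12L))
  test_pred <- predict(model, X[sp$test, , drop = FALSE])
  seg <- score_segments(test_pred$label, y[sp$test])
  roc <- roc_auc(test_pred$score, y[sp$test])

  # event scoring: consensus over channels on the whole record
  ev <- config$evaluate
  all_pred <- predict(model, X)
  grid <- attr(fm, "grid")
  consensus <- channel_consensus(fm, all_pred$label, ev$channel_vote)
  pred_events <- merge_segments_to_events(
    consensus, grid$t_start_s, grid$win_s,
    min_event_s = ev$min_event_s, gap_tolerance_s = ev$gap_tolerance_s)
  evs <- score_events(pred_events, true_events, total_s)

  single <- NULL
  if (single_features) {
    single <- lapply(feat_cols, function(fc) {
      m1 <- train_scg(X[sp$train, fc, drop = FALSE], y[sp$train],
                      hidden = cl$hidden, max_epochs = cl$max_epochs,
                      val_fraction = cl$val_fraction,
                      patience = cl$patience,
                      seed = derive_seed(config$seed, 12L))
      p1 <- predict(m1, X[sp$test, fc, drop = FALSE])
      list(accuracy_pct = 100 * mean(p1$label == y[sp$test]),
           auc = roc_auc(p1$score, y[sp$test])$auc)
    })
    names(single) <- feat_cols
  }

  list(
    report = list(sensitivity_pct = evs$sensitivity_pct,
                  specificity_pct = seg$specificity_pct,
                  fdr_per_hour = evs$fdr_per_hour,
                  auc = roc$auc,
                  accuracy_pct = seg$accuracy_pct,
                  confusion = seg[c("tn", "fp", "fn", "tp")],
                  n_true_events = evs$n_true,
                  n_detected_events = evs$n_detected,
                  n_false_events = evs$n_false),
    single_feature = single,
    model = model, features = fm,
    events = list(predicted = pred_events, true = true_events),
    ica_report = pr$report,
    split = sp,
    config_hash = config_hash(config)
  )
}

#' Per-window biomarking in display pages
#'
#' Emits the per-channel window decisions grouped into fixed-length display
#' pages (default 20 s), the layout a reviewer steps through.
#'
#' @param features Feature data frame from [extract_features()].
#' @param predicted_labels 0/1 predictions aligned with `features` rows.
#' @param win_s Window length in seconds.
#' @param page_s Page length in seconds (default 20).
#' @return Data frame with `page_index`, `t_start_s`, `t_end_s`, `channel`,
#'   `label`.
#' @export
biomark_table <- function(features, predicted_labels, win_s = 0.5,
                          page_s = 20) {
  data.frame(page_index = features$t_start_s %/% page_s,
             t_start_s = features$t_start_s,
             t_end_s = features$t_start_s + win_s,
             channel = features$channel_name,
             label = as.integer(predicted_labels),
             stringsAsFactors = FALSE)
}

#' Run the pipeline stages and write artifacts to disk
#'
#' Executes simulate, preprocess, extract, stats, train, evaluate and
#' biomark in order (or any prefix via `stages`), writing each boundary as
#' a file: raw/clean recordings as EDF + annotation CSV, features as CSV,
#' the statistics report and the detection report as JSON, the model as
#' JSON and the biomark table as CSV. Every JSON artifact carries the
#' config hash and seed.
#'
#' @param config Pipeline configuration list.
#' @param out_dir Output directory (created if missing).
#' @param input_path Optional existing EDF to analyse instead of simulating
#'   (requires `annotations_path` for training).
#' @param annotations_path Optional annotation CSV for `input_path`.
#' @param stages Stages to run, a prefix of
#'   `c("simulate", "preprocess", "extract", "stats", "train", "evaluate",
#'   "biomark")`.
#' @return Invisible list of written paths plus the in-memory results.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = ".", input_path = NULL,
                         annotations_path = NULL,
                         stages = c("simulate", "preprocess", "extract",
                                    "stats", "train", "evaluate",
                                    "biomark")) {
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  meta <- list(config_hash = config_hash(config), seed = config$seed)
  msg <- function(...) message(sprintf(...))
  .stage <- "input"
  # on any stage failure: drop this run's partial outputs, name the stage
  tryCatch({

  if (!is.null(input_path)) {
    .stage <- "input"
    rec <- read_edf(input_path, annotations_path)
    msg("input: loaded %d channels, %.0f s", nrow(rec$signals),
        recording_duration(rec))
  } else {
    if (!"simulate" %in% stages) stop("no input: need the simulate stage")
    .stage <- "simulate"
    sy <- config$synth
    scfg <- default_study_config(seed = config$seed,
                                 duration_s = sy$duration_s,
                                 n_seizures = sy$n_seizures,
                                 gain = sy$gain,
                                 n_channels = sy$n_channels)
    rec <- simulate_recording(scfg)
    paths$raw_edf <- file.path(out_dir, "raw.edf")
    paths$annotations <- file.path(out_dir, "annotations.csv")
    write_edf(rec, paths$raw_edf)
    write_annotations_csv(rec$annotations, paths$annotations)
    msg("simulate: %d channels, %.0f s, %d annotated event(s)",
        nrow(rec$signals), recording_duration(rec), nrow(rec$annotations))
  }
  if (!"preprocess" %in% stages)
    return(invisible(list(paths = paths, recording = rec)))

  .stage <- "preprocess"
  pp <- config$preprocess
  pr <- preprocess_recording(
    rec, spec = filter_spec_from_config(pp), ica = pp$ica,
    rule = rejection_rule(pp$kurtosis_threshold, pp$lowfreq_fraction,
                          pp$lowfreq_hz))
  clean <- pr$recording
  paths$clean_edf <- file.path(out_dir, "clean.edf")
  write_edf(clean, paths$clean_edf)
  n_rej <- if (is.null(pr$report)) 0L else sum(pr$report$rejected)
  msg("preprocess: notch + bandpass done, %d ICA component(s) rejected",
      n_rej)
  if (!"extract" %in% stages)
    return(invisible(list(paths = paths, recording = clean)))

  .stage <- "extract"
  fe <- config$features
  fm <- extract_features(clean, win_s = fe$win_s, n_bins = fe$n_bins,
                         alpha = fe$alpha, ar_order = fe$ar_order,
                         n_freq = fe$n_freq, annotations = rec$annotations)
  paths$features <- file.path(out_dir, "features.csv")
  write_features_csv(fm, paths$features)
  msg("extract: %d rows (%d channels x %d windows)", nrow(fm),
      nrow(rec$signals), attr(fm, "grid")$n_segments)

  out <- list(paths = paths, features = fm)
  .stage <- "stats"
  if ("stats" %in% stages && any(fm$label == 1)) {
    st <- feature_stats_report(fm)
    paths$stats <- file.path(out_dir, "stats.json")
    jsonlite::write_json(c(meta, list(stats = st)), paths$stats,
                         digits = NA, auto_unbox = TRUE)
    msg("stats: wrote %s", paths$stats)
  }
  if (!"train" %in% stages)
    return(invisible(c(out, list(paths = paths))))

  .stage <- "train"
  feat_cols <- c("psd_max", "shannon_H", "renyi_H", "teager")
  X <- as.matrix(fm[, feat_cols]); y <- fm$label
  cl <- config$classifier
  sp <- holdout_split(y, train_fraction = cl$train_fraction,
                      stratified = cl$stratified,
                      seed = derive_seed(config$seed, 11L))
  model <- train_scg(X[sp$train, , drop = FALSE], y[sp$train],
                     hidden = cl$hidden, max_epochs = cl$max_epochs,
                     val_fraction = cl$val_fraction, patience = cl$patience,
                     seed = derive_seed(config$seed, 12L))
  paths$model <- file.path(out_dir, "model.json")
  write_mlp_json(model, paths$model)
  msg("train: best epoch %d of %d", model$best_epoch, nrow(model$trace))

  .stage <- "evaluate"
  if ("evaluate" %in% stages) {
    test_pred <- predict(model, X[sp$test, , drop = FALSE])
    seg <- score_segments(test_pred$label, y[sp$test])
    roc <- roc_auc(test_pred$score, y[sp$test])
    all_pred <- predict(model, X)
    grid <- attr(fm, "grid")
    consensus <- channel_consensus(fm, all_pred$label,
                                   config$evaluate$channel_vote)
    pred_events <- merge_segments_to_events(
      consensus, grid$t_start_s, grid$win_s,
      min_event_s = config$evaluate$min_event_s,
      gap_tolerance_s = config$evaluate$gap_tolerance_s)
    true_events <- rec$annotations[rec$annotations$label == "epileptic", ,
                                   drop = FALSE]
    evs <- score_events(pred_events, true_events, recording_duration(rec))
    report <- c(meta, list(
      sensitivity_pct = evs$sensitivity_pct,
      specificity_pct = seg$specificity_pct,
      fdr_per_hour = evs$fdr_per_hour, auc = roc$auc,
      confusion = seg[c("tn", "fp", "fn", "tp")]))
    paths$report <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, paths$report, digits = NA,
                         auto_unbox = TRUE)
    paths$roc <- file.path(out_dir, "roc.csv")
    utils::write.csv(roc$curve, paths$roc, row.names = FALSE)
    msg("evaluate: S+ %.1f%%, S- %.1f%%, FDR %.2f/h, AUC %.3f",
        evs$sensitivity_pct, seg$specificity_pct, evs$fdr_per_hour,
        roc$auc)
    out$report <- report
  }
  .stage <- "biomark"
  if ("biomark" %in% stages) {
    all_pred <- predict(model, X)
    bm <- biomark_table(fm, all_pred$label, win_s = config$features$win_s)
    paths$biomark <- file.path(out_dir, "biomark.csv")
    utils::write.csv(bm, paths$biomark, row.names = FALSE)
    msg("biomark: wrote %s", paths$biomark)
  }
  invisible(c(out, list(paths = paths, model = model, split = sp)))

  }, error = function(e) {
    done <- unlist(paths)
    unlink(done[file.exists(done)])
    stop(sprintf("pipeline stage '%s' failed: %s", .stage,
                 conditionMessage(e)), call. = FALSE)
  })
}
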