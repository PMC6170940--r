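# eegseizer

Automated epileptic-seizure screening for long-term multi-channel EEG.

Reviewing hours of 19-channel scalp EEG for ictal discharges is slow and
error-prone. `eegseizer` implements a complete, tested screening pipeline
for this task: clean the record (50 Hz notch, 0.5–40 Hz elliptic bandpass,
ICA artifact rejection), cut every channel into 0.5 s windows, describe
each window by four features, validate the features statistically, classify
windows with a small neural network, and merge window decisions into
seizure events with clinical scoring. A seeded synthetic EEG generator
stands in for clinical recordings, so the entire pipeline is reproducible
and testable offline.

## The method

Per channel and 0.5 s window (*N* = 64 samples at 128 Hz):

* **Yule–Walker max PSD** — fit an AR(4) model via the biased
  autocorrelation and Levinson–Durbin, evaluate
  σ² / (f_s·|A(e^{iω})|²) on a 256-point grid over [0, f_s/2], keep the
  maximum. Ictal EEG concentrates narrow-band power, which AR spectra
  resolve well at short windows.
* **Shannon entropy** — E = −Σ p_i log₂ p_i with histogram bin
  probabilities p_i (16 uniform bins over the window's own range).
* **Rényi entropy (α = 2)** — E = −log₂ Σ p_i², the quadratic member of
  E = (1/(1−α)) log₂ Σ p_i^α, on the same histogram.
* **Teager energy** — TE = (1/(N−1)) Σ_{n=2}^{N−1} (x_n² − x_{n−1}x_{n+1}),
  a nonlinear operator jointly sensitive to amplitude and instantaneous
  frequency.

Per-class descriptive summaries (mean, SD, quartiles, IQR, SID) and the
two-sided Wilcoxon rank-sum test screen the features; a 4→10(tanh)→1
(sigmoid) perceptron trained by scaled conjugate gradient on a stratified
70/30 holdout classifies windows (targets 0 = normal, 1 = epileptic);
channel-consensus voting plus run-merging turns window decisions into
events scored by

* S⁺ = detected seizures / total seizures × 100,
* S⁻ = correctly labelled normal windows / total normal windows × 100,
* FDR = false detections per hour,
* ROC/AUC by threshold sweep (equal to Mann–Whitney concordance).

See `vignettes/seizure-detection-methods.Rmd` for every modelling and
numerical decision.

## Worked example

```r
library(eegseizer)

# 2 minutes of 6-channel EEG with two 3 Hz spike-wave seizures + 50 Hz noise
cfg <- synth_config(duration_s = 120, n_channels = 6, seed = 42,
                    seizure_events = data.frame(onset_s = c(30, 80),
                                                duration_s = c(12, 15)),
                    line_amp = 15)
rec <- simulate_recording(cfg)
rec
#> <eeg_recording> 6 channels x 15360 samples @ 128 Hz (120.0 s)
#>   channels: CH1, CH2, CH3, CH4, CH5, CH6
#>   annotations: 2 event(s)

clean <- preprocess_recording(rec)$recording
fm <- extract_features(clean, annotations = rec$annotations)
nrow(fm); sum(fm$label)
#> [1] 1440      # 6 channels x 240 windows
#> [1] 324       # ictal rows

rank_sum_test(fm$teager[fm$label == 0], fm$teager[fm$label == 1],
              exact = FALSE)
#> Teager rank-sum: p = 6.8e-163, z = -27.20   (feature separates classes)

sp <- holdout_split(fm$label, seed = 1)
feat <- c("psd_max", "shannon_H", "renyi_H", "teager")
model <- train_scg(as.matrix(fm[sp$train, feat]), fm$label[sp$train], seed = 1)
pred <- predict(model, as.matrix(fm[sp$test, feat]))
roc_auc(pred$score, fm$label[sp$test])$auc
#> [1] 0.998

all_pred <- predict(model, as.matrix(fm[, feat]))
grid <- attr(fm, "grid")
events <- merge_segments_to_events(channel_consensus(fm, all_pred$label),
                                   grid$t_start_s, grid$win_s)
events
#>   onset_s duration_s     label
#> 1      30       11.5 epileptic
#> 2      80       14.5 epileptic

score_events(events, rec$annotations[rec$annotations$label == "epileptic", ],
             120)[c("sensitivity_pct", "fdr_per_hour")]
#> $sensitivity_pct [1] 100
#> $fdr_per_hour    [1] 0
```

Both planted seizures are recovered with onsets exact to the window grid
and no false detections; the held-out AUC of 0.998 reflects the large
amplitude margin of gain-5 discharges over background.

`run_pipeline()` performs the same flow end to end with files at every
stage boundary (EDF recordings, feature CSV, model JSON, report JSON,
biomark CSV), and `inst/exec/eegseizer` exposes it as a command line
(`simulate`, `preprocess`, `extract`, `stats`, `train`, `evaluate`,
`biomark`) driven by a YAML config.

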