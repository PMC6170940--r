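test_that("window runs merge into events with gap bridging and duration filter", {
  t0 <- seq(0, by = 0.5, length.out = 5)
  ev <- merge_segments_to_events(c(0, 1, 1, 1, 0), t0, 0.5,
                                 min_event_s = 1.0, gap_tolerance_s = 0)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_s, 0.5)
  expect_equal(ev$duration_s, 1.5)
  # gap bridging: 1,0,1 with 0.5 s tolerance becomes one 1.5 s event
  ev2 <- merge_segments_to_events(c(1, 0, 1), seq(0, 1, 0.5), 0.5,
                                  min_event_s = 1.0,
                                  gap_tolerance_s = 0.5)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$duration_s, 1.5)
  # isolated positive shorter than min_event_s is dropped
  ev3 <- merge_segments_to_events(c(0, 1, 0), seq(0, 1, 0.5), 0.5,
                                  min_event_s = 1.0, gap_tolerance_s = 0)
  expect_equal(nrow(ev3), 0L)
  expect_equal(nrow(merge_segments_to_events(rep(0, 4), seq(0, 1.5, 0.5),
                                             0.5)), 0L)
})

test_that("event scoring implements overlap detection and per-hour FDR", {
  true_ev <- data.frame(onset_s = seq(0, 900, by = 100)[1:10],
                        duration_s = 10, label = "epileptic")
  pred <- true_ev[1:8, ]
  pred$onset_s <- pred$onset_s + 5       # partial overlap still detects
  sc <- score_events(pred, true_ev, total_duration_s = 7200)
  expect_equal(sc$sensitivity_pct, 80)
  expect_equal(sc$n_false, 0L)
  # 3 false events in 2 h -> 1.5 per hour
  pred2 <- rbind(pred, data.frame(onset_s = c(2000, 3000, 4000),
                                  duration_s = 5, label = "epileptic"))
  sc2 <- score_events(pred2, true_ev, 7200)
  expect_equal(sc2$fdr_per_hour, 1.5)
  # exact prediction: perfect scores
  sc3 <- score_events(true_ev, true_ev, 7200)
  expect_equal(sc3$sensitivity_pct, 100)
  expect_equal(sc3$fdr_per_hour, 0)
  # zero true events: sensitivity is not applicable, never 0/0
  sc4 <- score_events(pred, annotations_df(NULL), 7200)
  expect_true(is.na(sc4$sensitivity_pct))
  expect_equal(sc4$n_false, 8L)
})

test_that("segment scoring computes specificity and confusion counts", {
  sc <- score_segments(rep(0, 10), rep(0, 10))
  expect_equal(sc$specificity_pct, 100)
  truth <- c(rep(0, 100), rep(1, 20))
  pred <- truth
  pred[1:10] <- 1                       # 10 false positives
  sc2 <- score_segments(pred, truth)
  expect_equal(sc2$specificity_pct, 90)
  expect_equal(sc2$tn, 90L)
  expect_equal(sc2$fp, 10L)
  expect_equal(sc2$tp, 20L)
  sc3 <- score_segments(rep(1, 5), rep(1, 5))
  expect_true(is.na(sc3$specificity_pct))
  expect_error(score_segments(1:3, 1:4), "equal length")
})

test_that("ROC/AUC matches the pairwise concordance oracle", {
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1.0)
  set.seed(50)
  for (trial in 1:10) {
    n <- sample(20:200, 1)
    scores <- round(rnorm(n), 1)         # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    auc <- roc_auc(scores, labels)$auc
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    conc <- 0
    for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
    expect_equal(auc, conc / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(51)
  scores <- rnorm(300)
  labels <- rbinom(300, 1, 0.5)
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_auc(scores * 100 - 7, labels)$auc, a0,
               tolerance = 1e-12)
})

test_that("null AUC concentrates near one half", {
  set.seed(52)
  aucs <- replicate(5, {
    scores <- rnorm(2000)
    labels <- rbinom(2000, 1, 0.5)
    roc_auc(scores, labels)$auc
  })
  expect_true(all(abs(aucs - 0.5) < 0.04))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  scores <- rnorm(500)
  labels <- rbinom(500, 1, 0.3)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-10)
})

test_that("detection behaves monotonically in the merge parameters", {
  set.seed(54)
  labels <- rbinom(120, 1, 0.25)
  t0 <- seq(0, by = 0.5, length.out = 120)
  true_ev <- data.frame(onset_s = c(5, 30), duration_s = c(5, 5),
                        label = "epileptic")
  gaps <- c(0, 0.5, 1, 2)
  sens <- vapply(gaps, function(g) {
    ev <- merge_segments_to_events(labels, t0, 0.5, min_event_s = 0,
                                   gap_tolerance_s = g)
    score_events(ev, true_ev, 60)$sensitivity_pct
  }, 0)
  expect_true(all(diff(sens) >= 0))
  mins <- c(0, 0.5, 1, 2, 4)
  fdr <- vapply(mins, function(m) {
    ev <- merge_segments_to_events(labels, t0, 0.5, min_event_s = m,
                                   gap_tolerance_s = 0)
    score_events(ev, true_ev, 60)$fdr_per_hour
  }, 0)
  expect_true(all(diff(fdr) <= 0))
})
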