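test_that("stratified holdout split preserves class proportions within one row", {
  y <- rep(c(0L, 1L), each = 50)
  sp <- holdout_split(y, seed = 3)
  expect_length(sp$train, 70L)
  expect_length(sp$test, 30L)
  expect_equal(sum(y[sp$train]), 35L)
  expect_equal(sum(y[sp$test]), 15L)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  # identical seed, identical split
  expect_identical(sp, holdout_split(y, seed = 3))
  expect_false(identical(sp, holdout_split(y, seed = 4)))
  # 380 rows with 60 positives: 18 positives in the test set (+- 1)
  y2 <- c(rep(1L, 60), rep(0L, 320))
  sp2 <- holdout_split(y2, seed = 5)
  expect_lte(abs(sum(y2[sp2$test]) - 18L), 1L)
  expect_error(holdout_split(rep(0L, 50)), "both classes")
  expect_error(holdout_split(c(0L, 1L)), "at least 10 rows")
})

test_that("analytic SCG gradient matches central finite differences", {
  set.seed(41)
  for (trial in 1:5) {
    d <- sample(2:4, 1); h <- sample(2:5, 1); n <- 30
    X <- matrix(rnorm(n * d), n)
    y <- rbinom(n, 1, 0.5)
    w <- runif(d * h + 2 * h + 1, -0.5, 0.5)
    g <- eegseizer:::mlp_loss_grad(w, X, y, d, h)$grad
    num <- vapply(seq_along(w), function(i) {
      e <- rep(0, length(w)); e[i] <- 1e-6
      (eegseizer:::mlp_loss_grad(w + e, X, y, d, h)$loss -
         eegseizer:::mlp_loss_grad(w - e, X, y, d, h)$loss) / 2e-6
    }, 0)
    expect_lt(max(abs(g - num)) / max(abs(num)), 1e-6)
  }
})

test_that("SCG learns XOR to 100% training accuracy for at least 9 of 10 seeds", {
  base <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), ncol = 2, byrow = TRUE)
  y <- rep(c(0, 1, 1, 0), 25)
  wins <- 0L
  for (s in 1:10) {
    set.seed(s)
    X <- base[rep(1:4, 25), ] + matrix(rnorm(200, 0, 0.02), 100)
    m <- train_scg(X, y, seed = s, val_fraction = 0, max_epochs = 200)
    if (mean(predict(m, X)$label == y) == 1) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("well-separated Gaussian blobs are classified above 95% held out", {
  set.seed(9)
  X <- rbind(matrix(rnorm(200 * 4, 0), 200), matrix(rnorm(200 * 4, 3), 200))
  y <- rep(0:1, each = 200)
  sp <- holdout_split(y, seed = 4)
  m <- train_scg(X[sp$train, ], y[sp$train], seed = 7)
  acc <- mean(predict(m, X[sp$test, ])$label == y[sp$test])
  expect_gte(acc, 0.95)
})

test_that("seeded training is bit-reproducible", {
  set.seed(10)
  X <- matrix(rnorm(200 * 3), 200); y <- rbinom(200, 1, 0.5)
  m1 <- train_scg(X, y, seed = 2)
  m2 <- train_scg(X, y, seed = 2)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$trace, m2$trace)
})

test_that("early stopping bookkeeping returns the validation-loss argmin", {
  set.seed(11)
  X <- rbind(matrix(rnorm(150 * 2, 0), 150), matrix(rnorm(150 * 2, 2), 150))
  y <- rep(0:1, each = 150)
  m <- train_scg(X, y, seed = 5, val_fraction = 0.2, patience = 4)
  expect_equal(m$best_epoch,
               m$trace$epoch[which.min(m$trace$val_mse)])
})

test_that("prediction follows the output activation contract", {
  m <- structure(list(W1 = matrix(0, 2, 3), b1 = rep(0, 3),
                      w2 = rep(0, 3), b2 = 0, hidden = 3L, d = 2L,
                      scaler = list(center = c(0, 0),
                                    halfrange = c(1, 1))),
                 class = "mlp_model")
  p <- predict(m, matrix(rnorm(10), 5))
  expect_true(all(p$score == 0.5))
  expect_true(all(p$label == 0L))     # ties at 0.5 go to normal
  # monotonicity: raising output weights with positive hidden activations
  m$W1 <- matrix(1, 2, 3); m$b1 <- rep(2, 3)
  m$w2 <- rep(0.1, 3)
  s1 <- predict(m, matrix(1, 4, 2))$score
  m$w2 <- rep(0.5, 3)
  s2 <- predict(m, matrix(1, 4, 2))$score
  expect_true(all(s2 >= s1))
  # permuting rows permutes predictions
  set.seed(12)
  X <- matrix(rnorm(20), 10)
  perm <- sample(10)
  expect_equal(predict(m, X)$score[perm], predict(m, X[perm, ])$score)
  expect_error(predict(m, matrix(0, 2, 5)), "features")
})

test_that("the scaler is fitted on training data only", {
  set.seed(13)
  Xtr <- matrix(runif(60, 0, 1), 30)
  ytr <- rep(0:1, 15)
  m <- train_scg(Xtr, ytr, seed = 1, val_fraction = 0)
  # scaler range reflects the training rows, not any test extremes
  expect_true(all(m$scaler$center >= 0 & m$scaler$center <= 1))
  Xte <- matrix(runif(20, 50, 100), 10)   # far outside training range
  s <- predict(m, Xte)$score
  expect_true(all(is.finite(s)))
  # refitting with the test rows included changes the scaler
  m2 <- train_scg(rbind(Xtr, Xte), c(ytr, rep(0:1, 5)), seed = 1,
                  val_fraction = 0)
  expect_false(isTRUE(all.equal(m$scaler$halfrange,
                                m2$scaler$halfrange)))
})

test_that("model JSON round trip preserves weights and predictions", {
  set.seed(14)
  X <- matrix(rnorm(100 * 4), 100); y <- rbinom(100, 1, 0.5)
  m <- train_scg(X, y, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_mlp_json(m, f)
  m2 <- read_mlp_json(f)
  expect_equal(predict(m2, X)$score, predict(m, X)$score,
               tolerance = 1e-12)
})

test_that("training rejects invalid input", {
  X <- matrix(c(1, NA, 3, 4), 2)
  expect_error(train_scg(X, c(0, 1)), "non-finite")
  expect_error(train_scg(matrix(rnorm(20), 10), rep(1, 10)), "both classes")
})
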