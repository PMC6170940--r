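#' Stratified holdout split
#'
#' Disjoint, exhaustive train/test partition of row indices; with
#' stratification, per-class proportions are preserved to within one row.
#'
#' @param labels Integer vector of 0/1 row labels.
#' @param train_fraction Training proportion (default 0.7).
#' @param stratified Preserve class proportions (default TRUE).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List with integer index vectors `train` and `test`.
#' @export
holdout_split <- function(labels, train_fraction = 0.7, stratified = TRUE,
                          seed = 1L) {
  n <- length(labels)
  if (n < 10L) stop("need at least 10 rows to split")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  set.seed(seed)
  if (stratified) {
    train <- integer(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      k <- round(train_fraction * length(idx))
      k <- max(1L, min(length(idx) - 1L, k))
      train <- c(train, sample(idx, k))
    }
  } else {
    train <- sample.int(n, round(train_fraction * n))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

# per-feature affine map onto [-1, 1], fitted on training rows only
fit_scaler <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  halfrange <- (hi - lo) / 2
  halfrange[halfrange <= 0] <- 1
  list(center = (hi + lo) / 2, halfrange = halfrange)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$halfrange, "/")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_unpack <- function(w, d, h) {
  i <- 0L
  W1 <- matrix(w[i + seq_len(d * h)], d, h); i <- i + d * h
  b1 <- w[i + seq_len(h)]; i <- i + h
  w2 <- w[i + seq_len(h)]; i <- i + h
  b2 <- w[i + 1L]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

mlp_forward <- function(w, X, d, h) {
  p <- mlp_unpack(w, d, h)
  H <- tanh(sweep(X %*% p$W1, 2, p$b1, "+"))
  list(score = as.numeric(sigmoid(H %*% p$w2 + p$b2)), H = H, par = p)
}

# MSE loss E = 0.5 * mean((o - t)^2) and its analytic gradient
mlp_loss_grad <- function(w, X, t, d, h) {
  fw <- mlp_forward(w, X, d, h)
  o <- fw$score
  r <- o - t
  n <- length(t)
  loss <- 0.5 * mean(r^2)
  delta_o <- r * o * (1 - o) / n
  g_w2 <- as.numeric(crossprod(fw$H, delta_o))
  g_b2 <- sum(delta_o)
  delta_h <- (delta_o %o% fw$par$w2) * (1 - fw$H^2)
  g_W1 <- crossprod(X, delta_h)
  g_b1 <- colSums(delta_h)
  list(loss = loss, grad = c(as.numeric(g_W1), g_b1, g_w2, g_b2))
}

# Scaled conjugate gradient (Moller 1993): conjugate directions with a
# Hessian-free curvature estimate and Levenberg-Marquardt style lambda
# scaling; no line search. fn(w) must return list(loss, grad).
# on_epoch(k, w, loss) may return TRUE to stop early.
scg_optimize <- function(fn, w0, max_iter = 200L, sigma0 = 5e-5,
                         lambda0 = 1e-6, grad_tol = 1e-8,
                         on_epoch = NULL) {
  w <- w0
  np <- length(w)
  ev <- fn(w)
  fw <- ev$loss
  r <- -ev$grad
  p <- r
  lambda <- lambda0; lambda_bar <- 0
  success <- TRUE
  delta <- 0; mu <- 0
  for (k in seq_len(max_iter)) {
    if (success) {
      mu <- sum(p * r)
      pn2 <- sum(p * p)
      if (pn2 <= grad_tol^2) break
      sg <- sigma0 / sqrt(pn2)
      gplus <- fn(w + sg * p)$grad
      s <- (gplus - (-r)) / sg          # -r is the current gradient
      delta <- sum(p * s)
    }
    pn2 <- sum(p * p)
    delta_k <- delta + (lambda - lambda_bar) * pn2
    if (delta_k <= 0) {
      lambda_bar <- 2 * (lambda - delta_k / pn2)
      delta_k <- -delta_k + lambda * pn2
      lambda <- lambda_bar
    }
    alpha <- mu / delta_k
    ev2 <- fn(w + alpha * p)
    cmp <- 2 * delta_k * (fw - ev2$loss) / mu^2
    if (cmp >= 0) {
      w <- w + alpha * p
      fw <- ev2$loss
      r_new <- -ev2$grad
      lambda_bar <- 0
      success <- TRUE
      if (k %% np == 0) {
        p <- r_new
      } else {
        beta <- (sum(r_new * r_new) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (cmp >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (cmp < 0.25) lambda <- lambda + delta_k * (1 - cmp) / pn2
    if (!is.null(on_epoch) && isTRUE(on_epoch(k, w, fw))) break
    if (sqrt(sum(r * r)) < grad_tol) break
  }
  list(w = w, loss = fw)
}

#' Train the seizure classifier
#'
#' A single-hidden-layer perceptron (default 10 tanh units, logistic
#' sigmoid output) trained by scaled conjugate gradient on the mean squared
#' error against 0/1 targets. A validation slice carved from the training
#' rows drives early stopping: training halts once validation MSE has not
#' improved for `patience` epochs, and the weights of the best validation
#' epoch are returned. Features are affinely scaled to `[-1, 1]` with a
#' scaler fitted on the training rows only.
#'
#' @param X Numeric matrix of training rows (n x d).
#' @param y Integer 0/1 targets.
#' @param hidden Hidden-layer width (default 10).
#' @param max_epochs Maximum SCG iterations (default 200).
#' @param val_fraction Fraction of rows held out for early stopping
#'   (default 0.15; 0 disables early stopping).
#' @param patience Epochs without validation improvement before stopping
#'   (default 6).
#' @param seed Integer seed for the validation split and weight init;
#'   training is bit-reproducible given the seed.
#' @return An `mlp_model` with weights, scaler, per-epoch loss `trace` and
#'   `best_epoch`.
#' @export
train_scg <- function(X, y, hidden = 10L, max_epochs = 200L,
                      val_fraction = 0.15, patience = 6L, seed = 1L) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in training data")
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training rows")
  if (val_fraction < 0 || val_fraction >= 1)
    stop("val_fraction must be in [0, 1)")
  n <- nrow(X); d <- ncol(X)
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(X, scaler)

  set.seed(seed)
  if (val_fraction > 0 && n >= 10L) {
    vsp <- holdout_split(y, train_fraction = 1 - val_fraction,
                         seed = seed + 1L)
    fit_idx <- vsp$train; val_idx <- vsp$test
  } else {
    fit_idx <- seq_len(n); val_idx <- integer(0)
  }
  Xf <- Xs[fit_idx, , drop = FALSE]; yf <- y[fit_idx]
  Xv <- Xs[val_idx, , drop = FALSE]; yv <- y[val_idx]

  np <- d * hidden + hidden + hidden + 1L
  w0 <- stats::runif(np, -0.5, 0.5) / sqrt(d + 1)

  trace_epoch <- integer(0); trace_train <- numeric(0)
  trace_val <- numeric(0)
  best_val <- Inf; best_w <- w0; best_epoch <- 0L; since_best <- 0L
  has_val <- length(val_idx) > 0L

  on_epoch <- function(k, w, loss) {
    trace_epoch[[length(trace_epoch) + 1L]] <<- k
    trace_train[[length(trace_train) + 1L]] <<- loss
    vloss <- if (has_val) {
      o <- mlp_forward(w, Xv, d, hidden)$score
      0.5 * mean((o - yv)^2)
    } else loss
    trace_val[[length(trace_val) + 1L]] <<- vloss
    if (vloss < best_val - 1e-12) {
      best_val <<- vloss; best_w <<- w; best_epoch <<- k; since_best <<- 0L
    } else {
      since_best <<- since_best + 1L
    }
    has_val && since_best >= patience
  }

  fn <- function(w) mlp_loss_grad(w, Xf, yf, d, hidden)
  res <- scg_optimize(fn, w0, max_iter = max_epochs, on_epoch = on_epoch)
  w_final <- if (has_val) best_w else res$w
  if (!has_val) best_epoch <- length(trace_epoch)

  par <- mlp_unpack(w_final, d, hidden)
  structure(list(
    W1 = par$W1, b1 = par$b1, w2 = par$w2, b2 = par$b2,
    hidden = hidden, d = d, scaler = scaler,
    feature_names = colnames(X),
    trace = data.frame(epoch = trace_epoch, train_mse = trace_train,
                       val_mse = trace_val),
    best_epoch = best_epoch, seed = seed
  ), class = "mlp_model")
}

#' Predict with a trained classifier
#'
#' @param object An `mlp_model` from [train_scg()].
#' @param newdata Numeric matrix of rows to score (n x d).
#' @param ... Unused.
#' @return Data frame with `score` in `[0, 1]` (sigmoid output) and `label`
#'   in `{0, 1}` (`1` iff score strictly exceeds 0.5).
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$d)
    stop(sprintf("model expects %d features, got %d", object$d, ncol(X)))
  Xs <- apply_scaler(X, object$scaler)
  H <- tanh(sweep(Xs %*% object$W1, 2, object$b1, "+"))
  score <- as.numeric(sigmoid(H %*% object$w2 + object$b2))
  data.frame(score = score, label = as.integer(score > 0.5))
}

#' Serialize / load a classifier as JSON
#'
#' @param model An `mlp_model`.
#' @param path JSON file path.
#' @return `path` invisibly / the restored `mlp_model`.
#' @export
write_mlp_json <- function(model, path) {
  obj <- unclass(model)
  obj$W1 <- as.vector(obj$W1)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mlp_json
#' @export
read_mlp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$W1 <- matrix(obj$W1, obj$d, obj$hidden)
  obj$scaler <- list(center = as.numeric(obj$scaler$center),
                     halfrange = as.numeric(obj$scaler$halfrange))
  structure(obj, class = "mlp_model")
}
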