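#' Training configuration for the prediction modes
#'
#' The `default` mode trains one gradient-boosted tree classifier per
#' polymer (precision-oriented); the `sensitive` mode trains one shallow
#' neural network per polymer (single hidden layer, dropout, early
#' stopping, positive-class weighting; recall-oriented).  Hyperparameters
#' are selected by grid search on an internal validation split.
#'
#' @param mode `"default"` or `"sensitive"`.
#' @param hidden_units hidden-layer width (sensitive mode).
#' @param dropout_rate hidden-layer dropout probability in `[0, 1)`.
#' @param max_epochs maximum training epochs (sensitive mode).
#' @param patience early-stopping patience in epochs (< `max_epochs`).
#' @param validation_fraction fraction of training rows held out for
#'   hyperparameter selection and early stopping.
#' @param learning_rate optimizer step size (sensitive mode).
#' @param batch_size minibatch size (sensitive mode).
#' @param nrounds boosting rounds (default mode).
#' @param grid `data.frame` of hyperparameter candidates; `NULL` uses the
#'   built-in grid (default mode: `max_depth` x `eta`; sensitive mode:
#'   `hidden_units` x `dropout_rate`).
#' @param seed RNG seed; training is deterministic given the seed.
#' @return a list of class `train_config`.
#' @export
train_config <- function(mode = c("default", "sensitive"),
                         hidden_units = 128L, dropout_rate = 0.3,
                         max_epochs = 200L, patience = 10L,
                         validation_fraction = 0.1, learning_rate = 0.01,
                         batch_size = 32L, nrounds = 60L, grid = NULL,
                         seed = 42L) {
  mode <- match.arg(mode)
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate in [0, 1)")
  if (patience >= max_epochs) stop("patience must be < max_epochs")
  if (is.null(grid)) {
    grid <- if (mode == "default") {
      expand.grid(max_depth = c(3L, 5L, 7L), eta = c(0.05, 0.1, 0.3))
    } else {
      expand.grid(hidden_units = c(64L, 128L), dropout_rate = c(0.2, 0.3))
    }
  }
  structure(list(mode = mode, hidden_units = hidden_units,
                 dropout_rate = dropout_rate, max_epochs = max_epochs,
                 patience = patience,
                 validation_fraction = validation_fraction,
                 learning_rate = learning_rate, batch_size = batch_size,
                 nrounds = nrounds, grid = grid, seed = as.integer(seed)),
            class = "train_config")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

logloss <- function(y, p, w = rep(1, length(y))) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
}

# stratified validation indices, deterministic given seed
val_split <- function(y, fraction, seed) {
  set.seed(seed)
  idx_pos <- which(y == 1); idx_neg <- which(y == 0)
  n_vp <- max(1L, floor(fraction * length(idx_pos)))
  n_vn <- max(1L, floor(fraction * length(idx_neg)))
  val <- c(sample(idx_pos, n_vp), sample(idx_neg, n_vn))
  sort(val)
}

# ---- sensitive mode: single-hidden-layer network ------------------------

nn_init <- function(d, h, seed) {
  set.seed(seed)
  s1 <- sqrt(6 / (d + h)); s2 <- sqrt(6 / (h + 1))
  list(W1 = matrix(runif(d * h, -s1, s1), d, h), b1 = rep(0, h),
       W2 = matrix(runif(h, -s2, s2), h, 1), b2 = 0)
}

nn_forward <- function(par, X) {
  H <- pmax(X %*% par$W1 + rep(par$b1, each = nrow(X)), 0)
  drop(sigmoid(H %*% par$W2 + par$b2))
}

nn_train <- function(X, y, hidden, dropout, lr, batch, max_epochs,
                     patience, pos_weight, val_idx, seed) {
  d <- ncol(X)
  par <- nn_init(d, hidden, seed)
  adam <- lapply(par, function(p) list(m = p * 0, v = p * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0
  Xtr <- X[-val_idx, , drop = FALSE]; ytr <- y[-val_idx]
  Xva <- X[val_idx, , drop = FALSE]; yva <- y[val_idx]
  wva <- ifelse(yva == 1, pos_weight, 1)
  best <- list(loss = Inf, par = par, epoch = 0L)
  wait <- 0L
  set.seed(seed + 1L)
  for (epoch in seq_len(max_epochs)) {
    ord <- sample(nrow(Xtr))
    for (b0 in seq(1, length(ord), by = batch)) {
      idx <- ord[b0:min(b0 + batch - 1L, length(ord))]
      Xb <- Xtr[idx, , drop = FALSE]; yb <- ytr[idx]
      nb <- length(idx)
      wb <- ifelse(yb == 1, pos_weight, 1)
      Z1 <- Xb %*% par$W1 + rep(par$b1, each = nb)
      H <- pmax(Z1, 0)
      if (dropout > 0) {
        mask <- matrix(rbinom(nb * hidden, 1, 1 - dropout), nb, hidden) /
          (1 - dropout)
        H <- H * mask
      }
      p <- drop(sigmoid(H %*% par$W2 + par$b2))
      # gradient of weighted BCE
      gz <- wb * (p - yb) / sum(wb)
      gW2 <- t(H) %*% gz
      gb2 <- sum(gz)
      gH <- outer(gz, drop(par$W2))
      if (dropout > 0) gH <- gH * mask
      gZ1 <- gH * (Z1 > 0)
      gW1 <- t(Xb) %*% gZ1
      gb1 <- colSums(gZ1)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      t_step <- t_step + 1
      for (nm in names(par)) {
        adam[[nm]]$m <- beta1 * adam[[nm]]$m + (1 - beta1) * grads[[nm]]
        adam[[nm]]$v <- beta2 * adam[[nm]]$v + (1 - beta2) * grads[[nm]]^2
        mhat <- adam[[nm]]$m / (1 - beta1^t_step)
        vhat <- adam[[nm]]$v / (1 - beta2^t_step)
        par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    vloss <- logloss(yva, nn_forward(par, Xva), wva)
    if (vloss < best$loss - 1e-9) {
      best <- list(loss = vloss, par = par, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(par = best$par, val_loss = best$loss, epochs_run = epoch,
       best_epoch = best$epoch)
}

# ---- default mode: gradient-boosted trees -------------------------------

xgb_fit <- function(X, y, max_depth, eta, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(data = X, label = y)
  params <- list(objective = "binary:logistic", eval_metric = "logloss",
                 max_depth = max_depth, eta = eta, nthread = 1,
                 seed = seed)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

xgb_predict <- function(booster, X) {
  predict(booster, xgboost::xgb.DMatrix(data = X))
}

# ---- public surface -----------------------------------------------------

#' Train the per-polymer plastizyme classifiers
#'
#' Trains one independent binary probabilistic classifier per polymer
#' column (one-vs-rest; multi-label inputs allowed).  Hyperparameters are
#' chosen on an internal stratified validation split by log loss, then
#' the selected configuration is refit.  Deterministic given
#' `config$seed`.
#'
#' @param X n x d numeric embedding matrix.
#' @param Y n x k 0/1 label matrix, one column per polymer.
#' @param config a [train_config()] object.
#' @param embedder_name name of the embedder that produced `X`; recorded
#'   in the model and checked at prediction time.
#' @return an object of class `plastizyme_classifier`.
#' @export
train_classifier <- function(X, Y, config = train_config(),
                             embedder_name = "onehot-physchem-v1") {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) < 20L) stop("need at least 20 training examples")
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ")
  polymers <- colnames(Y)
  if (is.null(polymers)) stop("Y must have polymer column names")
  for (p in polymers) {
    if (sum(Y[, p] == 1) == 0L) stop("no positive examples for polymer ", p)
    if (sum(Y[, p] == 0) == 0L) stop("no negative examples for polymer ", p)
  }
  models <- list(); chosen <- list()
  for (ci in seq_along(polymers)) {
    p <- polymers[ci]
    y <- Y[, ci]
    seed_p <- config$seed + ci
    val_idx <- val_split(y, config$validation_fraction, seed_p)
    grid <- config$grid
    best <- list(loss = Inf, row = 1L)
    for (g in seq_len(nrow(grid))) {
      if (config$mode == "default") {
        fit <- xgb_fit(X[-val_idx, , drop = FALSE], y[-val_idx],
                       grid$max_depth[g], grid$eta[g], config$nrounds,
                       seed_p)
        vloss <- logloss(y[val_idx],
                         xgb_predict(fit, X[val_idx, , drop = FALSE]))
      } else {
        pos_w <- sum(y == 0) / max(1, sum(y == 1))
        fit <- nn_train(X, y, grid$hidden_units[g], grid$dropout_rate[g],
                        config$learning_rate, config$batch_size,
                        config$max_epochs, config$patience, pos_w,
                        val_idx, seed_p)
        vloss <- fit$val_loss
      }
      if (vloss < best$loss) best <- list(loss = vloss, row = g)
    }
    g <- best$row
    if (config$mode == "default") {
      final <- xgb_fit(X, y, grid$max_depth[g], grid$eta[g],
                       config$nrounds, seed_p)
    } else {
      pos_w <- sum(y == 0) / max(1, sum(y == 1))
      final <- nn_train(X, y, grid$hidden_units[g], grid$dropout_rate[g],
                        config$learning_rate, config$batch_size,
                        config$max_epochs, config$patience, pos_w,
                        val_idx, seed_p)
    }
    models[[p]] <- final
    chosen[[p]] <- grid[g, , drop = FALSE]
  }
  structure(list(mode = config$mode, polymers = polymers,
                 embedder_name = embedder_name, dim = ncol(X),
                 models = models, hyperparams = chosen,
                 seed = config$seed),
            class = "plastizyme_classifier")
}

#' Predict per-polymer plastizyme probabilities
#'
#' @param model a `plastizyme_classifier`.
#' @param X n x d embedding matrix (same embedder and dimension as used
#'   in training).
#' @return an n x k matrix of probabilities in `[0, 1]`, one column per
#'   polymer; row order preserved.
#' @export
predict_scores <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$dim) {
    stop("embedding dimension ", ncol(X), " does not match model (",
         model$dim, ")")
  }
  en <- attr(X, "embedder_name")
  if (!is.null(en) && !identical(en, model$embedder_name)) {
    stop("embeddings from '", en, "' but model trained on '",
         model$embedder_name, "'")
  }
  out <- vapply(model$polymers, function(p) {
    if (model$mode == "default") xgb_predict(model$models[[p]], X)
    else nn_forward(model$models[[p]]$par, X)
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) out <- matrix(out, nrow = 1L,
                                   dimnames = list(NULL, model$polymers))
  rownames(out) <- rownames(X)
  out
}

#' Threshold prediction scores
#'
#' Strictly-greater comparison: a score equal to the threshold is
#' negative.  Use 0.5 for benchmarking and 0.7 for high-confidence
#' reporting.
#'
#' @param scores numeric matrix (or vector) of probabilities.
#' @param threshold decision threshold in `(0, 1)`.
#' @return logical matrix of the same shape.
#' @export
classify <- function(scores, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  scores > threshold
}

#' Save / load a trained classifier
#'
#' The archive records the embedder name; [load_model()] refuses an
#' archive whose embedder does not match `expect_embedder`.
#'
#' @param model a `plastizyme_classifier`.
#' @param path archive path.
#' @param expect_embedder optional embedder name to enforce on load.
#' @return `path` / the model.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "plastizymr-model-v1", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path, expect_embedder = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format, "plastizymr-model-v1")) {
    stop("not a plastizymr model archive")
  }
  m <- obj$model
  if (!is.null(expect_embedder) &&
      !identical(m$embedder_name, expect_embedder)) {
    stop("model trained with embedder '", m$embedder_name,
         "' but '", expect_embedder, "' requested")
  }
  m
}
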