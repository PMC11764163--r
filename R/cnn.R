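# A compact 1D convolutional network written directly in R (matrix algebra
# plus hand-derived backpropagation). Architecture, fixed by design:
#   Conv1D(filters, kernel, ReLU) -> MaxPool(pool) -> Dropout ->
#   Flatten -> Dense(units, ReLU) -> Dense(1, sigmoid)
# trained with Adam on binary cross-entropy. The convolution runs along the
# feature axis of each sample.

#' Classifier configuration
#'
#' Defaults: 64 convolution filters of kernel size 3 with ReLU, max-pooling
#' of size 2, dropout 0.5, a 100-unit dense ReLU layer and a sigmoid output;
#' binary cross-entropy with Adam, at most 10 epochs with batch size 10, a
#' 20% validation split and early stopping after 5 epochs without validation
#' accuracy improvement; 80/20 train/test.
#'
#' @param conv_filters,kernel_size,pool_size,dropout,dense_units Architecture.
#' @param epochs,batch_size,validation_split,early_stop_patience,learning_rate
#'   Optimisation.
#' @param test_fraction Held-out fraction used when a split is created
#'   implicitly.
#' @param seed Integer seed.
#' @return Object of class `leida_cnn_config`.
#' @export
cnn_config <- function(conv_filters = 64, kernel_size = 3, pool_size = 2,
                       dropout = 0.5, dense_units = 100, epochs = 10,
                       batch_size = 10, validation_split = 0.2,
                       early_stop_patience = 5, learning_rate = 1e-3,
                       test_fraction = 0.2, seed = 1) {
  stopifnot(conv_filters >= 1, kernel_size >= 1, pool_size >= 1,
            dropout >= 0, dropout < 1, dense_units >= 1, epochs >= 1,
            batch_size >= 1, validation_split > 0, validation_split < 1,
            test_fraction > 0, test_fraction < 1, early_stop_patience >= 1)
  structure(as.list(environment()), class = "leida_cnn_config")
}

cnn_dims <- function(n_features, config) {
  f_out <- n_features - config$kernel_size + 1
  if (f_out < 1) stop("parameter error: kernel wider than the feature vector")
  p_out <- f_out %/% config$pool_size
  if (p_out < 1) stop("parameter error: no positions left after pooling")
  list(f_out = f_out, p_out = p_out,
       flat = p_out * config$conv_filters)
}

cnn_init_params <- function(n_features, config) {
  d <- cnn_dims(n_features, config)
  he <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  list(W1 = he(config$kernel_size, config$conv_filters, config$kernel_size),
       b1 = numeric(config$conv_filters),
       W2 = he(d$flat, config$dense_units, d$flat),
       b2 = numeric(config$dense_units),
       W3 = he(config$dense_units, 1, config$dense_units),
       b3 = numeric(1))
}

# Forward pass. X: B x F. Returns predictions and (if wanted) intermediates.
cnn_forward <- function(params, X, config, drop_mask = NULL,
                        keep_cache = FALSE) {
  B <- nrow(X)
  d <- cnn_dims(ncol(X), config)
  ker <- config$kernel_size
  # im2col: M1[(b, i), j] = X[b, i + j - 1], column-major in (b, i)
  M1 <- matrix(0, B * d$f_out, ker)
  for (j in seq_len(ker)) {
    M1[, j] <- as.vector(X[, j:(j + d$f_out - 1), drop = FALSE])
  }
  Z1 <- sweep(M1 %*% params$W1, 2, params$b1, "+")
  H1 <- pmax(Z1, 0)
  # max-pool pairs of positions (pool_size == 2 is the architecture default;
  # general pool handled by comparing the pool members)
  pool <- config$pool_size
  pooled_rows <- function(p, r) (p - 1) * pool * B + (r - 1) * B + seq_len(B)
  H2 <- matrix(-Inf, B * d$p_out, ncol(H1))
  argmax <- matrix(1L, B * d$p_out, ncol(H1))
  for (r in seq_len(pool)) {
    rows <- as.vector(vapply(seq_len(d$p_out), pooled_rows, numeric(B), r = r))
    cand <- H1[rows, , drop = FALSE]
    upd <- cand > H2
    argmax[upd] <- r
    H2[upd] <- cand[upd]
  }
  if (!is.null(drop_mask)) {
    keep <- 1 - config$dropout
    H2d <- H2 * drop_mask / keep
  } else {
    H2d <- H2
  }
  Hf <- matrix(as.vector(H2d), nrow = B)   # B x (p_out * filters)
  Z2 <- sweep(Hf %*% params$W2, 2, params$b2, "+")
  H3 <- pmax(Z2, 0)
  z3 <- as.vector(H3 %*% params$W3 + params$b3)
  p <- 1 / (1 + exp(-z3))
  out <- list(p = p)
  if (keep_cache) {
    out$cache <- list(M1 = M1, Z1 = Z1, H2 = H2, argmax = argmax,
                      drop_mask = drop_mask, Hf = Hf, Z2 = Z2, H3 = H3,
                      B = B, d = d)
  }
  out
}

# Binary cross-entropy loss and full gradients.
cnn_loss_grads <- function(params, X, y, config, drop_mask = NULL) {
  fw <- cnn_forward(params, X, config, drop_mask = drop_mask,
                    keep_cache = TRUE)
  cache <- fw$cache
  B <- cache$B; d <- cache$d
  eps <- 1e-12
  p <- pmin(pmax(fw$p, eps), 1 - eps)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  dz3 <- matrix((p - y) / B, ncol = 1)
  gW3 <- crossprod(cache$H3, dz3)
  gb3 <- sum(dz3)
  dH3 <- dz3 %*% t(params$W3)
  dZ2 <- dH3 * (cache$Z2 > 0)
  gW2 <- crossprod(cache$Hf, dZ2)
  gb2 <- colSums(dZ2)
  dHf <- dZ2 %*% t(params$W2)
  dH2d <- matrix(as.vector(dHf), nrow = B * d$p_out)
  if (!is.null(drop_mask)) {
    dH2 <- dH2d * drop_mask / (1 - config$dropout)
  } else {
    dH2 <- dH2d
  }
  # scatter pooled gradients back to the argmax positions
  pool <- config$pool_size
  dH1 <- matrix(0, B * d$f_out, config$conv_filters)
  for (r in seq_len(pool)) {
    rows <- as.vector(vapply(seq_len(d$p_out),
                             function(p2) (p2 - 1) * pool * B + (r - 1) * B + seq_len(B),
                             numeric(B)))
    sel <- cache$argmax == r
    tmp <- matrix(0, B * d$p_out, config$conv_filters)
    tmp[sel] <- dH2[sel]
    dH1[rows, ] <- dH1[rows, ] + tmp
  }
  dZ1 <- dH1 * (cache$Z1 > 0)
  gW1 <- crossprod(cache$M1, dZ1)
  gb1 <- colSums(dZ1)
  list(loss = loss, p = fw$p,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = as.matrix(gW3), b3 = gb3))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the 1D CNN classifier
#'
#' Standardises features using training-split statistics only, carves a
#' validation set out of the training split, trains with Adam on binary
#' cross-entropy for at most `config$epochs` epochs with early stopping on
#' validation accuracy (patience `config$early_stop_patience`, best weights
#' restored), and reports test accuracy at threshold 0.5.
#'
#' @param features A `leida_features`.
#' @param config A [cnn_config()].
#' @param split A `leida_split`; if `NULL`, a group-aware split is created
#'   from `config$test_fraction` and `config$seed`.
#' @return Object of class `leida_cnn`: `test_accuracy`, `history` (per-epoch
#'   train loss/accuracy and validation accuracy), `params`, `scaler`,
#'   `config`, `split`, `best_epoch`, `stopped_epoch`.
#' @export
train_cnn <- function(features, config = cnn_config(), split = NULL) {
  if (is.null(split)) {
    split <- split_data(features, test_fraction = config$test_fraction,
                        seed = config$seed, group_aware = TRUE)
  }
  X <- features$x; y <- features$y
  if (length(split$train) < config$batch_size) {
    stop("parameter error: fewer training samples than the batch size")
  }
  mu <- colMeans(X[split$train, , drop = FALSE])
  sdv <- apply(X[split$train, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  set.seed(derive_seed(config$seed, "cnn-train"))
  # validation carve-out from the training split
  tr <- split$train
  n_val <- max(1L, round(length(tr) * config$validation_split))
  val_idx <- sample(tr, n_val)
  fit_idx <- setdiff(tr, val_idx)
  if (length(fit_idx) < config$batch_size) {
    stop("parameter error: fewer training samples than the batch size")
  }
  params <- cnn_init_params(ncol(X), config)
  state <- adam_init(params)
  best <- list(acc = -Inf, params = params, epoch = 0L)
  history <- list()
  wait <- 0L
  stopped <- config$epochs
  for (ep in seq_len(config$epochs)) {
    ord <- sample(fit_idx)
    losses <- c(); correct <- 0L
    nb <- length(ord) %/% config$batch_size
    for (b in seq_len(max(1L, nb))) {
      rows <- ord[((b - 1) * config$batch_size + 1):
                    min(b * config$batch_size, length(ord))]
      Xb <- Xs[rows, , drop = FALSE]
      yb <- y[rows]
      d <- cnn_dims(ncol(X), config)
      drop_mask <- if (config$dropout > 0) {
        matrix(stats::runif(nrow(Xb) * d$p_out * config$conv_filters) >=
                 config$dropout, nrow(Xb) * d$p_out, config$conv_filters)
      } else NULL
      lg <- cnn_loss_grads(params, Xb, yb, config, drop_mask = drop_mask)
      upd <- adam_step(params, lg$grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      losses <- c(losses, lg$loss)
      correct <- correct + sum((lg$p >= 0.5) == (yb == 1))
    }
    val_p <- cnn_forward(params, Xs[val_idx, , drop = FALSE], config)$p
    val_acc <- mean((val_p >= 0.5) == (y[val_idx] == 1))
    history[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                                train_acc = correct / (max(1L, nb) * config$batch_size),
                                val_acc = val_acc)
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, params = params, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) { stopped <- ep; break }
    }
  }
  params <- best$params
  test_p <- cnn_forward(params, Xs[split$test, , drop = FALSE], config)$p
  test_acc <- mean((test_p >= 0.5) == (y[split$test] == 1))
  structure(list(test_accuracy = test_acc,
                 history = do.call(rbind, history),
                 params = params, scaler = list(mean = mu, sd = sdv),
                 config = config, split = split,
                 best_epoch = best$epoch, stopped_epoch = stopped,
                 kind = features$kind),
            class = "leida_cnn")
}

#' Predict condition probabilities with a trained CNN
#' @param model A `leida_cnn`.
#' @param x New samples (M x F matrix on the original feature scale).
#' @return Numeric vector of P(condition B) in \[0, 1\].
#' @export
predict_cnn <- function(model, x) {
  xs <- sweep(sweep(x, 2, model$scaler$mean), 2, model$scaler$sd, "/")
  cnn_forward(model$params, xs, model$config)$p
}

#' @export
print.leida_cnn <- function(x, ...) {
  cat(sprintf("<leida_cnn> %s features: test accuracy %.3f (best epoch %d)\n",
              x$kind %||% "?", x$test_accuracy, x$best_epoch))
  invisible(x)
}

#' Compare the three feature sets
#'
#' Trains the CNN on each feature kind over several seeds and tabulates mean
#' and sd of test accuracy, reproducing the qualitative ranking analysis
#' (leading eigenvectors vs flattened dPL vs raw signals).
#'
#' @param feature_sets Named list with elements `raw`, `dpl_flat`,
#'   `eigenvector` (each a `leida_features`).
#' @param config A [cnn_config()]; its seed is combined with the run index.
#' @param n_seeds Number of training repetitions per kind.
#' @param group_aware Split mode passed to [split_data()].
#' @return Data frame: kind, mean_accuracy, sd_accuracy, n_seeds.
#' @export
compare_feature_sets <- function(feature_sets, config = cnn_config(),
                                 n_seeds = 5, group_aware = TRUE) {
  stopifnot(all(c("raw", "dpl_flat", "eigenvector") %in% names(feature_sets)))
  rows <- lapply(c("raw", "dpl_flat", "eigenvector"), function(kind) {
    accs <- vapply(seq_len(n_seeds), function(i) {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, paste0(kind, "-rep-", i))
      sp <- split_data(feature_sets[[kind]], test_fraction = cfg$test_fraction,
                       seed = cfg$seed, group_aware = group_aware)
      train_cnn(feature_sets[[kind]], cfg, sp)$test_accuracy
    }, numeric(1))
    data.frame(kind = kind, mean_accuracy = mean(accs),
               sd_accuracy = stats::sd(accs), n_seeds = n_seeds)
  })
  do.call(rbind, rows)
}
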