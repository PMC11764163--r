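tiny_config <- function(epochs = 8, ...) {
  cnn_config(conv_filters = 4, kernel_size = 3, dense_units = 6,
             epochs = epochs, batch_size = 4, dropout = 0, ...)
}

test_that("layer dimensions follow the architecture arithmetic", {
  cfg <- cnn_config(conv_filters = 64, kernel_size = 3, pool_size = 2)
  d <- leidar:::cnn_dims(10, cfg)
  expect_identical(d$f_out, 8)
  expect_identical(d$p_out, 4)
  expect_identical(d$flat, 256)
  expect_error(leidar:::cnn_dims(2, cfg), "kernel wider")
})

test_that("forward pass matches a direct loop computation", {
  set.seed(51)
  cfg <- tiny_config()
  X <- matrix(rnorm(3 * 9), 3, 9)
  params <- leidar:::cnn_init_params(ncol(X), cfg)
  p <- leidar:::cnn_forward(params, X, cfg)$p
  # direct per-sample computation
  for (b in 1:3) {
    f_out <- 9 - 3 + 1
    conv <- matrix(0, f_out, 4)
    for (i in seq_len(f_out)) {
      conv[i, ] <- pmax(X[b, i:(i + 2)] %*% params$W1 + params$b1, 0)
    }
    pooled <- matrix(0, f_out %/% 2, 4)
    for (i in seq_len(nrow(pooled))) {
      pooled[i, ] <- pmax(conv[2 * i - 1, ], conv[2 * i, ])
    }
    flat <- as.vector(pooled)   # position-major, matching the flatten layer
    h <- pmax(flat %*% params$W2 + params$b2, 0)
    z <- as.vector(h %*% params$W3 + params$b3)
    expect_equal(p[b], 1 / (1 + exp(-z)), tolerance = 1e-12)
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(52)
  cfg <- tiny_config()
  X <- matrix(rnorm(5 * 8), 5, 8)
  y <- c(0, 1, 1, 0, 1)
  params <- leidar:::cnn_init_params(ncol(X), cfg)
  lg <- leidar:::cnn_loss_grads(params, X, y, cfg)
  eps <- 1e-6
  for (nm in names(params)) {
    theta <- params[[nm]]
    # probe a handful of coordinates per tensor
    coords <- sample(length(theta), min(5, length(theta)))
    for (ix in coords) {
      pp <- params; pp[[nm]][ix] <- theta[ix] + eps
      pm <- params; pm[[nm]][ix] <- theta[ix] - eps
      num <- (leidar:::cnn_loss_grads(pp, X, y, cfg)$loss -
                leidar:::cnn_loss_grads(pm, X, y, cfg)$loss) / (2 * eps)
      expect_equal(as.vector(lg$grads[[nm]])[ix], num, tolerance = 1e-4)
    }
  }
})

test_that("dropout masks rescale activations to preserve expectation", {
  set.seed(53)
  cfg <- cnn_config(conv_filters = 4, kernel_size = 3, dense_units = 6,
                    dropout = 0.5)
  X <- matrix(rnorm(2 * 9), 2, 9)
  params <- leidar:::cnn_init_params(ncol(X), cfg)
  d <- leidar:::cnn_dims(ncol(X), cfg)
  full <- leidar:::cnn_forward(params, X, cfg, keep_cache = TRUE)
  ones <- matrix(TRUE, nrow(X) * d$p_out, cfg$conv_filters)
  dropped <- leidar:::cnn_forward(params, X, cfg, drop_mask = ones,
                                  keep_cache = TRUE)
  # an all-keep mask halves nothing but applies the 1/keep rescale
  expect_equal(dropped$cache$Hf, full$cache$Hf * 2, tolerance = 1e-12)
})

test_that("training separates a linearly separable toy problem", {
  set.seed(54)
  n <- 120
  X <- rbind(matrix(rnorm(n * 8, mean = -1), n, 8),
             matrix(rnorm(n * 8, mean = 1), n, 8))
  f <- structure(list(kind = "raw", x = X, y = rep(0:1, each = n),
                      group = rep(sprintf("S%02d", 1:12), times = 20),
                      time = seq_len(2 * n), n_channels = 8),
                 class = "leida_features")
  cfg <- tiny_config(seed = 2)
  model <- train_cnn(f, cfg)
  expect_gt(model$test_accuracy, 0.9)
  expect_s3_class(model, "leida_cnn")
  expect_true(all(c("epoch", "train_loss", "val_acc") %in%
                    colnames(model$history)))
  # training history loss decreases overall
  expect_lt(tail(model$history$train_loss, 1), model$history$train_loss[1])
  # prediction API agrees with the stored test accuracy
  p <- predict_cnn(model, f$x[model$split$test, ])
  acc <- mean((p >= 0.5) == (f$y[model$split$test] == 1))
  expect_identical(acc, model$test_accuracy)
})

test_that("training is deterministic given the seed", {
  set.seed(55)
  X <- matrix(rnorm(80 * 7), 80, 7)
  y <- as.integer(X[, 1] + X[, 2] > 0)
  f <- structure(list(kind = "raw", x = X, y = y,
                      group = rep(sprintf("S%02d", 1:8), each = 10),
                      time = 1:80, n_channels = 7),
                 class = "leida_features")
  cfg <- tiny_config(seed = 7, epochs = 3)
  m1 <- train_cnn(f, cfg)
  m2 <- train_cnn(f, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$test_accuracy, m2$test_accuracy)
})

test_that("early stopping halts after patience epochs without improvement", {
  set.seed(56)
  # pure-noise labels: validation accuracy cannot improve systematically
  X <- matrix(rnorm(100 * 6), 100, 6)
  y <- rep(0:1, 50)
  f <- structure(list(kind = "raw", x = X, y = y,
                      group = rep(sprintf("S%02d", 1:10), each = 10),
                      time = 1:100, n_channels = 6),
                 class = "leida_features")
  cfg <- cnn_config(conv_filters = 2, kernel_size = 2, dense_units = 2,
                    dropout = 0, epochs = 50, batch_size = 10,
                    early_stop_patience = 3, seed = 3)
  m <- train_cnn(f, cfg)
  expect_lte(m$stopped_epoch, 50)
  expect_lte(m$stopped_epoch - m$best_epoch, 3 + 1)
  expect_identical(nrow(m$history), as.integer(m$stopped_epoch))
})

test_that("compare_feature_sets tabulates all three kinds", {
  set.seed(57)
  mk <- function() {
    X <- matrix(rnorm(60 * 6), 60, 6)
    structure(list(kind = "raw", x = X,
                   y = rep(0:1, each = 30),
                   group = rep(sprintf("S%02d", 1:6), times = 10),
                   time = 1:60, n_channels = 6),
              class = "leida_features")
  }
  fsets <- list(raw = mk(), dpl_flat = mk(), eigenvector = mk())
  cfg <- cnn_config(conv_filters = 2, kernel_size = 2, dense_units = 2,
                    dropout = 0, epochs = 1, batch_size = 5, seed = 1)
  tab <- compare_feature_sets(fsets, cfg, n_seeds = 2)
  expect_identical(tab$kind, c("raw", "dpl_flat", "eigenvector"))
  expect_identical(tab$n_seeds, rep(2, 3))
  expect_true(all(tab$mean_accuracy >= 0 & tab$mean_accuracy <= 1))
})
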