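# Activations, balanced batches, training with early stopping, prediction,
# majority voting, and the layer gradients of the network engine.

test_that("swish and softmax evaluate their closed forms", {
  expect_equal(swish(0), 0)
  expect_equal(swish(1), 1 / (1 + exp(-1)), tolerance = 1e-7)
  expect_equal(swish(30), 30, tolerance = 1e-7)
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(2, 0)), c(exp(2), 1) / (exp(2) + 1), tolerance = 1e-9)
  expect_equal(softmax(c(3, 5)), softmax(c(3 + 11, 5 + 11)))
  expect_equal(sum(softmax(rnorm(5))), 1)
})

test_that("balanced batches hold 32 of each class and oversample the minority", {
  labels <- rep(c(0, 1), c(1000, 100))
  bt <- balanced_batches(labels, 64, seed = 5)
  expect_length(bt, ceiling(1000 / 32))
  for (b in bt) {
    expect_length(b, 64)
    expect_equal(sum(labels[b] == 0), 32)
    expect_equal(sum(labels[b] == 1), 32)
  }
  # minority samples recur across the epoch
  minority_draws <- unlist(lapply(bt, function(b) b[labels[b] == 1]))
  expect_gt(length(minority_draws), 100)
  expect_identical(bt, balanced_batches(labels, 64, seed = 5))
})

test_that("perfectly balanced input is not replicated within one epoch pass", {
  labels <- rep(c(0, 1), each = 320)
  bt <- balanced_batches(labels, 64, seed = 6)
  drawn <- unlist(bt)
  expect_equal(sort(unique(drawn)), 1:640)
  expect_false(any(duplicated(drawn)))
})

test_that("the shallow network learns a linearly separable problem", {
  withr::local_seed(415)
  n <- 400
  X <- matrix(rnorm(n * 10), n, 10)
  y <- as.integer(X[, 1] + X[, 2] > 0)
  X[, 1] <- X[, 1] + y * 2  # widen the margin
  ho <- holdout_split(y, 0.8, seed = 1)
  spec <- shallow_spec(input_len = 10)
  cfg <- train_config(epochs_max = 120, patience = 100, learning_rate = 3e-3,
                      runs = 1)
  m <- train_model(spec, X[ho$train, ], y[ho$train], X[ho$validation, ],
                   y[ho$validation], cfg, seed = 1)
  acc <- mean(predict_windows(m, X[ho$validation, ]) == y[ho$validation])
  expect_gt(acc, 0.93)
})

test_that("shuffled labels keep the validation loss near ln 2", {
  withr::local_seed(416)
  n <- 300
  X <- matrix(rnorm(n * 8), n, 8)
  y <- sample(rep(0:1, each = n / 2))
  ho <- holdout_split(y, 0.8, seed = 2)
  m <- train_model(shallow_spec(8), X[ho$train, ], y[ho$train],
                   X[ho$validation, ], y[ho$validation],
                   train_config(epochs_max = 40, patience = 40, runs = 1),
                   seed = 2)
  expect_lt(abs(m$best_val_loss - log(2)), 0.25)
})

test_that("early stopping restores the best weights and respects patience", {
  withr::local_seed(417)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5)
  y <- sample(rep(0:1, each = n / 2))  # unlearnable: validation loss stalls
  ho <- holdout_split(y, 0.8, seed = 3)
  # an aggressive learning rate makes the validation loss bounce, so the
  # stopping rule is exercised away from the epoch cap
  m <- train_model(shallow_spec(5), X[ho$train, ], y[ho$train],
                   X[ho$validation, ], y[ho$validation],
                   train_config(epochs_max = 60, patience = 0,
                                learning_rate = 0.5, runs = 1),
                   seed = 3)
  # with patience 0, training stops exactly one epoch after the best one
  expect_equal(m$epochs_ran, m$best_epoch + 1L)
  m3 <- train_model(shallow_spec(5), X[ho$train, ], y[ho$train],
                    X[ho$validation, ], y[ho$validation],
                    train_config(epochs_max = 60, patience = 3,
                                 learning_rate = 0.5, runs = 1),
                    seed = 3)
  expect_equal(m3$epochs_ran, m3$best_epoch + 3L + 1L)
  # the returned validation loss is the best seen
  fw <- preictal:::net_forward(m$layers, X[ho$validation, ], training = FALSE)
  expect_equal(preictal:::softmax_xent(fw$out, y[ho$validation])$loss,
               m$best_val_loss, tolerance = 1e-10)
})

test_that("prediction is deterministic and binary", {
  withr::local_seed(418)
  X <- matrix(rnorm(50 * 6), 50, 6)
  y <- as.integer(X[, 1] > 0)
  m <- train_model(shallow_spec(6), X, y, X, y,
                   train_config(epochs_max = 10, patience = 10, runs = 1),
                   seed = 4)
  p1 <- predict_windows(m, X)
  expect_identical(p1, predict_windows(m, X))
  expect_true(all(p1 %in% c(0L, 1L)))
})

test_that("majority vote requires odd membership and counts strict majorities", {
  votes <- matrix(0L, 31, 3)
  votes[1:16, 1] <- 1L  # 16 of 31
  votes[1:15, 2] <- 1L  # 15 of 31
  votes[, 3] <- 1L      # unanimous
  expect_equal(majority_vote(votes), c(1L, 0L, 1L))
  expect_error(majority_vote(votes[1:30, ]), "odd")
  # invariant to member ordering
  expect_equal(majority_vote(votes[sample(31), ]), c(1L, 0L, 1L))
})

numeric_grad <- function(f, w, eps = 1e-5) {
  g <- array(0, dim(w) %||% length(w))
  for (i in seq_along(w)) {
    wp <- w; wp[i] <- wp[i] + eps
    wm <- w; wm[i] <- wm[i] - eps
    g[i] <- (f(wp) - f(wm)) / (2 * eps)
  }
  g
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("deep-network layer gradients match numeric differentiation", {
  withr::local_seed(419)
  b <- 3; Tn <- 8; cin <- 2
  x <- array(rnorm(b * Tn * cin), c(b, Tn, cin))
  y <- c(0L, 1L, 1L)
  layers <- list(
    preictal:::layer_conv1d(cin, 3, kernel = 3, stride = 1),
    preictal:::layer_conv1d(3, 3, kernel = 3, stride = 2),
    preictal:::layer_swish(),
    preictal:::layer_batchnorm(3),
    preictal:::layer_bilstm(3, 4),
    preictal:::layer_dense(8, 2))
  loss_of <- function(layers, xx = x) {
    fw <- preictal:::net_forward(layers, xx, training = TRUE)
    preictal:::softmax_xent(fw$out, y)$loss
  }
  fw <- preictal:::net_forward(layers, x, training = TRUE)
  ls <- preictal:::softmax_xent(fw$out, y)
  grads <- preictal:::net_backward(fw$layers, ls$dZ, fw$caches)
  for (li in seq_along(layers)) {
    for (p in preictal:::layer_param_names(layers[[li]])) {
      f <- function(w) {
        l2 <- layers
        l2[[li]][[p]] <- w
        loss_of(l2)
      }
      ng <- numeric_grad(f, layers[[li]][[p]])
      expect_equal(unname(as.vector(grads[[li]][[p]])), unname(as.vector(ng)),
                   tolerance = 1e-4,
                   label = sprintf("grad layer %d param %s", li, p))
    }
  }
})

test_that("the compact CNN-BiLSTM trains on a separable time-series toy", {
  withr::local_seed(420)
  n <- 80; Tn <- 32; cin <- 2
  x <- array(rnorm(n * Tn * cin, sd = 0.5), c(n, Tn, cin))
  y <- rep(0:1, each = n / 2)
  tt <- seq_len(Tn)
  for (i in which(y == 1)) {
    x[i, , 1] <- x[i, , 1] + 2 * sin(2 * pi * tt / 8)
  }
  spec <- deep_spec(input_shape = c(Tn, cin), blocks = 1, filters_start = 4,
                    lstm_units = 4, spatial_dropout = 0.2, dropout_rate = 0.2)
  ho <- holdout_split(y, 0.8, seed = 5)
  m <- train_model(spec, x[ho$train, , , drop = FALSE], y[ho$train],
                   x[ho$validation, , , drop = FALSE], y[ho$validation],
                   train_config(epochs_max = 30, patience = 30,
                                learning_rate = 3e-3, runs = 1),
                   seed = 5)
  expect_lt(m$best_val_loss, log(2))
  acc <- mean(predict_windows(m, x[ho$validation, , , drop = FALSE]) ==
                y[ho$validation])
  expect_gt(acc, 0.7)
})

test_that("ensembles are reproducible and vote member-order-invariantly", {
  withr::local_seed(421)
  X <- matrix(rnorm(120 * 6), 120, 6)
  y <- as.integer(X[, 1] + 0.5 * X[, 2] > 0)
  ho <- holdout_split(y, 0.8, seed = 6)
  cfg <- train_config(epochs_max = 15, patience = 15, runs = 3, seed_base = 9)
  e1 <- train_ensemble(shallow_spec(6), X[ho$train, ], y[ho$train],
                       X[ho$validation, ], y[ho$validation], cfg)
  e2 <- train_ensemble(shallow_spec(6), X[ho$train, ], y[ho$train],
                       X[ho$validation, ], y[ho$validation], cfg)
  expect_identical(predict_windows(e1, X), predict_windows(e2, X))
  e3 <- e1
  e3$members <- rev(e3$members)
  expect_identical(predict_windows(e1, X), predict_windows(e3, X))
})
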