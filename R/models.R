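#' Model specifications
#'
#' `shallow_spec()` describes the feature-based classifier: an input layer
#' over the flattened feature vector (1045 at the 19-channel montage), a
#' dropout layer with 50% rate, an optional hidden fully connected layer,
#' and a 2-neuron fully connected output read through softmax.
#' `deep_spec()` describes the compact CNN-BiLSTM over raw 10-s EEG windows
#' (2560 x 19 at 256 Hz): three convolutional blocks, each with one unit-
#' stride and one stride-2 convolution (a learnable pooling layer), spatial
#' dropout, swish activation and batch normalisation; filters start at
#' `filters_start` and double per block with kernel size 3 throughout; then
#' a bidirectional LSTM with 64 units per direction, 50% dropout, and a
#' 2-neuron softmax head.
#'
#' @param input_len length of the flattened feature vector.
#' @param dropout_rate dropout probability in `[0, 1)`.
#' @param hidden_neurons optional hidden layer width (`NULL` for none).
#' @return A model spec object.
#' @export
shallow_spec <- function(input_len, dropout_rate = 0.5, hidden_neurons = NULL) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1)
  structure(list(input_len = input_len, dropout_rate = dropout_rate,
                 hidden_neurons = hidden_neurons),
            class = c("shallow_spec", "model_spec"))
}

#' @rdname shallow_spec
#' @param input_shape `c(samples, channels)` of one raw window.
#' @param blocks number of convolutional blocks.
#' @param filters_start filters in the first block (doubling per block).
#' @param kernel_size convolution kernel length.
#' @param lstm_units units per LSTM direction.
#' @param spatial_dropout spatial dropout rate inside each block.
#' @export
deep_spec <- function(input_shape, blocks = 3, filters_start = 128,
                      kernel_size = 3, lstm_units = 64,
                      spatial_dropout = 0.5, dropout_rate = 0.5) {
  structure(list(input_shape = input_shape, blocks = blocks,
                 filters_start = filters_start, kernel_size = kernel_size,
                 lstm_units = lstm_units, spatial_dropout = spatial_dropout,
                 dropout_rate = dropout_rate),
            class = c("deep_spec", "model_spec"))
}

#' Training configuration
#'
#' Defaults follow the training regime of the pipeline: balanced batches of
#' 64 samples (32 per class), at most 500 epochs with early stopping at a
#' patience of 50 epochs, Adam at learning rate 3e-4, binary cross-entropy
#' loss, and 31 runs fused by majority vote.
#'
#' @param batch_size samples per batch (split evenly between classes).
#' @param epochs_max maximum training epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param learning_rate Adam learning rate.
#' @param runs ensemble members (odd, so majority votes cannot tie).
#' @param seed_base base seed; member `r` trains under `seed_base + r`.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 64, epochs_max = 500, patience = 50,
                         learning_rate = 3e-4, runs = 31, seed_base = 0) {
  stopifnot(batch_size %% 2 == 0, runs %% 2 == 1)
  structure(list(batch_size = batch_size, epochs_max = epochs_max,
                 patience = patience, learning_rate = learning_rate,
                 runs = runs, seed_base = seed_base),
            class = "train_config")
}

build_layers <- function(spec) UseMethod("build_layers")

#' @export
build_layers.shallow_spec <- function(spec) {
  layers <- list(layer_dropout(spec$dropout_rate))
  if (!is.null(spec$hidden_neurons)) {
    layers <- c(layers,
                list(layer_dense(spec$input_len, spec$hidden_neurons),
                     layer_swish(),
                     layer_dense(spec$hidden_neurons, 2L)))
  } else {
    layers <- c(layers, list(layer_dense(spec$input_len, 2L)))
  }
  layers
}

#' @export
build_layers.deep_spec <- function(spec) {
  layers <- list()
  c_in <- spec$input_shape[2]
  t_len <- spec$input_shape[1]
  for (b in seq_len(spec$blocks)) {
    f <- spec$filters_start * 2^(b - 1)
    layers <- c(layers, list(
      layer_conv1d(c_in, f, spec$kernel_size, stride = 1),
      layer_conv1d(f, f, spec$kernel_size, stride = 2),
      layer_spatial_dropout(spec$spatial_dropout),
      layer_swish(),
      layer_batchnorm(f)))
    c_in <- f
    t_len <- ceiling(t_len / 2)
  }
  c(layers, list(layer_bilstm(c_in, spec$lstm_units),
                 layer_dropout(spec$dropout_rate),
                 layer_dense(2L * spec$lstm_units, 2L)))
}

#' Balanced batch index stream for one epoch
#'
#' Every batch holds `batch_size/2` samples of each class. The majority
#' class is shuffled and consumed without replacement; the minority class is
#' oversampled by cycling through reshuffled replications. One epoch holds
#' `ceiling(n_majority / (batch_size/2))` batches. Deterministic given the
#' seed.
#'
#' @param labels class labels (0/1).
#' @param batch_size samples per batch.
#' @param seed integer seed.
#' @return List of integer index vectors, one per batch.
#' @export
balanced_batches <- function(labels, batch_size = 64, seed = 1) {
  idx0 <- which(labels == 0)
  idx1 <- which(labels == 1)
  if (!length(idx0) || !length(idx1)) stopf("both classes must be present")
  half <- batch_size %/% 2
  local_seed(derive_seed(seed, 21), {
    maj <- if (length(idx0) >= length(idx1)) idx0 else idx1
    mino <- if (length(idx0) >= length(idx1)) idx1 else idx0
    maj <- sample(maj)
    n_batches <- ceiling(length(maj) / half)
    mino_stream <- integer(0)
    while (length(mino_stream) < n_batches * half) {
      mino_stream <- c(mino_stream, sample(mino))
    }
    lapply(seq_len(n_batches), function(b) {
      m <- maj[((b - 1) * half + 1):min(b * half, length(maj))]
      if (length(m) < half) {
        pool <- setdiff(maj, m)
        need <- half - length(m)
        extra <- if (length(pool) >= need) {
          pool[sample.int(length(pool), need)]
        } else {
          maj[sample.int(length(maj), need, replace = TRUE)]
        }
        m <- c(m, extra)
      }
      c(m, mino_stream[((b - 1) * half + 1):(b * half)])
    })
  })
}

slice_input <- function(x, idx) {
  if (length(dim(x)) == 3) x[idx, , , drop = FALSE] else x[idx, , drop = FALSE]
}

#' Train one neural network with early stopping
#'
#' Minimises binary cross-entropy with Adam over balanced batches, tracking
#' the validation loss each epoch; training stops once the validation loss
#' has failed to improve for more than `patience` consecutive epochs (or at
#' `epochs_max`) and the best-validation-loss weights are restored.
#'
#' @param spec a [shallow_spec()] or [deep_spec()].
#' @param x_train,y_train normalised training inputs and 0/1 labels.
#' @param x_val,y_val validation inputs and labels.
#' @param config a [train_config()].
#' @param seed integer seed covering initialisation, batch order and dropout.
#' @return A `trained_model` with the best weights and training metadata.
#' @export
train_model <- function(spec, x_train, y_train, x_val, y_val,
                        config = train_config(), seed = 1) {
  stopifnot(length(unique(y_train)) == 2, length(unique(y_val)) == 2)
  local_seed(derive_seed(seed, 31), {
    layers <- build_layers(spec)
    state <- adam_init(layers)
    best_loss <- Inf
    best_snap <- snapshot_params(layers)
    best_epoch <- 0L
    stale <- 0L
    t_step <- 0L
    epoch <- 0L
    while (epoch < config$epochs_max) {
      epoch <- epoch + 1L
      batches <- balanced_batches(y_train, config$batch_size,
                                  seed = derive_seed(seed, 100 + epoch))
      for (b in batches) {
        fw <- net_forward(layers, slice_input(x_train, b), training = TRUE)
        layers <- fw$layers
        ls <- softmax_xent(fw$out, y_train[b])
        if (!is.finite(ls$loss)) stopf("non-finite training loss at epoch %d", epoch)
        grads <- net_backward(layers, ls$dZ, fw$caches)
        t_step <- t_step + 1L
        up <- adam_step(layers, grads, state, t_step, lr = config$learning_rate)
        layers <- up$layers
        state <- up$state
      }
      val <- net_forward(layers, x_val, training = FALSE)
      vloss <- softmax_xent(val$out, y_val)$loss
      if (!is.finite(vloss)) stopf("non-finite validation loss at epoch %d", epoch)
      if (vloss < best_loss - 1e-9) {
        best_loss <- vloss
        best_snap <- snapshot_params(layers)
        best_epoch <- epoch
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale > config$patience) break
      }
    }
    layers <- restore_params(layers, best_snap)
    structure(list(layers = layers, spec = spec, seed = seed,
                   epochs_ran = epoch, best_epoch = best_epoch,
                   best_val_loss = best_loss),
              class = "trained_model")
  })
}

#' Predict per-window classes
#'
#' Deterministic argmax of the softmax output; dropout is inactive at
#' inference.
#'
#' @param model a `trained_model` or `trained_ensemble`.
#' @param x normalised inputs (matrix of feature vectors, or array of raw
#'   windows for the deep model).
#' @return Integer vector of classes in `{0, 1}`.
#' @export
predict_windows <- function(model, x) {
  if (inherits(model, "trained_ensemble")) {
    votes <- vapply(model$members, function(m) predict_windows(m, x),
                    integer(if (length(dim(x)) == 3) dim(x)[1] else nrow(x)))
    return(majority_vote(t(matrix(votes, ncol = length(model$members)))))
  }
  fw <- net_forward(model$layers, x, training = FALSE)
  as.integer(max.col(fw$out, ties.method = "first") - 1L)
}

#' Majority vote across ensemble members
#'
#' @param member_predictions matrix (members x windows) of 0/1 classes; the
#'   member count must be odd so no vote can tie.
#' @return Integer vector of fused classes.
#' @export
majority_vote <- function(member_predictions) {
  m <- nrow(member_predictions)
  if (m %% 2 == 0) stopf("ensemble size must be odd; got %d members", m)
  as.integer(colSums(member_predictions) > m / 2)
}

#' Train a majority-voting ensemble
#'
#' Trains `config$runs` models that differ only in their seed
#' (`seed_base + run`), covering initialisation, batch shuffling and
#' dropout; predictions are fused by [majority_vote()] on per-window hard
#' labels, so the ensemble is a drop-in prediction source for the
#' firing-power stage.
#'
#' @inheritParams train_model
#' @return A `trained_ensemble`.
#' @export
train_ensemble <- function(spec, x_train, y_train, x_val, y_val,
                           config = train_config()) {
  members <- lapply(seq_len(config$runs), function(r) {
    train_model(spec, x_train, y_train, x_val, y_val, config,
                seed = config$seed_base + r)
  })
  structure(list(members = members, spec = spec, config = config),
            class = "trained_ensemble")
}

#' @export
print.trained_ensemble <- function(x, ...) {
  cat(sprintf("<trained_ensemble> %d members, %s\n", length(x$members),
              class(x$spec)[1]))
  invisible(x)
}
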