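# Minimal neural-network engine: dense, dropout, spatial dropout, 1-D
# convolution (temporal axis, channels as features), batch normalisation,
# swish, and a bidirectional LSTM, each with analytic backpropagation, plus
# Adam. Written against the two architectures this package trains; not a
# general framework. All gradients are verified against numeric
# differentiation in the test suite.

#' Swish activation
#'
#' Elementwise `x * sigmoid(x)`.
#'
#' @param x numeric vector, matrix or array.
#' @return Same shape as `x`.
#' @export
swish <- function(x) x * stats::plogis(x)

#' Softmax
#'
#' `exp(x_i) / sum_j exp(x_j)` with max-shift stabilisation; shift-invariant
#' and summing to 1.
#'
#' @param x numeric vector of scores.
#' @return Probability vector of the same length.
#' @export
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

sigmoid <- stats::plogis

# ---- layer constructors ---------------------------------------------------

glorot <- function(fan_in, fan_out, dims) {
  l <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -l, l), dims)
}

layer_dense <- function(n_in, n_out) {
  list(type = "dense", W = glorot(n_in, n_out, c(n_in, n_out)),
       b = numeric(n_out))
}

layer_dropout <- function(rate) list(type = "dropout", rate = rate)

layer_spatial_dropout <- function(rate) {
  list(type = "spatial_dropout", rate = rate)
}

layer_swish <- function() list(type = "swish")

layer_conv1d <- function(c_in, c_out, kernel = 3, stride = 1) {
  list(type = "conv1d", kernel = kernel, stride = stride,
       W = glorot(kernel * c_in, c_out, c(kernel, c_in, c_out)),
       b = numeric(c_out))
}

layer_batchnorm <- function(c_feat, momentum = 0.9) {
  list(type = "batchnorm", gamma = rep(1, c_feat), beta = numeric(c_feat),
       run_mean = numeric(c_feat), run_var = rep(1, c_feat),
       momentum = momentum, eps = 1e-5)
}

layer_bilstm <- function(c_in, units) {
  l <- sqrt(6 / (c_in + 4 * units))
  mk <- function() {
    b <- numeric(4 * units)
    b[(units + 1):(2 * units)] <- 1  # forget-gate bias
    list(Wx = array(stats::runif(c_in * 4 * units, -l, l), c(c_in, 4 * units)),
         Wh = array(stats::runif(units * 4 * units, -l, l), c(units, 4 * units)),
         b = b)
  }
  fw <- mk(); bw <- mk()
  list(type = "bilstm", units = units,
       Wx_f = fw$Wx, Wh_f = fw$Wh, b_f = fw$b,
       Wx_b = bw$Wx, Wh_b = bw$Wh, b_b = bw$b)
}

layer_param_names <- function(layer) {
  switch(layer$type,
         dense = c("W", "b"),
         conv1d = c("W", "b"),
         batchnorm = c("gamma", "beta"),
         bilstm = c("Wx_f", "Wh_f", "b_f", "Wx_b", "Wh_b", "b_b"),
         character(0))
}

# ---- forward / backward ---------------------------------------------------

forward_layer <- function(layer, x, training) {
  switch(layer$type,
    dense = {
      out <- sweep(x %*% layer$W, 2, layer$b, "+")
      list(layer = layer, out = out, cache = list(x = x))
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- array(stats::runif(length(x)) >= layer$rate, dim(x) %||% length(x))
        out <- x * mask / (1 - layer$rate)
        list(layer = layer, out = out, cache = list(mask = mask))
      } else {
        list(layer = layer, out = x, cache = list(mask = NULL))
      }
    },
    spatial_dropout = {
      d <- dim(x)  # (batch, T, C)
      if (training && layer$rate > 0) {
        keep <- matrix(stats::runif(d[1] * d[3]) >= layer$rate, d[1], d[3])
        mask <- aperm(array(keep, c(d[1], d[3], d[2])), c(1, 3, 2))
        out <- x * mask / (1 - layer$rate)
        list(layer = layer, out = out, cache = list(mask = mask))
      } else {
        list(layer = layer, out = x, cache = list(mask = NULL))
      }
    },
    swish = {
      s <- sigmoid(x)
      list(layer = layer, out = x * s, cache = list(x = x, s = s))
    },
    conv1d = conv1d_forward(layer, x),
    batchnorm = batchnorm_forward(layer, x, training),
    bilstm = bilstm_forward(layer, x),
    stopf("unknown layer type %s", layer$type))
}

backward_layer <- function(layer, dout, cache) {
  switch(layer$type,
    dense = list(
      dx = dout %*% t(layer$W),
      grads = list(W = crossprod(cache$x, dout), b = colSums(dout))),
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = list())
      else list(dx = dout * cache$mask / (1 - layer$rate), grads = list())
    },
    spatial_dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = list())
      else list(dx = dout * cache$mask / (1 - layer$rate), grads = list())
    },
    swish = {
      s <- cache$s
      list(dx = dout * (s + cache$x * s * (1 - s)), grads = list())
    },
    conv1d = conv1d_backward(layer, dout, cache),
    batchnorm = batchnorm_backward(layer, dout, cache),
    bilstm = bilstm_backward(layer, dout, cache),
    stopf("unknown layer type %s", layer$type))
}

# 1-D convolution along the temporal axis with "same" padding:
# x (batch, T, C_in) -> (batch, ceil(T / stride), C_out).
conv1d_forward <- function(layer, x) {
  d <- dim(x)
  b <- d[1]; Tn <- d[2]; cin <- d[3]
  k <- layer$kernel; st <- layer$stride
  t_out <- ceiling(Tn / st)
  pad <- (k - 1) %/% 2
  cout <- dim(layer$W)[3]
  out <- array(0, c(b, t_out, cout))
  src_list <- vector("list", k)
  for (m in seq_len(k)) {
    src <- (seq_len(t_out) - 1) * st + m - pad
    ok <- src >= 1 & src <= Tn
    src_list[[m]] <- list(src = src[ok], dst = which(ok))
    if (!any(ok)) next
    xm <- x[, src[ok], , drop = FALSE]
    dim(xm) <- c(b * sum(ok), cin)
    ym <- xm %*% matrix(layer$W[m, , ], cin, cout)
    dim(ym) <- c(b, sum(ok), cout)
    out[, which(ok), ] <- out[, which(ok), , drop = FALSE] + ym
  }
  out <- sweep(out, 3, layer$b, "+")
  list(layer = layer, out = out,
       cache = list(x = x, src_list = src_list, t_out = t_out))
}

conv1d_backward <- function(layer, dout, cache) {
  x <- cache$x
  d <- dim(x)
  b <- d[1]; Tn <- d[2]; cin <- d[3]
  k <- layer$kernel
  cout <- dim(layer$W)[3]
  dW <- array(0, dim(layer$W))
  dx <- array(0, d)
  db <- colSums(matrix(dout, b * cache$t_out, cout))
  for (m in seq_len(k)) {
    sl <- cache$src_list[[m]]
    if (!length(sl$dst)) next
    xm <- x[, sl$src, , drop = FALSE]
    dim(xm) <- c(b * length(sl$src), cin)
    dym <- dout[, sl$dst, , drop = FALSE]
    dim(dym) <- c(b * length(sl$dst), cout)
    dW[m, , ] <- crossprod(xm, dym)
    dxm <- dym %*% t(matrix(layer$W[m, , ], cin, cout))
    dim(dxm) <- c(b, length(sl$src), cin)
    dx[, sl$src, ] <- dx[, sl$src, , drop = FALSE] + dxm
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

# Batch normalisation over batch and time per feature channel.
batchnorm_forward <- function(layer, x, training) {
  d <- dim(x)
  cfe <- d[length(d)]
  xm <- matrix(x, prod(d) / cfe, cfe)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(sweep(xm, 2, mu)^2)
    layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
  }
  xhat <- sweep(sweep(xm, 2, mu), 2, sqrt(v + layer$eps), "/")
  out <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  dim(out) <- d
  list(layer = layer, out = out,
       cache = list(xhat = xhat, v = v, d = d, training = training))
}

batchnorm_backward <- function(layer, dout, cache) {
  d <- cache$d
  cfe <- d[length(d)]
  N <- prod(d) / cfe
  dy <- matrix(dout, N, cfe)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  if (cache$training) {
    inv_sd <- 1 / sqrt(cache$v + layer$eps)
    t1 <- sweep(dy, 2, colMeans(dy))
    t2 <- sweep(xhat, 2, colMeans(dy * xhat) , "*")
    dx <- sweep(t1 - t2, 2, layer$gamma * inv_sd, "*")
  } else {
    dx <- sweep(dy, 2, layer$gamma / sqrt(layer$v + layer$eps), "*")
  }
  dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# One-direction LSTM pass over x (batch, T, C); returns last hidden state.
lstm_pass <- function(x, Wx, Wh, b, reverse = FALSE) {
  d <- dim(x)
  bsz <- d[1]; Tn <- d[2]
  U <- as.integer(ncol(Wx) / 4)
  h <- matrix(0, bsz, U)
  cc <- matrix(0, bsz, U)
  steps <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  caches <- vector("list", Tn)
  for (s in seq_along(steps)) {
    t <- steps[s]
    xt <- matrix(x[, t, ], bsz, d[3])
    z <- xt %*% Wx + h %*% Wh
    z <- sweep(z, 2, b, "+")
    i <- sigmoid(z[, 1:U, drop = FALSE])
    f <- sigmoid(z[, (U + 1):(2 * U), drop = FALSE])
    g <- tanh(z[, (2 * U + 1):(3 * U), drop = FALSE])
    o <- sigmoid(z[, (3 * U + 1):(4 * U), drop = FALSE])
    c_prev <- cc
    h_prev <- h
    cc <- f * c_prev + i * g
    h <- o * tanh(cc)
    caches[[s]] <- list(t = t, xt = xt, h_prev = h_prev, c_prev = c_prev,
                        i = i, f = f, g = g, o = o, c = cc)
  }
  list(h_last = h, caches = caches)
}

lstm_pass_backward <- function(dh_last, caches, Wx, Wh, x_dim) {
  U <- ncol(dh_last)
  bsz <- x_dim[1]
  dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh)); db <- numeric(4 * U)
  dx <- array(0, x_dim)
  dh <- dh_last
  dc <- matrix(0, bsz, U)
  for (s in rev(seq_along(caches))) {
    cc <- caches[[s]]
    tc <- tanh(cc$c)
    do_ <- dh * tc
    dcc <- dc + dh * cc$o * (1 - tc^2)
    di <- dcc * cc$g
    df <- dcc * cc$c_prev
    dg <- dcc * cc$i
    dc <- dcc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2), do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$xt, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dx[, cc$t, ] <- dx[, cc$t, , drop = FALSE] +
      array(dz %*% t(Wx), c(bsz, 1, x_dim[3]))
    dh <- dz %*% t(Wh)
  }
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}

bilstm_forward <- function(layer, x) {
  fw <- lstm_pass(x, layer$Wx_f, layer$Wh_f, layer$b_f, reverse = FALSE)
  bw <- lstm_pass(x, layer$Wx_b, layer$Wh_b, layer$b_b, reverse = TRUE)
  list(layer = layer, out = cbind(fw$h_last, bw$h_last),
       cache = list(fw = fw, bw = bw, x_dim = dim(x)))
}

bilstm_backward <- function(layer, dout, cache) {
  U <- layer$units
  gf <- lstm_pass_backward(dout[, 1:U, drop = FALSE], cache$fw$caches,
                           layer$Wx_f, layer$Wh_f, cache$x_dim)
  gb <- lstm_pass_backward(dout[, (U + 1):(2 * U), drop = FALSE],
                           cache$bw$caches, layer$Wx_b, layer$Wh_b,
                           cache$x_dim)
  list(dx = gf$dx + gb$dx,
       grads = list(Wx_f = gf$dWx, Wh_f = gf$dWh, b_f = gf$db,
                    Wx_b = gb$dWx, Wh_b = gb$dWh, b_b = gb$db))
}

# ---- network --------------------------------------------------------------

net_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    st <- forward_layer(layers[[i]], x, training)
    layers[[i]] <- st$layer
    caches[[i]] <- st$cache
    x <- st$out
  }
  list(layers = layers, out = x, caches = caches)
}

net_backward <- function(layers, dout, caches) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    st <- backward_layer(layers[[i]], dout, caches[[i]])
    grads[[i]] <- st$grads
    dout <- st$dx
  }
  grads
}

# Softmax cross-entropy on logits Z (batch x 2) with labels y in {0, 1}.
softmax_xent <- function(Z, y) {
  P <- row_softmax(Z)
  idx <- cbind(seq_along(y), y + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, dZ = dZ / length(y), probs = P)
}

adam_init <- function(layers) {
  lapply(layers, function(l) {
    nm <- layer_param_names(l)
    stats::setNames(lapply(nm, function(p) {
      list(m = array(0, dim(l[[p]]) %||% length(l[[p]])),
           v = array(0, dim(l[[p]]) %||% length(l[[p]])))
    }), nm)
  })
}

adam_step <- function(layers, grads, state, t, lr = 3e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    for (p in names(state[[i]])) {
      g <- grads[[i]][[p]]
      if (is.null(g)) next
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

snapshot_params <- function(layers) {
  lapply(layers, function(l) {
    nm <- c(layer_param_names(l),
            if (l$type == "batchnorm") c("run_mean", "run_var"))
    stats::setNames(lapply(nm, function(p) l[[p]]), nm)
  })
}

restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    for (p in names(snap[[i]])) layers[[i]][[p]] <- snap[[i]][[p]]
  }
  layers
}
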