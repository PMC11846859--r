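## Minimal 1-D convolutional network engine (internal).
##
## Implements exactly what the denoising autoencoder and the spectral
## classifier need: 1-D "same"-padded strided convolutions via im2col +
## BLAS matrix products, nearest-neighbour upsampling, dense layers, relu /
## sigmoid / softmax activations, Glorot-uniform initialisation, Adam, and
## categorical/binary cross-entropy and mean-squared-error losses. All
## randomness flows from an explicit seed; training is deterministic.

nn_conv <- function(kernel, filters, stride = 1L, activation = "relu") {
  list(type = "conv", k = as.integer(kernel), filters = as.integer(filters),
       stride = as.integer(stride), activation = activation)
}
nn_upsample <- function(factor = 2L) list(type = "upsample", factor = as.integer(factor))
nn_flatten <- function() list(type = "flatten")
nn_dense <- function(units, activation = "relu") {
  list(type = "dense", units = as.integer(units), activation = activation)
}

glorot <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

## instantiate parameters; input is (length, channels)
nn_init <- function(layers, input_len, input_ch = 1L, seed = 1L) {
  set.seed(seed)
  len <- input_len; ch <- input_ch
  params <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      out_len <- ceiling(len / l$stride)
      params[[i]] <- list(
        W = matrix(glorot(l$k * ch, l$k * l$filters, l$k * ch * l$filters),
                   l$k * ch, l$filters),
        b = numeric(l$filters))
      layers[[i]]$in_ch <- ch; layers[[i]]$in_len <- len
      layers[[i]]$out_len <- out_len
      len <- out_len; ch <- l$filters
    } else if (l$type == "upsample") {
      layers[[i]]$in_len <- len
      len <- len * l$factor
    } else if (l$type == "flatten") {
      layers[[i]]$in_len <- len; layers[[i]]$in_ch <- ch
      len <- len * ch; ch <- NA_integer_
    } else if (l$type == "dense") {
      params[[i]] <- list(
        W = matrix(glorot(len, l$units, len * l$units), len, l$units),
        b = numeric(l$units))
      layers[[i]]$in_len <- len
      len <- l$units
    } else stop("unknown layer type: ", l$type)
  }
  structure(list(layers = layers, params = params,
                 input_len = input_len, input_ch = input_ch,
                 output_len = len),
            class = "nn_model")
}

activate <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         tanh = tanh(z),
         linear = z,
         sigmoid = 1 / (1 + exp(-z)),
         softmax = {
           e <- exp(z - apply(z, 1L, max))
           e / rowSums(e)
         },
         stop("unknown activation: ", act))
}
activate_grad <- function(a, act) {    # d activation / d preactivation, given a
  switch(act,
         relu = (a > 0) * 1,
         tanh = 1 - a^2,
         linear = 1,
         sigmoid = a * (1 - a),
         stop("no pointwise gradient for: ", act))
}

conv_starts <- function(l) {
  out_len <- ceiling(l$in_len / l$stride)
  pad_total <- max(0L, (out_len - 1L) * l$stride + l$k - l$in_len)
  pad_l <- pad_total %/% 2L
  list(out_len = out_len, pad_l = pad_l, pad_total = pad_total,
       starts = (seq_len(out_len) - 1L) * l$stride + 1L)
}

## im2col layout: colmat is (batch*out_len, k*in_ch), the (j, c) column being
## the padded input at offset j-1, channel c; gathered one kernel offset at a
## time to avoid 4-d reshapes.
conv_forward <- function(l, p, X) {    # X: (batch, len, ch)
  b <- dim(X)[1L]
  cs <- conv_starts(l)
  len_pad <- l$in_len + cs$pad_total
  Xp <- array(0, c(b, len_pad, l$in_ch))
  Xp[, cs$pad_l + seq_len(l$in_len), ] <- X
  colmat <- matrix(0, b * cs$out_len, l$k * l$in_ch)
  ch_cols <- (seq_len(l$in_ch) - 1L) * l$k
  for (j in seq_len(l$k)) {
    slice <- Xp[, cs$starts + (j - 1L), , drop = FALSE]
    dim(slice) <- c(b * cs$out_len, l$in_ch)
    colmat[, ch_cols + j] <- slice
  }
  z <- colmat %*% p$W
  z <- z + rep(p$b, each = nrow(z))
  a <- activate(z, l$activation)
  list(out = array(a, c(b, cs$out_len, l$filters)),
       cache = list(colmat = colmat, a = a, cs = cs, batch = b))
}

conv_backward <- function(l, p, cache, dOut) {  # dOut: (b, out_len, filters)
  cs <- cache$cs; b <- cache$batch
  dA <- matrix(dOut, b * cs$out_len, l$filters)
  dZ <- dA * activate_grad(cache$a, l$activation)
  dW <- crossprod(cache$colmat, dZ)
  db <- colSums(dZ)
  dcol <- dZ %*% t(p$W)                                   # (b*out_len, k*ch)
  len_pad <- l$in_len + cs$pad_total
  dXp <- array(0, c(b, len_pad, l$in_ch))
  ch_cols <- (seq_len(l$in_ch) - 1L) * l$k
  for (j in seq_len(l$k)) {                 # positions unique for fixed j
    pos <- cs$starts + (j - 1L)
    slice <- dcol[, ch_cols + j, drop = FALSE]
    dim(slice) <- c(b, cs$out_len, l$in_ch)
    dXp[, pos, ] <- dXp[, pos, , drop = FALSE] + slice
  }
  dX <- dXp[, cs$pad_l + seq_len(l$in_len), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

nn_forward <- function(model, X, keep_cache = FALSE) {
  if (is.matrix(X)) X <- array(X, c(dim(X), 1L))
  caches <- if (keep_cache) vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]; p <- model$params[[i]]
    if (l$type == "conv") {
      f <- conv_forward(l, p, X)
      X <- f$out
      if (keep_cache) caches[[i]] <- f$cache
    } else if (l$type == "upsample") {
      b <- dim(X)[1L]
      idx <- rep(seq_len(dim(X)[2L]), each = l$factor)
      X <- X[, idx, , drop = FALSE]
    } else if (l$type == "flatten") {
      b <- dim(X)[1L]
      X <- matrix(X, b, l$in_len * l$in_ch)
    } else if (l$type == "dense") {
      z <- sweep(X %*% p$W, 2L, p$b, `+`)
      a <- activate(z, l$activation)
      if (keep_cache) caches[[i]] <- list(x = X, a = a)
      X <- a
    }
  }
  list(out = X, caches = caches)
}

## dOut arrives as gradient wrt the network output (post-activation for
## pointwise activations; for softmax+cce the caller passes dZ directly and
## flags it).
nn_backward <- function(model, caches, dOut, softmax_dz = FALSE) {
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]; p <- model$params[[i]]
    if (l$type == "dense") {
      c <- caches[[i]]
      dZ <- if (i == length(model$layers) && softmax_dz) dOut
            else dOut * activate_grad(c$a, l$activation)
      grads[[i]] <- list(dW = crossprod(c$x, dZ), db = colSums(dZ))
      dOut <- dZ %*% t(p$W)
    } else if (l$type == "flatten") {
      b <- nrow(dOut)
      dOut <- array(dOut, c(b, l$in_len, l$in_ch))
    } else if (l$type == "upsample") {
      b <- dim(dOut)[1L]
      out_len <- dim(dOut)[2L] %/% l$factor
      d <- array(dOut, c(b, l$factor, out_len, dim(dOut)[3L]))
      dOut <- array(colSums(aperm(d, c(2L, 1L, 3L, 4L))),
                    c(b, out_len, dim(dOut)[3L]))
    } else if (l$type == "conv") {
      bk <- conv_backward(l, p, caches[[i]], dOut)
      grads[[i]] <- bk[c("dW", "db")]
      dOut <- bk$dX
    }
  }
  grads
}

nn_loss <- function(out, target, loss) {
  eps <- 1e-12
  switch(loss,
         cce = -mean(rowSums(target * log(out + eps))),
         bce = -mean(target * log(out + eps) + (1 - target) * log(1 - out + eps)),
         mse = mean((out - target)^2),
         stop("unknown loss: ", loss))
}

## gradient of the loss wrt the final pre-activation (cce/bce) or activation
nn_loss_grad <- function(out, target, loss) {
  n <- length(out)
  switch(loss,
         cce = list(d = (out - target) / nrow(out), softmax_dz = TRUE),
         bce = list(d = (out - target) / n, softmax_dz = TRUE),  # sigmoid cancels
         mse = list(d = 2 * (out - target) / n, softmax_dz = FALSE))
}

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
  })
}

adam_step <- function(model, grads, state, t, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(model$params)) {
    if (is.null(model$params[[i]])) next
    g <- grads[[i]]; s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    model$params[[i]]$W <- model$params[[i]]$W -
      lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    model$params[[i]]$b <- model$params[[i]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(model = model, state = state)
}

## Generic training loop. X: (n, len) matrix; Y: (n, out) matrix.
## Optional validation list(X, Y) drives early stopping on validation loss
## with the given patience, never before min_epochs; best weights restored.
nn_train <- function(model, X, Y, epochs, batch_size, loss,
                     lr = 1e-3, seed = 1L, validation = NULL,
                     min_epochs = epochs, patience = Inf, verbose = FALSE) {
  set.seed(seed)
  n <- nrow(X)
  state <- adam_init(model$params)
  t <- 0L
  history <- numeric(0)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  wait <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      fw <- nn_forward(model, X[idx, , drop = FALSE], keep_cache = TRUE)
      ep_loss <- ep_loss + nn_loss(fw$out, Y[idx, , drop = FALSE], loss)
      lg <- nn_loss_grad(fw$out, Y[idx, , drop = FALSE], loss)
      grads <- nn_backward(model, fw$caches, lg$d, lg$softmax_dz)
      t <- t + 1L
      up <- adam_step(model, grads, state, t, lr)
      model <- up$model; state <- up$state
      nb <- nb + 1L
    }
    mon <- if (!is.null(validation)) {
      vo <- nn_forward(model, validation$X)$out
      nn_loss(vo, validation$Y, loss)
    } else ep_loss / nb
    history <- c(history, mon)
    if (verbose) message(sprintf("epoch %d: monitored loss %.5f", ep, mon))
    if (mon < best$loss - 1e-6) {
      best <- list(loss = mon, params = model$params, epoch = ep)
      wait <- 0L
    } else wait <- wait + 1L
    if (ep >= min_epochs && wait >= patience) break
  }
  model$params <- best$params
  list(model = model, history = history, epochs_run = length(history),
       best_epoch = best$epoch)
}

nn_predict <- function(model, X) nn_forward(model, X)$out
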