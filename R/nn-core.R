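# Internal 1-D convolutional network engine.
#
# Activations flow as plain matrices, one row per sample; a length-by-channel
# tensor (n, len, ch) is stored as the n x (len*ch) matrix whose column
# (pos, c) sits at pos + len*(c-1). With that layout, reshaping a convolution
# output (n*out_len, M) into the next layer's (n, out_len*M) input is a single
# matrix() call, and the convolution itself is one gather (im2col) plus one
# BLAS GEMM. All gradients are exact; no autodiff.

.im2col_cache <- new.env(parent = emptyenv())

# Gather indices turning the (n, len, ch) layout into the patch matrix
# A[(b, j), (l, c)] = x[b, (j-1)*stride + l, c], plus the precomputed
# ordering that turns the backward scatter-add into one cumsum over sorted
# segments; cached per shape.
im2col_idx <- function(n, len, ch, L, stride, out_len) {
  key <- paste(n, len, ch, L, stride, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  b <- rep(seq_len(n), times = out_len * L * ch)
  j <- rep(rep(seq_len(out_len), each = n), times = L * ch)
  l <- rep(rep(seq_len(L), each = n * out_len), times = ch)
  c_ <- rep(seq_len(ch), each = n * out_len * L)
  idx <- b + n * ((j - 1L) * stride + l - 1L) + n * len * (c_ - 1L)
  ord <- order(idx, method = "radix")
  runs <- rle(idx[ord])
  entry <- list(idx = idx, ord = ord,
                seg_ends = cumsum(runs$lengths), targets = runs$values)
  .im2col_cache[[key]] <- entry
  entry
}

conv_out_len <- function(input_len, L, stride) {
  if (input_len < L) stopf("conv input length %d shorter than kernel length %d", input_len, L)
  (input_len - L) %/% stride + 1L
}

act_fun <- function(z, name) {
  switch(name,
         relu = pmax(z, 0),
         tanh = tanh(z),
         identity = z,
         stopf("unknown activation '%s'", name))
}

# derivative w.r.t. the pre-activation, expressed via pre (z) and post (h)
act_grad <- function(z, h, name) {
  switch(name,
         relu = (z > 0) + 0,
         tanh = 1 - h * h,
         identity = 1,
         stopf("unknown activation '%s'", name))
}

.bn_eps <- 1e-3
.bn_momentum <- 0.99

# One convolution block: im2col gather, GEMM against the (L*ch x M) kernel
# matrix, per-kernel bias, optional batch normalization, activation.
conv_layer_forward <- function(layer, x, n, training) {
  len <- layer$in_len; ch <- layer$in_ch
  out_len <- layer$out_len
  im2col <- im2col_idx(n, len, ch, layer$L, layer$stride, out_len)
  A <- matrix(x[im2col$idx], nrow = n * out_len)
  Z <- A %*% layer$W
  Z <- sweep(Z, 2, layer$b, "+")
  cache <- list(A = A, n = n)
  if (layer$batch_norm) {
    if (training) {
      mu <- colMeans(Z)
      zc <- sweep(Z, 2, mu, "-")
      v <- colMeans(zc * zc)
      inv <- 1 / sqrt(v + .bn_eps)
      Zhat <- sweep(zc, 2, inv, "*")
      layer$run_mean <- .bn_momentum * layer$run_mean + (1 - .bn_momentum) * mu
      layer$run_var <- .bn_momentum * layer$run_var + (1 - .bn_momentum) * v
      cache$mu <- mu; cache$inv <- inv; cache$Zhat <- Zhat
    } else {
      inv <- 1 / sqrt(layer$run_var + .bn_eps)
      Zhat <- sweep(sweep(Z, 2, layer$run_mean, "-"), 2, inv, "*")
    }
    pre <- sweep(sweep(Zhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  } else {
    pre <- Z
  }
  H <- act_fun(pre, layer$activation)
  cache$pre <- pre; cache$H <- H
  list(layer = layer, out = matrix(H, nrow = n), cache = cache)
}

conv_layer_backward <- function(layer, cache, d_out) {
  n <- cache$n
  dH <- matrix(d_out, nrow = n * layer$out_len)
  dpre <- dH * act_grad(cache$pre, cache$H, layer$activation)
  grads <- list()
  if (layer$batch_norm) {
    grads$gamma <- colSums(dpre * cache$Zhat)
    grads$beta <- colSums(dpre)
    dZhat <- sweep(dpre, 2, layer$gamma, "*")
    m1 <- colMeans(dZhat)
    m2 <- colMeans(dZhat * cache$Zhat)
    dZ <- sweep(sweep(dZhat, 2, m1, "-") - sweep(cache$Zhat, 2, m2, "*"),
                2, cache$inv, "*")
  } else {
    dZ <- dpre
  }
  grads$b <- colSums(dZ)
  grads$W <- crossprod(cache$A, dZ)
  dA <- tcrossprod(dZ, layer$W)
  im2col <- im2col_idx(n, layer$in_len, layer$in_ch, layer$L, layer$stride,
                       layer$out_len)
  # scatter-add dA back onto the input positions: segment sums over the
  # index-sorted gradient via one cumsum
  cs <- cumsum(dA[im2col$ord])
  seg <- cs[im2col$seg_ends]
  dx <- numeric(n * layer$in_len * layer$in_ch)
  dx[im2col$targets] <- seg - c(0, seg[-length(seg)])
  list(grads = grads, d_in = matrix(dx, nrow = n))
}

dense_layer_forward <- function(layer, x) {
  pre <- sweep(x %*% layer$W, 2, layer$b, "+")
  H <- act_fun(pre, layer$activation)
  list(out = H, cache = list(x = x, pre = pre, H = H))
}

dense_layer_backward <- function(layer, cache, d_out) {
  dpre <- d_out * act_grad(cache$pre, cache$H, layer$activation)
  list(grads = list(W = crossprod(cache$x, dpre), b = colSums(dpre)),
       d_in = tcrossprod(dpre, layer$W))
}

# scaled-uniform weight init, limit sqrt(6 / fan_in)
init_weights <- function(nrow, ncol) {
  lim <- sqrt(6 / nrow)
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

new_conv_layer <- function(in_len, in_ch, M, L, stride, activation, batch_norm) {
  out_len <- conv_out_len(in_len, L, stride)
  list(type = "conv", in_len = in_len, in_ch = in_ch, M = M, L = L,
       stride = stride, out_len = out_len, activation = activation,
       batch_norm = batch_norm,
       W = init_weights(L * in_ch, M), b = numeric(M),
       gamma = if (batch_norm) rep(1, M), beta = if (batch_norm) numeric(M),
       run_mean = if (batch_norm) numeric(M), run_var = if (batch_norm) rep(1, M))
}

new_dense_layer <- function(n_in, n_out, activation) {
  list(type = "dense", n_in = n_in, n_out = n_out, activation = activation,
       W = init_weights(n_in, n_out), b = numeric(n_out))
}

# Assemble the two-branch network: feature branch (conv stack -> flatten ->
# dense), scalar concentration branch (dense), concatenation, dense head.
build_network <- function(spec, seed) {
  with_seed(seed, {
    convs <- list()
    len <- spec$input_width; ch <- 1L
    for (i in seq_along(spec$conv)) {
      blk <- spec$conv[[i]]
      convs[[i]] <- new_conv_layer(len, ch, blk$M, blk$L, blk$stride,
                                   blk$activation %||% spec$activation,
                                   blk$batch_norm %||% TRUE)
      len <- convs[[i]]$out_len; ch <- blk$M
    }
    flat <- len * ch
    feature_dense <- new_dense_layer(flat, spec$feature_dense, spec$activation)
    conc_dense <- new_dense_layer(1L, spec$conc_dense, spec$activation)
    head <- list()
    widths <- c(spec$feature_dense + spec$conc_dense, spec$head)
    for (i in seq_along(spec$head)) {
      act <- if (i == length(spec$head)) "identity" else spec$activation
      head[[i]] <- new_dense_layer(widths[i], widths[i + 1], act)
    }
    structure(list(conv = convs, feature_dense = feature_dense,
                   conc_dense = conc_dense, head = head,
                   flat = flat, spec = spec, seed = as.integer(seed)),
              class = "mgo_network")
  })
}

# Full forward pass; returns prediction vector plus (in training) every cache
# needed for the exact backward pass. `net` is returned because batch-norm
# running statistics advance during training-mode forward passes.
network_forward <- function(net, x, conc, training = FALSE) {
  n <- nrow(x)
  caches <- list(conv = vector("list", length(net$conv)))
  h <- x
  for (i in seq_along(net$conv)) {
    step <- conv_layer_forward(net$conv[[i]], h, n, training)
    net$conv[[i]] <- step$layer
    caches$conv[[i]] <- step$cache
    h <- step$out
  }
  fd <- dense_layer_forward(net$feature_dense, h)
  cd <- dense_layer_forward(net$conc_dense, matrix(conc, ncol = 1))
  z <- cbind(fd$out, cd$out)
  caches$feature_dense <- fd$cache
  caches$conc_dense <- cd$cache
  caches$head <- vector("list", length(net$head))
  for (i in seq_along(net$head)) {
    step <- dense_layer_forward(net$head[[i]], z)
    caches$head[[i]] <- step$cache
    z <- step$out
  }
  list(net = net, pred = drop(z), caches = if (training) caches)
}

network_backward <- function(net, caches, d_pred) {
  d <- matrix(d_pred, ncol = 1)
  grads <- list(head = vector("list", length(net$head)),
                conv = vector("list", length(net$conv)))
  for (i in rev(seq_along(net$head))) {
    bk <- dense_layer_backward(net$head[[i]], caches$head[[i]], d)
    grads$head[[i]] <- bk$grads
    d <- bk$d_in
  }
  nf <- net$spec$feature_dense
  bf <- dense_layer_backward(net$feature_dense, caches$feature_dense,
                             d[, seq_len(nf), drop = FALSE])
  bc <- dense_layer_backward(net$conc_dense, caches$conc_dense,
                             d[, nf + seq_len(net$spec$conc_dense), drop = FALSE])
  grads$feature_dense <- bf$grads
  grads$conc_dense <- bc$grads
  d <- bf$d_in
  for (i in rev(seq_along(net$conv))) {
    bk <- conv_layer_backward(net$conv[[i]], caches$conv[[i]], d)
    grads$conv[[i]] <- bk$grads
    d <- bk$d_in
  }
  grads
}

# Flat views over trainable parameters, used by the Adam step and the
# parameter count. Order is stable: conv blocks, feature dense, conc dense,
# head.
param_slots <- function(net) {
  slots <- list()
  for (i in seq_along(net$conv)) {
    nm <- c("W", "b", if (net$conv[[i]]$batch_norm) c("gamma", "beta"))
    for (f in nm) slots[[length(slots) + 1L]] <- list(path = c("conv", i, f))
  }
  for (f in c("W", "b")) slots[[length(slots) + 1L]] <- list(path = c("feature_dense", f))
  for (f in c("W", "b")) slots[[length(slots) + 1L]] <- list(path = c("conc_dense", f))
  for (i in seq_along(net$head)) {
    for (f in c("W", "b")) slots[[length(slots) + 1L]] <- list(path = c("head", i, f))
  }
  slots
}

get_param <- function(net, path) {
  if (length(path) == 3) net[[path[1]]][[as.integer(path[2])]][[path[3]]]
  else net[[path[1]]][[path[2]]]
}

set_param <- function(net, path, value) {
  if (length(path) == 3) net[[path[1]]][[as.integer(path[2])]][[path[3]]] <- value
  else net[[path[1]]][[path[2]]] <- value
  net
}

get_grad <- function(grads, path) {
  if (length(path) == 3) grads[[path[1]]][[as.integer(path[2])]][[path[3]]]
  else grads[[path[1]]][[path[2]]]
}

adam_init <- function(net, slots) {
  list(t = 0L,
       m = lapply(slots, function(s) get_param(net, s$path) * 0),
       v = lapply(slots, function(s) get_param(net, s$path) * 0))
}

adam_step <- function(net, grads, state, slots, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1 ^ state$t
  bc2 <- 1 - beta2 ^ state$t
  for (i in seq_along(slots)) {
    g <- get_grad(grads, slots[[i]]$path)
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    upd <- lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
    set_param(net, slots[[i]]$path, get_param(net, slots[[i]]$path) - upd) -> net
  }
  list(net = net, state = state)
}
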