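# Internal neural-net primitives. Tensors are column-major R arrays with
# dims (H, W, C, N); convolution kernels have dims (k, k, Cin, Cout).
# The heavy kernels live in src/conv_ops.cpp. Convolutions inside the
# encoder/decoder are batch-normalized (conv -> BN -> ReLU); the output
# heads are plain convolutions.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

conv_fw <- function(x, p, stride = 1L, pad = 1L) {
  .conv2d_fw(x, p$W, p$b, as.integer(stride), as.integer(pad))
}

conv_bw <- function(x, p, gy, stride = 1L, pad = 1L) {
  .conv2d_bw(x, p$W, gy, as.integer(stride), as.integer(pad))
}

tconv_fw <- function(x, p) .tconv2_fw(x, p$W, p$b)
tconv_bw <- function(x, p, gy) .tconv2_bw(x, p$W, gy)

# He-normal initialization for a conv kernel of dims (k, k, Cin, Cout);
# with bn = TRUE the layer also carries batch-norm scale/shift.
init_conv <- function(k, cin, cout, gain = 2, bn = FALSE) {
  sd <- sqrt(gain / (k * k * cin))
  p <- list(W = array(stats::rnorm(k * k * cin * cout, sd = sd),
                      dim = c(k, k, cin, cout)),
            b = numeric(cout))
  if (bn) {
    p$gamma <- rep(1, cout)
    p$beta <- numeric(cout)
  }
  p
}

init_dense <- function(cin, cout, gain = 2) {
  list(W = matrix(stats::rnorm(cin * cout, sd = sqrt(gain / cin)), cin, cout),
       b = numeric(cout))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Per-channel sums over the (H, W, N) axes of an (H, W, C, N) array.
channel_sums <- function(x) {
  d <- dim(x)
  rowSums(matrix(colSums(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

# Broadcast a per-channel vector over an (H, W, C, N) shape.
bcast_channels <- function(v, d) {
  array(rep(v, each = d[1] * d[2]), dim = d)
}

# Batch normalization. In training mode the batch statistics normalize and
# the running buffers (kept in the model's `bn` environment under `key`)
# are updated; in eval mode the running statistics are used. Returns the
# normalized tensor plus what backward needs.
bn_fw <- function(z, p, bn_env, key, train) {
  d <- dim(z)
  m <- d[1] * d[2] * d[4]
  if (train) {
    mu <- channel_sums(z) / m
    var <- channel_sums(z^2) / m - mu^2
    var <- pmax(var, 0)
    buf <- bn_env[[key]]
    if (is.null(buf)) buf <- list(mean = numeric(d[3]), var = rep(1, d[3]))
    bn_env[[key]] <- list(
      mean = (1 - BN_MOMENTUM) * buf$mean + BN_MOMENTUM * mu,
      var = (1 - BN_MOMENTUM) * buf$var + BN_MOMENTUM * var)
  } else {
    buf <- bn_env[[key]]
    if (is.null(buf)) buf <- list(mean = numeric(d[3]), var = rep(1, d[3]))
    mu <- buf$mean
    var <- buf$var
  }
  inv_std <- 1 / sqrt(var + BN_EPS)
  xhat <- (z - bcast_channels(mu, d)) * bcast_channels(inv_std, d)
  out <- bcast_channels(p$gamma, d) * xhat + bcast_channels(p$beta, d)
  list(out = out, xhat = xhat, inv_std = inv_std)
}

# Backward through training-mode batch norm.
bn_bw <- function(g, p, xhat, inv_std) {
  d <- dim(g)
  m <- d[1] * d[2] * d[4]
  sg <- channel_sums(g)
  sgx <- channel_sums(g * xhat)
  gx <- bcast_channels(p$gamma * inv_std, d) *
    (g - bcast_channels(sg / m, d) - xhat * bcast_channels(sgx / m, d))
  list(gx = gx, ggamma = sgx, gbeta = sg)
}

# conv -> BN -> (optional) ReLU composite. Returns output and a cache entry.
cbr_fw <- function(x, p, bn_env, key, train, stride = 1L, pad = 1L,
                   act = TRUE) {
  z <- conv_fw(x, p, stride, pad)
  bn <- bn_fw(z, p, bn_env, key, train)
  out <- if (act) relu(bn$out) else bn$out
  list(out = out,
       cache = list(x = x, xhat = bn$xhat, inv_std = bn$inv_std,
                    mask = if (act) (bn$out > 0) else NULL,
                    stride = stride, pad = pad))
}

cbr_bw <- function(gout, p, cache) {
  g <- if (is.null(cache$mask)) gout else gout * cache$mask
  bnb <- bn_bw(g, p, cache$xhat, cache$inv_std)
  cb <- conv_bw(cache$x, p, bnb$gx, cache$stride, cache$pad)
  list(gx = cb$gx,
       grads = list(W = cb$gw, b = cb$gb, gamma = bnb$ggamma,
                    beta = bnb$gbeta))
}

# transposed conv -> BN -> ReLU composite (decoder upsampling).
tbr_fw <- function(x, p, bn_env, key, train) {
  z <- tconv_fw(x, p)
  bn <- bn_fw(z, p, bn_env, key, train)
  out <- relu(bn$out)
  list(out = out,
       cache = list(x = x, xhat = bn$xhat, inv_std = bn$inv_std,
                    mask = (bn$out > 0)))
}

tbr_bw <- function(gout, p, cache) {
  g <- gout * cache$mask
  bnb <- bn_bw(g, p, cache$xhat, cache$inv_std)
  tb <- tconv_bw(cache$x, p, bnb$gx)
  list(gx = tb$gx,
       grads = list(W = tb$gw, b = tb$gb, gamma = bnb$ggamma,
                    beta = bnb$gbeta))
}

# Channel-axis concatenation of two (H, W, C, N) arrays.
cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Walk two parallel nested lists of arrays, applying f leaf-wise.
map_leaves <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- map_leaves(a[[nm]], b[[nm]], f)
    out
  } else {
    f(a, b)
  }
}

zero_like <- function(a) {
  if (is.list(a)) lapply(a, zero_like) else a * 0
}

# Plain SGD with momentum over nested parameter lists. `frozen` names
# top-level parameter groups excluded from the update.
sgd_step <- function(params, grads, velocity, lr, momentum = 0.9,
                     frozen = character()) {
  for (grp in names(params)) {
    if (grp %in% frozen || is.null(grads[[grp]])) next
    velocity[[grp]] <- map_leaves(velocity[[grp]], grads[[grp]],
                                  function(v, g) momentum * v + g)
    params[[grp]] <- map_leaves(params[[grp]], velocity[[grp]],
                                function(p, v) p - lr * v)
  }
  list(params = params, velocity = velocity)
}

# Snapshot / restore the batch-norm buffer environment as a plain list.
bn_snapshot <- function(model) as.list(model$bn, all.names = TRUE)

bn_restore <- function(model, snap) {
  rm(list = ls(model$bn, all.names = TRUE), envir = model$bn)
  for (k in names(snap)) model$bn[[k]] <- snap[[k]]
  model
}

# Stable digest of a nested list of numerics, used to assert freezing.
params_digest <- function(x) {
  v <- unlist(x, use.names = FALSE)
  c(n = length(v), sum = sum(v), sumsq = sum(v * v))
}
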