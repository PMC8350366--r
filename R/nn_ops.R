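# Internal differentiable layer primitives. All activations are 4D arrays
# (X, Y, Z, C); parameters live in a flat named list. Each *_fwd returns
# the output plus the cache its *_bwd needs; backward passes return the
# input gradient and parameter gradients.

IN_EPS <- 1e-5

nn_conv_fwd <- function(params, name, x, k) {
  W <- params[[paste0(name, "_W")]]
  b <- params[[paste0(name, "_b")]]
  d <- dim(x)
  y <- cpp_conv3d_fwd(x, d[1:3], d[4], W, b, as.integer(k))
  list(y = y, cache = list(x = x, name = name, k = k))
}

nn_conv_bwd <- function(params, cache, gy, grads) {
  W <- params[[paste0(cache$name, "_W")]]
  d <- dim(cache$x)
  r <- cpp_conv3d_bwd(cache$x, d[1:3], d[4], W, gy, as.integer(cache$k))
  grads[[paste0(cache$name, "_W")]] <- grads[[paste0(cache$name, "_W")]] + r$dW
  grads[[paste0(cache$name, "_b")]] <- grads[[paste0(cache$name, "_b")]] + r$db
  list(dx = r$dx, grads = grads)
}

# Fused instance normalisation (per channel per sample — robust to batch
# size 1) + leaky ReLU. The backward pass recomputes the normalised
# activations from the cached input and moments rather than storing them.
nn_inlrelu_fwd <- function(params, name, x, slope) {
  g <- params[[paste0(name, "_g")]]
  b <- params[[paste0(name, "_b")]]
  d <- dim(x)
  r <- cpp_in_lrelu_fwd(x, d[1:3], d[4], g, b, slope, IN_EPS)
  list(y = r$y, cache = list(x = x, mu = r$mu, inv_sd = r$inv_sd,
                             name = name, slope = slope))
}

nn_inlrelu_bwd <- function(params, cache, gy, grads) {
  g <- params[[paste0(cache$name, "_g")]]
  b <- params[[paste0(cache$name, "_b")]]
  d <- dim(cache$x)
  r <- cpp_in_lrelu_bwd(cache$x, d[1:3], d[4], g, b, cache$slope,
                        cache$mu, cache$inv_sd, gy)
  grads[[paste0(cache$name, "_g")]] <- grads[[paste0(cache$name, "_g")]] + r$dg
  grads[[paste0(cache$name, "_b")]] <- grads[[paste0(cache$name, "_b")]] + r$db
  list(dx = r$dx, grads = grads)
}

nn_dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, cache = NULL))
  keep <- array(stats::runif(length(x)) >= rate, dim = dim(x))
  list(y = x * keep / (1 - rate), cache = list(keep = keep, rate = rate))
}

nn_dropout_bwd <- function(cache, gy) {
  if (is.null(cache)) return(gy)
  gy * cache$keep / (1 - cache$rate)
}

nn_maxpool_fwd <- function(x) {
  d <- dim(x)
  r <- cpp_maxpool2_fwd(x, d[1:3], d[4])
  list(y = r$y, cache = list(idx = r$idx, in_dims = d))
}

nn_maxpool_bwd <- function(cache, gy) {
  cpp_maxpool2_bwd(gy, cache$idx, cache$in_dims[1:3], cache$in_dims[4])
}

nn_upsample_fwd <- function(x) {
  d <- dim(x)
  cpp_upsample2_fwd(x, d[1:3], d[4])
}

nn_upsample_bwd <- function(gy, in_dims) {
  cpp_upsample2_bwd(gy, in_dims[1:3], in_dims[4])
}

sigmoid <- function(x) 1 / (1 + exp(-x))
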