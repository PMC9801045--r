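# Minimal network engine used by the accessibility model.  Activations flow
# as (channels, positions, batch) arrays; the heavy primitives (im2col
# convolution, the fused ReLU -> batch norm -> dropout unit, pooling) live in
# src/core.cpp, while the small dense head and the Adam optimizer are plain R
# matrix algebra.  Forward passes return caches that the hand-written
# backward passes consume; gradients are verified against finite differences
# in the test suite.

## ---- parameter initialisation -------------------------------------------

nn_init_conv <- function(c_in, c_out, k) {
  list(W = matrix(rnorm(c_out * c_in * k, sd = sqrt(2 / (c_in * k))),
                  nrow = c_out),
       b = rep(0, c_out))
}

nn_init_bn <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c))
}

nn_init_dense <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_out * n_in, sd = sqrt(2 / n_in)), nrow = n_out),
       b = rep(0, n_out))
}

## ---- head layers (small, kept in R) --------------------------------------

relu_fw <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, cache = mask)
}

relu_bw <- function(cache, gout) {
  gout[!cache] <- 0
  gout
}

dropout_fw <- function(x, rate, mode) {
  if (mode != "train" || rate <= 0) {
    return(list(out = x, cache = NULL))
  }
  keep <- 1 - rate
  mask <- array((runif(length(x)) < keep) / keep, dim(x) %||% length(x))
  list(out = x * mask, cache = mask)
}

dropout_bw <- function(cache, gout) {
  if (is.null(cache)) gout else gout * cache
}

dense_fw <- function(p, x) {
  list(out = p$W %*% x + p$b, cache = x)
}

dense_bw <- function(p, cache, gout) {
  list(gin = crossprod(p$W, gout),
       grads = list(W = tcrossprod(gout, cache), b = rowSums(gout)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
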