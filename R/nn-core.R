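# Minimal dense/conv1d neural-network primitives on base-R matrix algebra.
# Batched activations use a stacked layout: a (n_samples * L) x channels
# matrix whose row (s - 1) * L + l holds position l of sample s.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' @noRd
#' Gather index for 1-D convolution over the stacked batch layout.
#' Row r of the result maps output position (s, l) and kernel tap t to the
#' source row of the (zero-padded) input; out-of-range taps point at a
#' sentinel zero row appended by the forward/backward kernels.
conv1d_index <- function(L, kernel, pad, n_samples) {
  L_out <- L + 2L * pad - kernel + 1L
  zero_row <- n_samples * L + 1L
  base <- outer(seq_len(L_out) - pad - 1L, seq_len(kernel), "+") # L_out x k
  idx <- matrix(0L, n_samples * L_out, kernel)
  offsets <- rep((seq_len(n_samples) - 1L) * L, each = L_out)
  for (t in seq_len(kernel)) {
    src <- base[, t]
    ok <- src >= 1L & src <= L
    col <- rep.int(src, n_samples) + offsets
    col[!rep.int(ok, n_samples)] <- zero_row
    idx[, t] <- col
  }
  structure(idx, L = L, L_out = L_out, n_samples = n_samples)
}

#' @noRd
#' 1-D convolution as a sum of k gathered GEMMs. `W` is (kernel * C_in) x
#' C_out with kernel-tap-major row blocks; `b` length C_out.
conv1d_forward <- function(A, idx, W, b) {
  C <- ncol(A)
  k <- ncol(idx)
  Az <- rbind(A, 0)
  Z <- matrix(b, nrow(idx), length(b), byrow = TRUE)
  for (t in seq_len(k)) {
    blk <- ((t - 1L) * C + 1L):(t * C)
    Z <- Z + Az[idx[, t], , drop = FALSE] %*% W[blk, , drop = FALSE]
  }
  Z
}

#' @noRd
conv1d_backward <- function(dZ, A, idx, W) {
  C <- ncol(A)
  k <- ncol(idx)
  Az <- rbind(A, 0)
  dW <- matrix(0, nrow(W), ncol(W))
  dAz <- matrix(0, nrow(A) + 1L, C)
  for (t in seq_len(k)) {
    blk <- ((t - 1L) * C + 1L):(t * C)
    rows <- idx[, t]
    dW[blk, ] <- crossprod(Az[rows, , drop = FALSE], dZ)
    # within one tap every in-range source row appears at most once, so
    # read-modify-write assignment accumulates correctly (the sentinel
    # pad row collides with itself; its gradient is discarded anyway)
    dAz[rows, ] <- dAz[rows, , drop = FALSE] + dZ %*% t(W[blk, , drop = FALSE])
  }
  list(dW = dW, db = colSums(dZ), dA = dAz[seq_len(nrow(A)), , drop = FALSE])
}

dense_forward <- function(A, W, b) {
  sweep(A %*% W, 2L, b, "+")
}

dense_backward <- function(dZ, A, W) {
  list(dW = crossprod(A, dZ), db = colSums(dZ), dA = tcrossprod(dZ, W))
}

#' @noRd
#' Uniform fan-in initialisation (U(-1/sqrt(fan_in), 1/sqrt(fan_in))),
#' the scheme used for both dense and convolutional parameter tensors.
init_linear <- function(fan_in, fan_out) {
  bound <- 1 / sqrt(fan_in)
  list(
    W = matrix(runif(fan_in * fan_out, -bound, bound), fan_in, fan_out),
    b = runif(fan_out, -bound, bound)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cosine-annealing learning-rate schedule with warm restarts
#'
#' Returns the learning rate used during `epoch` (1-based) under a cosine
#' schedule that decays from `lr_max` towards zero and restarts at the top
#' of every `cycle`-epoch cycle, so epochs 1, 1 + cycle, 1 + 2 * cycle, ...
#' all run at `lr_max`.
#'
#' @param epoch 1-based epoch index (vectorised).
#' @param lr_max peak learning rate (the configured `learning_rate`).
#' @param cycle restart period in epochs.
#' @return numeric vector of learning rates.
#' @export
cosine_lr <- function(epoch, lr_max, cycle = 5L) {
  stopifnot(all(epoch >= 1), lr_max > 0, cycle >= 1)
  phase <- ((epoch - 1) %% cycle) / cycle
  lr_max * 0.5 * (1 + cos(pi * phase))
}
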