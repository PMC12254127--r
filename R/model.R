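#' Dual-input sgRNA activity model
#'
#' The model predicts sgRNA editing activity jointly from the guide
#' sequence and the Cas9 variant protein:
#'
#' * sgRNA branch: the 59 x 5 one-hot matrix passes through a dual-path
#'   CNN (one single convolution and one stack of three convolutions, all
#'   kernel 5 / padding 2 / 64 filters, sigmoid-activated). The two 59 x 64
#'   maps are concatenated, flattened (7552 values), passed through a
#'   2048-unit fully connected layer and projected linearly to 256.
#' * protein branch: a per-residue embedding (L x 1280 by default) passes
#'   through a multi-scale TextCNN (kernels 5/9/13, 128 ReLU filters each,
#'   global max pooling) whose 384-wide concat is mapped by a sigmoid
#'   fully connected layer to 256.
#' * fusion: a two-layer gate network on the 512-wide concat emits a
#'   per-sample scalar w in (0,1); the fused representation is
#'   `w * H_rna + (1 - w) * H_pt`, fed to a 256 -> 128 -> 1 head ending in
#'   a sigmoid.
#'
#' @name model
NULL

RNA_FILTERS <- 64L
RNA_KERNEL <- 5L
RNA_PAD <- 2L
RNA_FC1 <- 2048L
REPR_WIDTH <- 256L
PT_KERNELS <- c(5L, 9L, 13L)
PT_FILTERS <- 128L
FUSION_HIDDEN <- 128L
HEAD_HIDDEN <- 128L

#' Create an untrained model
#'
#' Parameters are drawn from a uniform fan-in scheme under `seed`, making
#' initialisation (and therefore training) reproducible.
#'
#' @param seed integer RNG seed for initialisation.
#' @param embed_width per-residue protein embedding width the model will
#'   consume (1280 for the default stub/ESM2-sized embedder).
#' @param conv_activation activation inside the sgRNA convolutions and the
#'   2048-unit layer: `"sigmoid"` (default) or `"relu"` (ablation switch).
#' @return a `casguide_model` object (parameters + architecture config).
#' @export
new_model <- function(seed = 1L, embed_width = 1280L,
                      conv_activation = c("sigmoid", "relu")) {
  conv_activation <- match.arg(conv_activation)
  set.seed(as.integer(seed))
  D <- as.integer(embed_width)
  flat_width <- SGRNA_LENGTH * 2L * RNA_FILTERS # 59 * 128 = 7552

  p <- list()
  add <- function(p, name, fan_in, fan_out) {
    lin <- init_linear(fan_in, fan_out)
    p[[paste0(name, ".W")]] <- lin$W
    p[[paste0(name, ".b")]] <- lin$b
    p
  }
  p <- add(p, "rna.conv1", RNA_KERNEL * 5L, RNA_FILTERS)
  p <- add(p, "rna.conv2a", RNA_KERNEL * 5L, RNA_FILTERS)
  p <- add(p, "rna.conv2b", RNA_KERNEL * RNA_FILTERS, RNA_FILTERS)
  p <- add(p, "rna.conv2c", RNA_KERNEL * RNA_FILTERS, RNA_FILTERS)
  p <- add(p, "rna.fc1", flat_width, RNA_FC1)
  p <- add(p, "rna.fc2", RNA_FC1, REPR_WIDTH)
  for (k in PT_KERNELS) {
    p <- add(p, paste0("pt.conv_k", k), k * D, PT_FILTERS)
  }
  p <- add(p, "pt.fc", length(PT_KERNELS) * PT_FILTERS, REPR_WIDTH)
  p <- add(p, "fus.fc1", 2L * REPR_WIDTH, FUSION_HIDDEN)
  p <- add(p, "fus.fc2", FUSION_HIDDEN, 1L)
  p <- add(p, "head.fc1", REPR_WIDTH, HEAD_HIDDEN)
  p <- add(p, "head.fc2", HEAD_HIDDEN, 1L)

  structure(list(
    params = p,
    config = list(seed = as.integer(seed), embed_width = D,
                  conv_activation = conv_activation,
                  kernel_scales = PT_KERNELS, filters_per_scale = PT_FILTERS),
    scaler = list(min = 0, max = 1),
    history = NULL
  ), class = "casguide_model")
}

#' @export
print.casguide_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat("Dual-input sgRNA activity model\n")
  cat("  parameters:       ", format(n_par, big.mark = ","), "\n")
  cat("  embedding width:  ", x$config$embed_width, "\n")
  cat("  conv activation:  ", x$config$conv_activation, "\n")
  cat("  trained:          ", if (is.null(x$history)) "no" else
    paste0(length(x$history$train_loss), " epochs"), "\n")
  invisible(x)
}

act_fun <- function(name) if (name == "relu") relu else sigmoid

act_grad <- function(name, a) if (name == "relu") (a > 0) + 0 else a * (1 - a)

#' @noRd
#' (n*L) x C stacked layout -> n x (L*C) per-sample flattening (position
#' fastest) and its inverse.
flatten_stacked <- function(H, n, L) {
  A <- array(H, c(L, n, ncol(H)))
  M <- aperm(A, c(2L, 1L, 3L))
  dim(M) <- c(n, L * ncol(H))
  M
}

unflatten_stacked <- function(M, n, L, C) {
  A <- array(M, c(n, L, C))
  H <- aperm(A, c(2L, 1L, 3L))
  dim(H) <- c(L * n, C)
  H
}

#' sgRNA dual-path encoder
#'
#' Maps one-hot guide matrices to the 256-wide branch representation
#' H_rna. Both convolutional paths preserve the 59-position axis (kernel
#' 5, padding 2) and emit 64 channels.
#'
#' @param model a `casguide_model`.
#' @param X one-hot input from [one_hot_encode()] (single 59 x 5 matrix or
#'   stacked batch).
#' @param cache return intermediate activations (used by the training
#'   loop's backward pass).
#' @return `n x 256` matrix (with `cache = TRUE`, a list holding the
#'   intermediates and `$h_rna`).
#' @export
dual_path_forward <- function(model, X, cache = FALSE) {
  p <- model$params
  act <- act_fun(model$config$conv_activation)
  n <- attr(X, "n_samples") %||% (nrow(X) / SGRNA_LENGTH)
  stopifnot(nrow(X) == n * SGRNA_LENGTH, ncol(X) == 5L)
  idx <- conv1d_index(SGRNA_LENGTH, RNA_KERNEL, RNA_PAD, n)

  a1 <- act(conv1d_forward(X, idx, p[["rna.conv1.W"]], p[["rna.conv1.b"]]))
  z1 <- act(conv1d_forward(X, idx, p[["rna.conv2a.W"]], p[["rna.conv2a.b"]]))
  z2 <- act(conv1d_forward(z1, idx, p[["rna.conv2b.W"]], p[["rna.conv2b.b"]]))
  z3 <- act(conv1d_forward(z2, idx, p[["rna.conv2c.W"]], p[["rna.conv2c.b"]]))

  Fmat <- cbind(flatten_stacked(a1, n, SGRNA_LENGTH),
                flatten_stacked(z3, n, SGRNA_LENGTH))
  f1 <- act(dense_forward(Fmat, p[["rna.fc1.W"]], p[["rna.fc1.b"]]))
  h_rna <- dense_forward(f1, p[["rna.fc2.W"]], p[["rna.fc2.b"]])
  if (!cache) return(h_rna)
  list(h_rna = h_rna, X = X, idx = idx, n = n,
       a1 = a1, z1 = z1, z2 = z2, z3 = z3, Fmat = Fmat, f1 = f1)
}

#' @noRd
dual_path_backward <- function(model, fwd, d_h_rna) {
  p <- model$params
  actg <- function(a) act_grad(model$config$conv_activation, a)
  g <- list()
  n <- fwd$n; L <- SGRNA_LENGTH

  bk <- dense_backward(d_h_rna, fwd$f1, p[["rna.fc2.W"]])
  g[["rna.fc2.W"]] <- bk$dW; g[["rna.fc2.b"]] <- bk$db
  d_f1 <- bk$dA * actg(fwd$f1)
  bk <- dense_backward(d_f1, fwd$Fmat, p[["rna.fc1.W"]])
  g[["rna.fc1.W"]] <- bk$dW; g[["rna.fc1.b"]] <- bk$db

  half <- L * RNA_FILTERS
  d_a1 <- unflatten_stacked(bk$dA[, seq_len(half), drop = FALSE], n, L, RNA_FILTERS) *
    actg(fwd$a1)
  d_z3 <- unflatten_stacked(bk$dA[, half + seq_len(half), drop = FALSE], n, L, RNA_FILTERS) *
    actg(fwd$z3)

  bk <- conv1d_backward(d_a1, fwd$X, fwd$idx, p[["rna.conv1.W"]])
  g[["rna.conv1.W"]] <- bk$dW; g[["rna.conv1.b"]] <- bk$db
  bk <- conv1d_backward(d_z3, fwd$z2, fwd$idx, p[["rna.conv2c.W"]])
  g[["rna.conv2c.W"]] <- bk$dW; g[["rna.conv2c.b"]] <- bk$db
  d_z2 <- bk$dA * actg(fwd$z2)
  bk <- conv1d_backward(d_z2, fwd$z1, fwd$idx, p[["rna.conv2b.W"]])
  g[["rna.conv2b.W"]] <- bk$dW; g[["rna.conv2b.b"]] <- bk$db
  d_z1 <- bk$dA * actg(fwd$z1)
  bk <- conv1d_backward(d_z1, fwd$X, fwd$idx, p[["rna.conv2a.W"]])
  g[["rna.conv2a.W"]] <- bk$dW; g[["rna.conv2a.b"]] <- bk$db
  g
}

#' Multi-scale TextCNN over a protein embedding
#'
#' For each kernel scale (5, 9, 13): a valid 1-D convolution with 128 ReLU
#' filters followed by global max pooling over positions; the 384-wide
#' concatenation passes through a sigmoid fully connected layer to the
#' 256-wide branch representation H_pt.
#'
#' @param model a `casguide_model`.
#' @param emb `L x D` per-residue embedding (see [embed_protein()]); `L`
#'   must be at least the largest kernel scale.
#' @param cache return intermediates for the backward pass.
#' @param cols optional precomputed window matrices from
#'   [textcnn_cols()]; the embedding is fixed during training, so the
#'   training loop builds them once per variant and each convolution
#'   reduces to one matrix product.
#' @return length-256 numeric vector (or cache list with `$h_pt`).
#' @export
textcnn_forward <- function(model, emb, cache = FALSE, cols = NULL) {
  p <- model$params
  L <- nrow(emb)
  if (ncol(emb) != model$config$embed_width) {
    stop("embedding width ", ncol(emb), " does not match the model's ",
         model$config$embed_width)
  }
  if (L < max(PT_KERNELS)) {
    stop("protein of length ", L, " is shorter than the largest kernel scale (",
         max(PT_KERNELS), ")")
  }
  if (is.null(cols)) cols <- textcnn_cols(emb)
  scales <- list()
  pooled <- numeric(0)
  for (k in PT_KERNELS) {
    nm <- paste0("pt.conv_k", k)
    Z <- relu(sweep(cols[[nm]] %*% p[[paste0(nm, ".W")]], 2L,
                    p[[paste0(nm, ".b")]], "+"))
    amax <- max.col(t(Z), ties.method = "first")
    pool <- Z[cbind(amax, seq_len(ncol(Z)))]
    scales[[nm]] <- list(Z = Z, amax = amax)
    pooled <- c(pooled, pool)
  }
  z_cat <- matrix(pooled, 1L)
  h_pt <- sigmoid(dense_forward(z_cat, p[["pt.fc.W"]], p[["pt.fc.b"]]))
  if (!cache) return(drop(h_pt))
  list(h_pt = drop(h_pt), cols = cols, scales = scales, z_cat = z_cat,
       h_act = h_pt)
}

#' Precompute TextCNN convolution windows for a fixed embedding
#'
#' @param emb `L x D` protein embedding.
#' @param kernels kernel scales to build windows for.
#' @return named list (one per kernel scale) of `(L - k + 1) x (k * D)`
#'   window matrices.
#' @export
textcnn_cols <- function(emb, kernels = PT_KERNELS) {
  L <- nrow(emb); C <- ncol(emb)
  out <- list()
  for (k in kernels) {
    idx <- conv1d_index(L, k, 0L, 1L)
    Xc <- matrix(0, nrow(idx), k * C)
    for (t in seq_len(k)) {
      Xc[, (t - 1L) * C + seq_len(C)] <- emb[idx[, t], , drop = FALSE]
    }
    out[[paste0("pt.conv_k", k)]] <- Xc
  }
  out
}

#' @noRd
#' d_h_pt: length-256 gradient summed over the samples carrying this
#' variant (the embedding is shared, so branch work is done once per
#' variant and its gradient is the within-variant sum).
textcnn_backward <- function(model, fwd, d_h_pt) {
  p <- model$params
  g <- list()
  d_pre <- matrix(d_h_pt, 1L) * (fwd$h_act * (1 - fwd$h_act))
  bk <- dense_backward(d_pre, fwd$z_cat, p[["pt.fc.W"]])
  g[["pt.fc.W"]] <- bk$dW; g[["pt.fc.b"]] <- bk$db
  off <- 0L
  for (k in PT_KERNELS) {
    nm <- paste0("pt.conv_k", k)
    sc <- fwd$scales[[nm]]
    d_pool <- bk$dA[1L, off + seq_len(PT_FILTERS)]
    off <- off + PT_FILTERS
    # gradient reaches only the argmax row of each feature map, and the
    # embedding itself is fixed, so dW is a single cross product over
    # the (sparse) pooled gradient
    dZ <- matrix(0, nrow(sc$Z), ncol(sc$Z))
    dZ[cbind(sc$amax, seq_len(PT_FILTERS))] <- d_pool
    dZ <- dZ * (sc$Z > 0)
    g[[paste0(nm, ".W")]] <- crossprod(fwd$cols[[nm]], dZ)
    g[[paste0(nm, ".b")]] <- colSums(dZ)
  }
  g
}

#' Dynamic weight fusion of the two branch representations
#'
#' A two-layer gate network (inner ReLU, outer sigmoid) on the 512-wide
#' concatenation emits one scalar `w` per sample; the fused vector is the
#' convex combination `w * h_rna + (1 - w) * h_pt`, so `w` is the learned
#' share of the sgRNA branch and `1 - w` the protein branch's.
#'
#' @param model a `casguide_model`.
#' @param h_rna `n x 256` sgRNA representations.
#' @param h_pt `n x 256` protein representations (one row per sample).
#' @param cache return intermediates.
#' @return list with `fused` (`n x 256`) and `w` (length-n vector in
#'   (0,1)).
#' @export
fuse_representations <- function(model, h_rna, h_pt, cache = FALSE) {
  p <- model$params
  h_rna <- rbind(h_rna); h_pt <- rbind(h_pt)
  if (ncol(h_rna) != ncol(h_pt)) {
    stop("branch representation widths differ (", ncol(h_rna), " vs ",
         ncol(h_pt), ")")
  }
  zc <- cbind(h_rna, h_pt)
  af <- relu(dense_forward(zc, p[["fus.fc1.W"]], p[["fus.fc1.b"]]))
  w <- sigmoid(dense_forward(af, p[["fus.fc2.W"]], p[["fus.fc2.b"]]))
  fused <- h_rna * drop(w) + h_pt * (1 - drop(w))
  out <- list(fused = fused, w = drop(w))
  if (cache) out <- c(out, list(zc = zc, af = af, h_rna = h_rna, h_pt = h_pt))
  out
}

#' @noRd
model_forward <- function(model, X, h_pt_rows, cache = FALSE) {
  p <- model$params
  rna <- dual_path_forward(model, X, cache = TRUE)
  fus <- fuse_representations(model, rna$h_rna, h_pt_rows, cache = TRUE)
  ah <- relu(dense_forward(fus$fused, p[["head.fc1.W"]], p[["head.fc1.b"]]))
  yhat <- sigmoid(dense_forward(ah, p[["head.fc2.W"]], p[["head.fc2.b"]]))
  if (!cache) return(drop(yhat))
  list(yhat = drop(yhat), rna = rna, fus = fus, ah = ah, y_act = yhat)
}

#' @noRd
#' Full backward pass. `pt_caches` maps variant name -> textcnn_forward
#' cache; `variant_of` gives each sample's variant. Returns the gradient
#' list aligned with model$params.
model_backward <- function(model, fwd, d_yhat, pt_caches, variant_of) {
  p <- model$params
  g <- list()
  d_pre <- matrix(d_yhat, ncol = 1L) * (fwd$y_act * (1 - fwd$y_act))
  bk <- dense_backward(d_pre, fwd$ah, p[["head.fc2.W"]])
  g[["head.fc2.W"]] <- bk$dW; g[["head.fc2.b"]] <- bk$db
  d_ah <- bk$dA * (fwd$ah > 0)
  bk <- dense_backward(d_ah, fwd$fus$fused, p[["head.fc1.W"]])
  g[["head.fc1.W"]] <- bk$dW; g[["head.fc1.b"]] <- bk$db
  d_fused <- bk$dA

  fus <- fwd$fus
  w <- fus$w
  d_w <- rowSums(d_fused * (fus$h_rna - fus$h_pt))
  d_wpre <- matrix(d_w * w * (1 - w), ncol = 1L)
  bk <- dense_backward(d_wpre, fus$af, p[["fus.fc2.W"]])
  g[["fus.fc2.W"]] <- bk$dW; g[["fus.fc2.b"]] <- bk$db
  d_af <- bk$dA * (fus$af > 0)
  bk <- dense_backward(d_af, fus$zc, p[["fus.fc1.W"]])
  g[["fus.fc1.W"]] <- bk$dW; g[["fus.fc1.b"]] <- bk$db

  half <- REPR_WIDTH
  d_h_rna <- d_fused * w + bk$dA[, seq_len(half), drop = FALSE]
  d_h_pt <- d_fused * (1 - w) + bk$dA[, half + seq_len(half), drop = FALSE]

  g <- c(g, dual_path_backward(model, fwd$rna, d_h_rna))

  pt_g <- NULL
  for (v in names(pt_caches)) {
    rows <- which(variant_of == v)
    if (!length(rows)) next
    dv <- colSums(d_h_pt[rows, , drop = FALSE])
    gv <- textcnn_backward(model, pt_caches[[v]], dv)
    pt_g <- if (is.null(pt_g)) gv else Map(`+`, pt_g, gv)
  }
  g <- c(g, pt_g)
  g[names(p)]
}

#' Predict sgRNA activity
#'
#' @param object a `casguide_model`.
#' @param records data.frame of sgRNA records (`sequence`, `variant`).
#' @param embeddings named list of protein embeddings, one per variant
#'   label occurring in `records` (see [embed_protein()]).
#' @param rescale map the sigmoid output back to the activity scale seen
#'   at training time (inverse of the stored min-max scaler). With an
#'   untrained model the scaler is the identity on [0, 1].
#' @param ... unused.
#' @return numeric vector of predicted activities; strictly inside the
#'   training activity range (the open unit interval before rescaling).
#' @export
predict.casguide_model <- function(object, records, embeddings,
                                   rescale = TRUE, ...) {
  missing <- setdiff(unique(records$variant), names(embeddings))
  if (length(missing)) {
    stop("no protein embedding available for variant(s): ",
         paste(missing, collapse = ", "))
  }
  X <- one_hot_encode(records$sequence)
  h_pt <- vapply(embeddings[unique(records$variant)],
                 function(e) textcnn_forward(object, e),
                 numeric(REPR_WIDTH))
  h_pt_rows <- t(h_pt)[match(records$variant, unique(records$variant)), ,
                       drop = FALSE]
  yhat <- model_forward(object, X, h_pt_rows)
  if (rescale) {
    s <- object$scaler
    yhat <- s$min + yhat * (s$max - s$min)
  }
  unname(yhat)
}
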