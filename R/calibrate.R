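#' Variance-calibrating initialisation
#'
#' One-hot genomic inputs with long constant segments (the 36-nt
#' scaffold, the GG of the PAM) give freshly initialised networks
#' activations dominated by a sample-independent offset: the
#' between-sample signal reaching the regression head is orders of
#' magnitude smaller than the activations themselves, and training from
#' a plain fan-in initialisation spends most of its budget re-scaling
#' layers. `calibrate_model` removes that offset at initialisation: in a
#' single forward sweep over a probe batch it centres every layer's
#' preactivations (folding the mean into the bias) and rescales weights
#' so preactivation standard deviation over the probe is 1 (0.5 for the
#' output logit). The procedure is deterministic given the model seed
#' and the probe data, and leaves the architecture untouched.
#'
#' @param model an untrained `casguide_model`.
#' @param records probe sgRNA records (a few hundred suffice; the
#'   training loop passes a subset of the training set).
#' @param embeddings named list of protein embeddings covering the probe
#'   records' variants.
#' @return the model with calibrated parameters.
#' @export
calibrate_model <- function(model, records, embeddings) {
  p <- model$params
  act <- act_fun(model$config$conv_activation)
  n <- nrow(records)
  L <- SGRNA_LENGTH
  X <- one_hot_encode(records$sequence)
  idx <- conv1d_index(L, RNA_KERNEL, RNA_PAD, n)

  # centre to zero-mean, rescale to unit sd, fold the shift into biases
  adjust <- function(p, name, Z, target = 1) {
    mu <- colMeans(Z)
    s <- pmax(apply(Z, 2L, stats::sd), 1e-6) / target
    p[[paste0(name, ".W")]] <- sweep(p[[paste0(name, ".W")]], 2L, s, "/")
    p[[paste0(name, ".b")]] <- (p[[paste0(name, ".b")]] - mu) / s
    p
  }
  conv_step <- function(p, name, A) {
    Z <- conv1d_forward(A, idx, p[[paste0(name, ".W")]], p[[paste0(name, ".b")]])
    p <- adjust(p, name, Z)
    list(p = p, A = act(conv1d_forward(A, idx, p[[paste0(name, ".W")]],
                                       p[[paste0(name, ".b")]])))
  }

  st <- conv_step(p, "rna.conv1", X); p <- st$p; a1 <- st$A
  st <- conv_step(p, "rna.conv2a", X); p <- st$p; z <- st$A
  st <- conv_step(p, "rna.conv2b", z); p <- st$p; z <- st$A
  st <- conv_step(p, "rna.conv2c", z); p <- st$p; z3 <- st$A

  Fmat <- cbind(flatten_stacked(a1, n, L), flatten_stacked(z3, n, L))
  Z <- dense_forward(Fmat, p[["rna.fc1.W"]], p[["rna.fc1.b"]])
  p <- adjust(p, "rna.fc1", Z)
  f1 <- act(dense_forward(Fmat, p[["rna.fc1.W"]], p[["rna.fc1.b"]]))
  Z <- dense_forward(f1, p[["rna.fc2.W"]], p[["rna.fc2.b"]])
  p <- adjust(p, "rna.fc2", Z)
  h_rna <- dense_forward(f1, p[["rna.fc2.W"]], p[["rna.fc2.b"]])

  # protein branch: probe over the distinct variants
  model$params <- p
  uv <- unique(records$variant)
  pool_rows <- function() {
    t(vapply(uv, function(v) {
      fwd <- textcnn_forward(model, embeddings[[v]], cache = TRUE)
      drop(fwd$z_cat)
    }, numeric(length(PT_KERNELS) * PT_FILTERS)))
  }
  if (length(uv) >= 2L) {
    for (k in PT_KERNELS) {
      nm <- paste0("pt.conv_k", k)
      Zs <- do.call(rbind, lapply(uv, function(v) {
        emb <- embeddings[[v]]
        conv1d_forward(emb, conv1d_index(nrow(emb), k, 0L, 1L),
                       p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]])
      }))
      p <- adjust(p, nm, Zs)
    }
    model$params <- p
    zc <- pool_rows()
    Z <- dense_forward(zc, p[["pt.fc.W"]], p[["pt.fc.b"]])
    p <- adjust(p, "pt.fc", Z)
    model$params <- p
  }
  h_pt <- t(vapply(uv, function(v) textcnn_forward(model, embeddings[[v]]),
                   numeric(REPR_WIDTH)))[match(records$variant, uv), ,
                                         drop = FALSE]

  # fusion gate and prediction head on the calibrated representations
  zcomb <- cbind(h_rna, h_pt)
  Z <- dense_forward(zcomb, p[["fus.fc1.W"]], p[["fus.fc1.b"]])
  p <- adjust(p, "fus.fc1", Z)
  af <- relu(dense_forward(zcomb, p[["fus.fc1.W"]], p[["fus.fc1.b"]]))
  p <- adjust(p, "fus.fc2", dense_forward(af, p[["fus.fc2.W"]], p[["fus.fc2.b"]]))

  model$params <- p
  fus <- fuse_representations(model, h_rna, h_pt)
  Z <- dense_forward(fus$fused, p[["head.fc1.W"]], p[["head.fc1.b"]])
  p <- adjust(p, "head.fc1", Z)
  ah <- relu(dense_forward(fus$fused, p[["head.fc1.W"]], p[["head.fc1.b"]]))
  p <- adjust(p, "head.fc2",
              dense_forward(ah, p[["head.fc2.W"]], p[["head.fc2.b"]]),
              target = 0.5)

  model$params <- p
  model$config$calibrated <- TRUE
  model
}
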