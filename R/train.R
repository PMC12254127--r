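#' Training configuration
#'
#' Defaults are the package's reference configuration:
#' learning rate 1e-4, batch size 256, 100 epochs, Adam on an MSE loss,
#' cosine-annealing schedule restarting every 5 epochs.
#'
#' @param learning_rate peak learning rate (cosine schedule decays from
#'   it within each cycle).
#' @param batch_size minibatch size.
#' @param epochs number of passes over the training set.
#' @param optimizer only `"adam"` is implemented.
#' @param loss only `"mse"` is implemented.
#' @param scheduler `"cosine"` (warm restarts) or `"constant"`.
#' @param scheduler_cycle restart period of the cosine schedule, epochs.
#' @param seed RNG seed for initialisation and batch shuffling.
#' @return a `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 256L,
                            epochs = 100L, optimizer = "adam", loss = "mse",
                            scheduler = "cosine", scheduler_cycle = 5L,
                            seed = 1L) {
  stopifnot(learning_rate >= 0, batch_size >= 1, epochs >= 0)
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "mse")
  scheduler <- match.arg(scheduler, c("cosine", "constant"))
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 loss = loss, scheduler = scheduler,
                 scheduler_cycle = as.integer(scheduler_cycle),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' The reference hyperparameter grid
#'
#' @return list with `learning_rates`, `batch_sizes`, `epoch_counts`
#'   (4 x 4 x 3 = 48 combinations).
#' @export
grid_space <- function(learning_rates = c(1e-4, 5e-4, 1e-3, 5e-3),
                       batch_sizes = c(64L, 128L, 256L, 512L),
                       epoch_counts = c(50L, 100L, 200L)) {
  list(learning_rates = learning_rates, batch_sizes = as.integer(batch_sizes),
       epoch_counts = as.integer(epoch_counts))
}

#' @noRd
#' Min-max scaler over training activities; degenerate (constant) targets
#' map to 0.5 so the sigmoid head has a reachable value.
fit_scaler <- function(activity) {
  lo <- min(activity); hi <- max(activity)
  if (hi <= lo) {
    lo <- lo - 0.5; hi <- lo + 1
  }
  list(min = lo, max = hi)
}

scale_activity <- function(activity, scaler) {
  (activity - scaler$min) / (scaler$max - scaler$min)
}

#' @noRd
#' Forward pass over a record set in scaled space. Recomputes the protein
#' branch once per unique variant.
forward_records <- function(model, X, variant_of, embeddings, cols = NULL) {
  uv <- unique(variant_of)
  h_pt <- vapply(uv, function(v) {
    textcnn_forward(model, embeddings[[v]], cols = cols[[v]])
  }, numeric(REPR_WIDTH))
  h_pt_rows <- t(h_pt)[match(variant_of, uv), , drop = FALSE]
  model_forward(model, X, h_pt_rows)
}

#' Train the dual-input model
#'
#' Activities are min-max scaled to [0, 1] (the sigmoid head bounds the
#' output); the scaler is stored on the model and inverted by
#' [predict.casguide_model()]. Batches are reshuffled every epoch under
#' the run seed and mix all variants. When a validation set is given, the
#' returned parameters are the checkpoint with the best validation
#' Spearman; otherwise the final epoch's.
#'
#' @param records training data.frame (`sequence`, `activity`, `variant`).
#' @param embeddings named list of protein embeddings covering every
#'   variant label in `records` (and `val`).
#' @param config a [training_config()].
#' @param val optional validation data.frame of the same shape.
#' @param model optionally, a pre-initialised or pre-trained
#'   `casguide_model` to continue from (skips calibration).
#' @param calibrate apply the variance-calibrating initialisation
#'   ([calibrate_model()]) on a probe of the training data before the
#'   first epoch. Off by default: it speeds loss convergence on pooled
#'   multi-variant data but can destabilise rank ordering on small
#'   single-variant sets.
#' @param verbose print per-epoch losses.
#' @return a trained `casguide_model`; `$history` holds per-epoch
#'   `train_loss`, `val_loss`, `val_spearman`, `lr` and `best_epoch`.
#' @export
train_model <- function(records, embeddings, config = training_config(),
                        val = NULL, model = NULL, calibrate = FALSE,
                        verbose = FALSE) {
  stopifnot(inherits(config, "training_config"))
  if (!nrow(records)) stop("empty training set")
  if (!length(embeddings)) stop("empty variant embedding map")
  missing <- setdiff(unique(c(records$variant, val$variant)), names(embeddings))
  if (length(missing)) {
    stop("no protein embedding for variant(s): ", paste(missing, collapse = ", "))
  }

  if (is.null(model)) {
    model <- new_model(seed = config$seed,
                       embed_width = ncol(embeddings[[1]]))
    if (calibrate) {
      set.seed(config$seed)
      probe <- records[sample.int(nrow(records),
                                  min(nrow(records), 512L)), , drop = FALSE]
      model <- calibrate_model(model, probe, embeddings)
    }
  }
  model$scaler <- fit_scaler(records$activity)
  y <- scale_activity(records$activity, model$scaler)
  n <- nrow(records)
  L <- SGRNA_LENGTH

  X_all <- one_hot_encode(records$sequence)
  Xv_all <- if (!is.null(val)) one_hot_encode(val$sequence) else NULL
  yv <- if (!is.null(val)) scale_activity(val$activity, model$scaler) else NULL

  # embeddings are constant through training: precompute their
  # convolution windows once per variant
  used_vars <- unique(c(records$variant, val$variant))
  emb_cols <- lapply(embeddings[used_vars], textcnn_cols)

  # exclusive deep copies: the optimizer updates tensors in place
  model$params <- lapply(model$params, function(x) x + 0)
  opt_m <- lapply(model$params, function(p) p * 0)
  opt_v <- lapply(model$params, function(p) p * 0)
  opt_t <- 0L
  hist <- list(train_loss = numeric(0), val_loss = numeric(0),
               val_spearman = numeric(0), lr = numeric(0))
  best <- list(rho = -Inf, params = NULL, epoch = NA_integer_)
  set.seed(config$seed)

  for (epoch in seq_len(config$epochs)) {
    lr <- if (config$scheduler == "cosine") {
      cosine_lr(epoch, config$learning_rate, config$scheduler_cycle)
    } else {
      config$learning_rate
    }
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (b in batches) {
      rows <- rep((b - 1L) * L, each = L) + seq_len(L)
      Xb <- X_all[rows, , drop = FALSE]
      attr(Xb, "n_samples") <- length(b); attr(Xb, "L") <- L
      vb <- records$variant[b]
      uv <- unique(vb)
      pt_caches <- lapply(uv, function(v) {
        textcnn_forward(model, embeddings[[v]], cache = TRUE,
                        cols = emb_cols[[v]])
      })
      names(pt_caches) <- uv
      h_pt_rows <- t(vapply(pt_caches, `[[`, numeric(REPR_WIDTH), "h_pt"))[
        match(vb, uv), , drop = FALSE]
      fwd <- model_forward(model, Xb, h_pt_rows, cache = TRUE)
      resid <- fwd$yhat - y[b]
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        stop("training diverged: non-finite loss at epoch ", epoch,
             " (learning rate ", lr, "); lower the learning rate")
      }
      ep_loss <- ep_loss + loss * length(b)
      if (lr > 0) {
        grads <- model_backward(model, fwd, 2 * resid / length(b),
                                pt_caches, vb)
        opt_t <- opt_t + 1L
        bc1 <- 1 - 0.9^opt_t
        bc2 <- 1 - 0.999^opt_t
        for (nm in names(model$params)) {
          adam_update_inplace(model$params[[nm]], grads[[nm]],
                              opt_m[[nm]], opt_v[[nm]],
                              lr, 0.9, 0.999, 1e-8, bc1, bc2)
        }
      }
    }
    hist$train_loss <- c(hist$train_loss, ep_loss / n)
    hist$lr <- c(hist$lr, lr)
    if (!is.null(val)) {
      yhat_v <- forward_records(model, Xv_all, val$variant, embeddings,
                                cols = emb_cols)
      hist$val_loss <- c(hist$val_loss, mean((yhat_v - yv)^2))
      rho <- tryCatch(spearman(yhat_v, yv)$rho, error = function(e) NA_real_)
      hist$val_spearman <- c(hist$val_spearman, rho)
      if (is.finite(rho) && rho > best$rho) {
        # deep copy: in-place optimizer updates must not reach the checkpoint
        best <- list(rho = rho, params = lapply(model$params, function(x) x + 0),
                     epoch = epoch)
      }
    }
    if (verbose) {
      cat(sprintf("epoch %3d  lr %.2e  train MSE %.5f%s\n", epoch, lr,
                  ep_loss / n,
                  if (!is.null(val)) sprintf("  val MSE %.5f  val rho %.4f",
                                             utils::tail(hist$val_loss, 1),
                                             utils::tail(hist$val_spearman, 1))
                  else ""))
    }
  }

  if (!is.null(best$params)) {
    model$params <- best$params
    hist$best_epoch <- best$epoch
  } else {
    hist$best_epoch <- config$epochs
  }
  model$history <- hist
  model$config$training <- config
  model
}

#' Exhaustive hyperparameter grid search
#'
#' Enumerates the Cartesian product of the grid, trains one model per
#' combination and returns the configuration maximising validation
#' Spearman, with the full leaderboard.
#'
#' @param records,embeddings,val as in [train_model()] (`val` required).
#' @param space a [grid_space()].
#' @param seed run seed shared by all candidate configs.
#' @param verbose print one line per candidate.
#' @return list with `best_config` (a [training_config()]), `best_model`,
#'   and `leaderboard` (data.frame sorted by validation Spearman).
#' @export
grid_search <- function(records, embeddings, val, space = grid_space(),
                        seed = 1L, verbose = FALSE) {
  if (is.null(val) || !nrow(val)) stop("grid search needs a validation set")
  grid <- expand.grid(learning_rate = space$learning_rates,
                      batch_size = space$batch_sizes,
                      epochs = space$epoch_counts,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  best <- list(rho = -Inf, config = NULL, model = NULL)
  for (i in seq_len(nrow(grid))) {
    cfg <- training_config(learning_rate = grid$learning_rate[i],
                           batch_size = grid$batch_size[i],
                           epochs = grid$epochs[i], seed = seed)
    fit <- tryCatch(train_model(records, embeddings, cfg, val = val),
                    error = function(e) e)
    rho <- if (inherits(fit, "error")) NA_real_ else max(fit$history$val_spearman)
    rows[[i]] <- data.frame(learning_rate = cfg$learning_rate,
                            batch_size = cfg$batch_size, epochs = cfg$epochs,
                            val_spearman = rho)
    if (verbose) {
      cat(sprintf("lr %.4g  batch %d  epochs %d  ->  val rho %s\n",
                  cfg$learning_rate, cfg$batch_size, cfg$epochs,
                  format(rho, digits = 4)))
    }
    if (is.finite(rho) && rho > best$rho) {
      best <- list(rho = rho, config = cfg, model = fit)
    }
  }
  leaderboard <- do.call(rbind, rows)
  leaderboard <- leaderboard[order(-leaderboard$val_spearman), ]
  rownames(leaderboard) <- NULL
  if (is.null(best$config)) stop("every grid candidate failed to train")
  list(best_config = best$config, best_model = best$model,
       leaderboard = leaderboard)
}
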