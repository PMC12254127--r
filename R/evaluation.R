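#' Spearman rank correlation
#'
#' Computed as the Pearson correlation of average-tie ranks, which on
#' tie-free data equals the classical closed form
#' `rho = 1 - 6 * sum(d_i^2) / (n * (n^2 - 1))` with `d_i` the per-item
#' rank difference.
#'
#' @param pred,truth equal-length numeric vectors, `n >= 2`.
#' @return a `spearman_result`: list with `rho` and `n`.
#' @examples
#' spearman(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$rho # 0.8
#' @export
spearman <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("prediction and truth vectors have different lengths (",
         length(pred), " vs ", length(truth), ")")
  }
  n <- length(pred)
  if (n < 2L) stop("Spearman correlation needs at least 2 observations")
  if (any(!is.finite(pred)) || any(!is.finite(truth))) {
    stop("non-finite values in Spearman input")
  }
  r1 <- rank(pred, ties.method = "average")
  r2 <- rank(truth, ties.method = "average")
  d1 <- r1 - mean(r1); d2 <- r2 - mean(r2)
  v1 <- sum(d1^2); v2 <- sum(d2^2)
  if (v1 == 0 || v2 == 0) {
    stop("Spearman correlation undefined for constant input (zero rank variance)")
  }
  structure(list(rho = sum(d1 * d2) / sqrt(v1 * v2), n = n),
            class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f (n = %d)\n", x$rho, x$n))
  invisible(x)
}

#' 7:1:2 train/validation/test split
#'
#' Uniform random partition into 70% / 10% / 20% by
#' floor-then-largest-remainder allocation, reproducible under `seed`.
#'
#' @param records data.frame of sgRNA records.
#' @param seed integer seed.
#' @param ratios length-3 proportions summing to 1.
#' @return list with `train`, `val`, `test` data.frames (attributes
#'   `indices` holds the row indices used).
#' @export
split_712 <- function(records, seed = 1L, ratios = c(0.7, 0.1, 0.2)) {
  n <- nrow(records)
  if (n < 10L) stop("need at least 10 records to split (got ", n, ")")
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-9)
  raw <- n * ratios
  sizes <- floor(raw)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  idx <- list(train = ord[seq_len(sizes[1])],
              val = ord[sizes[1] + seq_len(sizes[2])],
              test = ord[sizes[1] + sizes[2] + seq_len(sizes[3])])
  out <- lapply(idx, function(i) records[i, , drop = FALSE])
  attr(out, "indices") <- idx
  out
}

#' Build a deployment-scenario split
#'
#' Datasets are classed as small-scale ("newly identified" variants) when
#' their total size is below `size_threshold`, else large-scale
#' ("well-established"). The three scenarios are:
#'
#' * `well_established`: train and test on the large datasets only.
#' * `newly_identified`: train on every dataset's training split
#'   (including the small variants' few records); test on the small
#'   variants' test splits.
#' * `newly_discovered`: train on the large datasets' training splits
#'   only -- zero records from the small variants -- and test on exactly
#'   the same small-variant test splits as `newly_identified`.
#'
#' @param datasets named list of record data.frames (one per dataset,
#'   each with a `variant` column).
#' @param scenario one of the three scenario names.
#' @param size_threshold small/large cut on total dataset size.
#' @param seed seed forwarded to each dataset's [split_712()].
#' @return a `scenario_split`: list with `scenario`, `train`, `val`,
#'   `test` (data.frames carrying a `dataset` column), and the small /
#'   large dataset names.
#' @export
build_scenario <- function(datasets,
                           scenario = c("well_established", "newly_identified",
                                        "newly_discovered"),
                           size_threshold = 1500L, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(length(datasets) >= 1L, !is.null(names(datasets)))
  sizes <- vapply(datasets, nrow, integer(1))
  small <- names(datasets)[sizes < size_threshold]
  large <- setdiff(names(datasets), small)

  splits <- lapply(names(datasets), function(nm) {
    sp <- split_712(datasets[[nm]], seed = seed)
    lapply(sp, function(df) {
      if (nrow(df)) df$dataset <- nm
      df
    })
  })
  names(splits) <- names(datasets)

  pick <- function(part, from) {
    do.call(rbind, c(lapply(splits[from], `[[`, part),
                     list(make.row.names = FALSE)))
  }
  train_from <- switch(scenario,
    well_established = large,
    newly_identified = names(datasets),
    newly_discovered = large)
  test_from <- switch(scenario,
    well_established = large,
    newly_identified = small,
    newly_discovered = small)
  if (!length(train_from)) {
    stop("scenario '", scenario, "' has no qualifying training datasets")
  }
  if (!length(test_from)) {
    stop("scenario '", scenario, "' has no qualifying test datasets ",
         "(no dataset ", if (scenario == "well_established") ">= " else "< ",
         size_threshold, " records)")
  }
  structure(list(scenario = scenario,
                 train = pick("train", train_from),
                 val = pick("val", train_from),
                 test = pick("test", test_from),
                 small = small, large = large,
                 size_threshold = size_threshold, seed = as.integer(seed)),
            class = "scenario_split")
}

#' @export
print.scenario_split <- function(x, ...) {
  cat("Scenario '", x$scenario, "': train ", nrow(x$train), ", val ",
      nrow(x$val), ", test ", nrow(x$test), " records\n", sep = "")
  cat("  small-scale datasets: ",
      if (length(x$small)) paste(x$small, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Variant-specific vs cross-variant training protocols
#'
#' `variant_specific` trains one model per dataset on that dataset's own
#' training split; `cross_variant` pools every dataset's training split
#' into a single model conditioned on the variant protein. Both are
#' evaluated on each dataset's held-out test split.
#'
#' @param datasets named list of record data.frames.
#' @param embeddings named list of protein embeddings covering every
#'   variant.
#' @param strategy `"variant_specific"` or `"cross_variant"`.
#' @param config a [training_config()].
#' @param seed split seed.
#' @return list with `results` (tidy data.frame: dataset, variant,
#'   strategy, n_test, spearman) and `models`.
#' @export
run_protocol <- function(datasets, embeddings,
                         strategy = c("cross_variant", "variant_specific"),
                         config = training_config(), seed = 1L) {
  strategy <- match.arg(strategy)
  splits <- lapply(datasets, split_712, seed = seed)

  models <- list()
  if (strategy == "cross_variant") {
    train <- do.call(rbind, c(lapply(splits, `[[`, "train"),
                              list(make.row.names = FALSE)))
    val <- do.call(rbind, c(lapply(splits, `[[`, "val"),
                            list(make.row.names = FALSE)))
    models[["pooled"]] <- train_model(train, embeddings, config, val = val)
  } else {
    for (nm in names(datasets)) {
      models[[nm]] <- train_model(splits[[nm]]$train, embeddings, config,
                                  val = splits[[nm]]$val)
    }
  }

  rows <- lapply(names(datasets), function(nm) {
    model <- if (strategy == "cross_variant") models[["pooled"]] else models[[nm]]
    test <- splits[[nm]]$test
    pred <- predict(model, test, embeddings, rescale = FALSE)
    data.frame(dataset = nm, variant = test$variant[1], strategy = strategy,
               n_test = nrow(test), spearman = spearman(pred, test$activity)$rho)
  })
  list(results = do.call(rbind, rows), models = models)
}
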