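test_that("training defaults mirror the reference configuration", {
  cfg <- training_config()
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$batch_size, 256L)
  expect_equal(cfg$epochs, 100L)
  expect_equal(cfg$optimizer, "adam")
  expect_equal(cfg$loss, "mse")
  expect_equal(cfg$scheduler, "cosine")
  expect_equal(cfg$scheduler_cycle, 5L)

  sp <- grid_space()
  expect_equal(sp$learning_rates, c(1e-4, 5e-4, 1e-3, 5e-3))
  expect_equal(sp$batch_sizes, c(64L, 128L, 256L, 512L))
  expect_equal(sp$epoch_counts, c(50L, 100L, 200L))
})

test_that("the cosine schedule restarts at the configured peak every cycle", {
  lr <- cosine_lr(1:20, lr_max = 1e-3, cycle = 5)
  expect_equal(lr[c(1, 6, 11, 16)], rep(1e-3, 4))
  # strictly decreasing within a cycle
  expect_true(all(diff(lr[1:5]) < 0))
  expect_true(all(diff(lr[6:10]) < 0))
  expect_true(all(lr > 0 & lr <= 1e-3))
  # epoch 1 + cycle/2 sits at half amplitude plus the cosine offset
  expect_equal(cosine_lr(3.5, 1, 5), 0.5)
})

test_that("a zero learning rate leaves parameters untouched", {
  embs <- fixture_embeddings()
  recs <- fixture_records(n_guides = 5)$records
  cfg <- training_config(learning_rate = 0, epochs = 1, scheduler = "constant",
                         seed = 3)
  m0 <- new_model(seed = 3, embed_width = 32)
  fit <- train_model(recs, embs, cfg, model = m0)
  expect_equal(fit$params, m0$params, tolerance = 0)
  expect_length(fit$history$train_loss, 1L)
})

test_that("MSE converges towards zero on a constant-target dataset", {
  embs <- fixture_embeddings()
  recs <- fixture_records(n_guides = 6)$records
  recs$activity <- 0.4
  cfg <- training_config(epochs = 12, seed = 4)
  fit <- train_model(recs, embs, cfg)
  loss <- fit$history$train_loss
  # momentum makes individual epochs wiggle; the running best is monotone
  # by construction and the tail must sit essentially at zero
  expect_lt(mean(tail(loss, 3)), 1e-3)
  expect_lte(min(loss), loss[1])
  expect_true(all(loss < 0.05))
})

test_that("training records history, stores the scaler and inverts it at prediction", {
  embs <- fixture_embeddings()
  sim <- fixture_records(n_guides = 8, seed = 21)
  recs <- sim$records
  recs$activity <- recs$activity * 30 + 10 # activities far outside [0,1]
  cfg <- training_config(epochs = 3, seed = 5)
  fit <- train_model(recs, embs, cfg, val = recs[1:6, ])
  expect_length(fit$history$train_loss, 3L)
  expect_length(fit$history$val_spearman, 3L)
  expect_equal(fit$scaler$min, min(recs$activity))
  expect_equal(fit$scaler$max, max(recs$activity))
  pred <- predict(fit, recs, embs)
  expect_true(all(pred > 10 & pred < 40))
  # raw predictions stay in the unit interval
  raw <- predict(fit, recs, embs, rescale = FALSE)
  expect_true(all(raw > 0 & raw < 1))
})

test_that("training is reproducible under a fixed seed", {
  embs <- fixture_embeddings()
  recs <- fixture_records(n_guides = 5)$records
  cfg <- training_config(epochs = 2, seed = 11)
  f1 <- train_model(recs, embs, cfg)
  f2 <- train_model(recs, embs, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
})

test_that("missing embeddings and empty inputs are informative errors", {
  embs <- fixture_embeddings()
  recs <- fixture_records(n_guides = 4)$records
  expect_error(train_model(recs[0, ], embs), "empty training set")
  expect_error(train_model(recs, list()), "empty variant embedding")
  expect_error(train_model(recs, embs["WT-SpCas9"]), "SpCas9-HF1")
})

test_that("a non-finite loss aborts with a diagnostic", {
  embs <- fixture_embeddings()
  recs <- fixture_records(n_guides = 5)$records
  poisoned <- new_model(seed = 6, embed_width = 32)
  poisoned$params[["head.fc2.W"]][1] <- NaN
  cfg <- training_config(epochs = 2, seed = 6)
  expect_error(train_model(recs, embs, cfg, model = poisoned),
               "non-finite loss")
})

test_that("grid search enumerates the space and returns the best candidate", {
  embs <- fixture_embeddings()
  sim <- fixture_records(n_guides = 10, seed = 31)
  recs <- sim$records
  val <- fixture_records(n_guides = 4, seed = 32)$records

  # singleton space returns its only element
  single <- grid_space(learning_rates = 1e-4, batch_sizes = 64L,
                       epoch_counts = 2L)
  gs <- grid_search(recs, embs, val, single, seed = 7)
  expect_equal(nrow(gs$leaderboard), 1L)
  expect_equal(gs$best_config$learning_rate, 1e-4)
  expect_equal(gs$best_config$epochs, 2L)

  # a planted scenario: an absurd lr diverges or trails, a sane one wins
  planted <- grid_space(learning_rates = c(1e-3, 1e7), batch_sizes = 64L,
                        epoch_counts = 3L)
  gs2 <- grid_search(recs, embs, val, planted, seed = 7)
  expect_equal(nrow(gs2$leaderboard), 2L)
  expect_equal(gs2$best_config$learning_rate, 1e-3)

  # the full reference space enumerates 4 x 4 x 3 combinations
  full <- grid_space()
  expect_equal(length(full$learning_rates) * length(full$batch_sizes) *
                 length(full$epoch_counts), 48L)
  expect_error(grid_search(recs, embs, NULL), "validation")
})
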