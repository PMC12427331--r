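tiny_train_setup <- function(seed = 31, n_founders = 30, offspring = 40,
                             n_blocks = 10, ...) {
  out <- tiny_sim(seed = seed, n_founders = n_founders,
                  offspring = offspring, n_blocks = n_blocks, ...)
  v <- build_vocabulary()
  imp <- impute_and_discretize(recode_to_minor(out$genotypes))
  tk <- tokenize_genotypes(imp$integer, v, max_len = NULL,
                           snps = out$genotypes$snps)
  y <- stats::setNames(out$phenotypes$value, out$phenotypes$id)
  split <- forward_split(out$pedigree)
  list(sim = out, vocab = v, tokens = tk, y = y, split = split)
}

test_that("the learning-rate schedule warms up linearly then decays to zero", {
  lr <- 1e-3
  expect_equal(lr_at_step(5, 100, lr, 10), lr * 5 / 10)
  expect_equal(lr_at_step(10, 100, lr, 10), lr)
  expect_equal(lr_at_step(55, 100, lr, 10), lr * 45 / 90)
  expect_equal(lr_at_step(100, 100, lr, 10), 0)
  # pointwise over the whole run
  s <- 1:100
  got <- vapply(s, lr_at_step, 1, total_steps = 100, lr = lr,
                warmup_steps = 10)
  want <- ifelse(s <= 10, lr * s / 10, lr * (100 - s) / 90)
  expect_equal(got, want)
  expect_error(lr_at_step(1, 5, lr, 10), "warmup")
  # cosine variant shares the warmup and the endpoint
  expect_equal(lr_at_step(10, 100, lr, 10, "cosine"), lr)
  expect_equal(lr_at_step(100, 100, lr, 10, "cosine"), 0, tolerance = 1e-12)
})

test_that("zero pre-training epochs return the initial weights", {
  st <- tiny_train_setup()
  m <- init_model(model_config("tiny", max_positions = 16), seed = 1)
  res <- pretrain(m, st$tokens, masking_spec(),
                  pretrain_config(total_epochs = 0), st$vocab)
  expect_identical(res$final_model$params, m$params)
  expect_identical(res$model$params, m$params)
  expect_equal(nrow(res$log), 0)
})

test_that("pre-training is deterministic and reduces the masked loss", {
  st <- tiny_train_setup()
  m <- init_model(model_config("tiny", max_positions = 16), seed = 2)
  cfg <- pretrain_config(total_epochs = 3, warmup_steps = 2, lr = 3e-4,
                         batch_size = 32, seed = 5)
  r1 <- pretrain(m, st$tokens, masking_spec(), cfg, st$vocab)
  r2 <- pretrain(m, st$tokens, masking_spec(), cfg, st$vocab)
  expect_identical(r1$log$train_loss, r2$log$train_loss)
  expect_identical(r1$log$val_loss, r2$log$val_loss)
  expect_identical(r1$model$params, r2$model$params)
  expect_lt(r1$log$train_loss[3], r1$log$train_loss[1])
  expect_equal(r1$best_epoch, which.min(r1$log$val_loss))
})

test_that("fine-tuning fits a near-constant phenotype and honours patience", {
  st <- tiny_train_setup(seed = 32)
  cfgm <- model_config("tiny", max_positions = 16)
  m <- init_model(cfgm, seed = 3)
  # near-constant labels: the standardised target is tiny noise around 0,
  # so predictions revert to the training mean almost immediately
  yc <- st$y * 0 + 5 + rnorm(length(st$y), sd = 1e-3)
  names(yc) <- names(st$y)
  fit <- finetune(m, st$tokens, yc, st$split,
                  finetune_config(total_epochs = 3, warmup_steps = 2,
                                  early_stopping_patience = 3,
                                  batch_size = 32))
  preds <- predict(fit, st$tokens, ids = st$split$test)
  expect_lt(max(abs(preds - 5)), 0.05)

  # lr = 0: validation R2 never improves after the first epoch, so a
  # patience of 2 stops the run at epoch 3
  f0 <- finetune(m, st$tokens, st$y, st$split,
                 finetune_config(lr = 0, total_epochs = 6, warmup_steps = 2,
                                 early_stopping_patience = 2,
                                 batch_size = 32))
  expect_equal(nrow(f0$log), 3)
  expect_true(f0$stopped_early)
  expect_equal(f0$best_epoch, 1)
  expect_equal(f0$best_epoch, which.max(f0$log$val_r2))
})

test_that("validation data steer selection but never the gradients", {
  st <- tiny_train_setup(seed = 33)
  m <- init_model(model_config("tiny", max_positions = 16), seed = 4)
  cfg <- finetune_config(total_epochs = 2, warmup_steps = 2,
                         early_stopping_patience = 2, batch_size = 32)
  splitA <- st$split
  splitB <- st$split
  # swap half the validation set for test individuals: training ids equal
  k <- floor(length(splitB$validation) / 2)
  splitB$validation <- c(splitB$validation[seq_len(k)],
                         splitB$test[seq_len(2)])
  fA <- finetune(m, st$tokens, st$y, splitA, cfg)
  fB <- finetune(m, st$tokens, st$y, splitB, cfg)
  expect_identical(fA$log$train_mse, fB$log$train_mse)
})

test_that("fine-tuning validates its inputs", {
  st <- tiny_train_setup(seed = 34)
  m <- init_model(model_config("tiny", max_positions = 16), seed = 5)
  bad <- st$split; bad$validation <- bad$validation[1]
  expect_error(finetune(m, st$tokens, st$y, bad,
                        finetune_config(total_epochs = 1,
                                        early_stopping_patience = 1)),
               "2 validation")
  overlap <- st$split; overlap$validation <- overlap$train[1:3]
  expect_error(finetune(m, st$tokens, st$y, overlap,
                        finetune_config(total_epochs = 1,
                                        early_stopping_patience = 1)),
               "overlap")
  expect_error(finetune_config(total_epochs = 5,
                               early_stopping_patience = 10), "patience")
})

test_that("grid search picks the best validated configuration", {
  st <- tiny_train_setup(seed = 35, h2_additive = 0.6)
  m <- init_model(model_config("tiny", max_positions = 16), seed = 6)
  base <- finetune_config(total_epochs = 2, warmup_steps = 1,
                          early_stopping_patience = 2, batch_size = 32)
  single <- grid_search(m, st$tokens, st$y, st$split,
                        grid = list(lr = 5e-4), base_config = base)
  expect_equal(single$best_config$lr, 5e-4)
  expect_equal(nrow(single$results), 1)
  # duplicated entries collapse to the deduplicated grid
  dup <- grid_search(m, st$tokens, st$y, st$split,
                     grid = list(lr = c(5e-4, 5e-4)), base_config = base)
  expect_equal(nrow(dup$results), 1)
  expect_equal(dup$best_config$lr, single$best_config$lr)
  expect_equal(dup$best_result$best_val_r2, single$best_result$best_val_r2)
  # a wildly diverging learning rate loses to a sane one
  two <- grid_search(m, st$tokens, st$y, st$split,
                     grid = list(lr = c(5e-4, 50)), base_config = base)
  expect_equal(two$best_config$lr, 5e-4)
  expect_error(grid_search(m, st$tokens, st$y, st$split, grid = list()),
               "empty")
})

test_that("checkpoints round-trip weights and verify the vocabulary hash", {
  st <- tiny_train_setup(seed = 36)
  m <- init_model(model_config("tiny", max_positions = 16), seed = 7)
  res <- pretrain(m, st$tokens, masking_spec(),
                  pretrain_config(total_epochs = 1, warmup_steps = 1,
                                  batch_size = 32), st$vocab)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(res$model, path)
  back <- load_model(path, vocab = st$vocab)
  expect_identical(back$params, res$model$params)
  wrong <- build_vocabulary(k = 5)
  expect_error(load_model(path, vocab = wrong), "different vocabulary")
})
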