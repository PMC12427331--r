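#' Pre-training configuration
#'
#' Masked 6-mer pre-training defaults: AdamW (decoupled weight decay),
#' peak learning rate 1e-4, 100 linear warmup steps then linear decay to
#' zero, 100 epochs, weight decay 0.01, seed 42.
#'
#' @param lr peak learning rate.
#' @param warmup_steps linear warmup length in optimiser steps.
#' @param total_epochs number of passes over the corpus (masking is
#'   resampled every epoch).
#' @param batch_size sequences per optimiser step.
#' @param weight_decay decoupled weight-decay coefficient (applied to
#'   weight matrices and embeddings, not biases or LayerNorm parameters).
#' @param schedule `"linear"` decay (default) or `"cosine"`.
#' @param val_frac fraction of sequences held out to track validation
#'   cross-entropy.
#' @param seed integer seed governing shuffling, masking and dropout.
#' @return A `pretrain_config` list.
#' @export
pretrain_config <- function(lr = 1e-4, warmup_steps = 100,
                            total_epochs = 100, batch_size = 64,
                            weight_decay = 0.01,
                            schedule = c("linear", "cosine"),
                            val_frac = 0.1, seed = 42) {
  structure(list(lr = lr, warmup_steps = as.integer(warmup_steps),
                 total_epochs = as.integer(total_epochs),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 schedule = match.arg(schedule),
                 val_frac = val_frac, seed = as.integer(seed)),
            class = "pretrain_config")
}

#' Fine-tuning configuration
#'
#' Supervised regression defaults: learning rate 5e-4, 10 warmup steps,
#' 50 epochs, mean-squared-error loss, early stopping after 10 epochs
#' without validation-R-squared improvement, seed 42.  (Note the stated
#' fine-tuning rate exceeds the pre-training rate even though transfer
#' learning typically uses a smaller one; both are plain arguments.)
#'
#' @inheritParams pretrain_config
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping.
#' @return A `finetune_config` list.
#' @export
finetune_config <- function(lr = 5e-4, warmup_steps = 10,
                            total_epochs = 50, batch_size = 64,
                            weight_decay = 0.01,
                            schedule = c("linear", "cosine"),
                            early_stopping_patience = 10, seed = 42) {
  patience <- as.integer(early_stopping_patience)
  if (patience > total_epochs) abort("patience must be <= total_epochs")
  structure(list(lr = lr, warmup_steps = as.integer(warmup_steps),
                 total_epochs = as.integer(total_epochs),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 schedule = match.arg(schedule),
                 early_stopping_patience = patience,
                 seed = as.integer(seed)),
            class = "finetune_config")
}

#' Learning rate at a given optimiser step
#'
#' Linear warmup from 0 to `lr` over `warmup_steps`, then linear (or
#' cosine) decay to 0 at `total_steps`.
#'
#' @param step 1-based optimiser step.
#' @param total_steps total number of steps in the run.
#' @param lr peak learning rate.
#' @param warmup_steps warmup length.
#' @param schedule `"linear"` or `"cosine"`.
#' @return The scalar learning rate.
#' @export
lr_at_step <- function(step, total_steps, lr, warmup_steps,
                       schedule = "linear") {
  if (warmup_steps >= total_steps) abort("warmup_steps must be < total steps")
  if (step <= warmup_steps) return(lr * step / warmup_steps)
  frac <- (total_steps - step) / (total_steps - warmup_steps)
  frac <- max(frac, 0)
  if (schedule == "cosine") {
    lr * 0.5 * (1 + cos(pi * (1 - frac)))
  } else {
    lr * frac
  }
}

# ---- AdamW ----------------------------------------------------------------

adamw_init <- function(params) {
  zeros <- lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
  decay <- vapply(names(params), function(n) {
    grepl("W", n) || n %in% c("tok_emb", "pos_emb", "cls_w2")
  }, TRUE)
  list(m = zeros, v = zeros, t = 0L, decay = decay)
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (state$decay[[nm]]) upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

mlm_eval_loss <- function(params, config, tokens, rows, masked_cache,
                          batch_size) {
  total <- 0; n <- 0
  for (start in seq(1, length(rows), by = batch_size)) {
    rr <- rows[start:min(start + batch_size - 1, length(rows))]
    sl <- batch_slices(masked_cache$input_ids, masked_cache$attention_mask,
                       rr, masked_cache$labels)
    storage.mode(sl$ids) <- "integer"
    storage.mode(sl$labels) <- "integer"
    out <- cpp_tf_mlm(params, sl$ids,
                      matrix(as.numeric(sl$mask), nrow(sl$mask)),
                      sl$labels, config, train = FALSE, seed = 1L,
                      want_grads = FALSE, single = use_single(config))
    total <- total + out$loss * out$n_labeled
    n <- n + out$n_labeled
  }
  total / n
}

#' Pre-train the Transformer with masked 6-mer prediction
#'
#' Self-supervised stage: every epoch a fresh random corruption of the
#' token corpus is generated ([apply_masking()]) and the model is trained
#' to recover the original tokens at the selected positions with a
#' cross-entropy loss, using AdamW and a warmup-then-decay schedule.  A
#' held-out fraction of sequences tracks validation cross-entropy (its
#' corruption is fixed across epochs so the curve is comparable); the
#' checkpoint with the lowest validation loss is retained alongside the
#' final one.  The run is deterministic given the configuration seed.
#'
#' @param model a `snpformer_model` from [init_model()].
#' @param tokens a `tokenized_batch` from [tokenize_genotypes()].
#' @param masking a [masking_spec()].
#' @param config a [pretrain_config()].
#' @param vocab the vocabulary used to tokenize.
#' @param val_rows row indices for the validation split; by default a
#'   random `val_frac` of sequences (seeded).
#' @param verbose print per-epoch losses.
#' @return A `pretrain_result`: `model` (best-validation checkpoint),
#'   `final_model`, `log` tibble (epoch, train_loss, val_loss, lr,
#'   seconds), `best_epoch`.
#' @export
pretrain <- function(model, tokens, masking = masking_spec(),
                     config = pretrain_config(),
                     vocab = build_vocabulary(), val_rows = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(model, "snpformer_model"),
            inherits(tokens, "tokenized_batch"))
  if (!is.null(tokens$vocab_hash) &&
      tokens$vocab_hash != vocab_hash(vocab)) {
    abort("token batch was built with a different vocabulary")
  }
  n <- nrow(tokens$input_ids)
  if (n < 2) abort("pre-training corpus is empty or trivial")
  if (is.null(val_rows)) {
    val_rows <- with_seed(derive_seed(config$seed, 10),
                          sort(sample.int(n, max(1, round(config$val_frac * n)))))
  }
  train_rows <- setdiff(seq_len(n), val_rows)
  params <- model$params
  cfg_list <- unclass(model$config)
  state <- adamw_init(params)
  n_batches <- ceiling(length(train_rows) / config$batch_size)
  total_steps <- max(config$total_epochs * n_batches, 1)
  # fixed validation corruption
  val_masked <- apply_masking(tokens, masking, vocab,
                              seed = derive_seed(config$seed, 11))
  log <- vector("list", config$total_epochs)
  best <- list(loss = Inf, params = params, epoch = 0L)
  if (config$total_epochs == 0) {
    val0 <- mlm_eval_loss(params, cfg_list, tokens, val_rows, val_masked,
                          config$batch_size)
    best <- list(loss = val0, params = params, epoch = 0L)
  }
  step <- 0L
  for (epoch in seq_len(config$total_epochs)) {
    t0 <- proc.time()[3]
    masked <- apply_masking(tokens, masking, vocab,
                            seed = derive_seed(config$seed, 12, epoch))
    ord <- with_seed(derive_seed(config$seed, 13, epoch),
                     sample(train_rows))
    ep_loss <- 0; ep_n <- 0
    for (b in seq_len(n_batches)) {
      rr <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size,
                                                      length(ord))]
      sl <- batch_slices(masked$input_ids, masked$attention_mask, rr,
                         masked$labels)
      storage.mode(sl$ids) <- "integer"
      storage.mode(sl$labels) <- "integer"
      step <- step + 1L
      out <- cpp_tf_mlm(params, sl$ids,
                        matrix(as.numeric(sl$mask), nrow(sl$mask)),
                        sl$labels, cfg_list, train = TRUE,
                        seed = derive_seed(config$seed, 14, step),
                        want_grads = TRUE, single = use_single(cfg_list))
      lr <- lr_at_step(step, total_steps, config$lr, config$warmup_steps,
                       config$schedule)
      res <- adamw_step(params, out$grads, state, lr, config$weight_decay)
      params <- res$params; state <- res$state
      ep_loss <- ep_loss + out$loss * out$n_labeled
      ep_n <- ep_n + out$n_labeled
    }
    val_loss <- mlm_eval_loss(params, cfg_list, tokens, val_rows,
                              val_masked, config$batch_size)
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
    }
    log[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = ep_loss / ep_n, val_loss = val_loss,
      lr = lr_at_step(step, total_steps, config$lr, config$warmup_steps,
                      config$schedule),
      seconds = proc.time()[3] - t0)
    if (verbose) {
      message(sprintf("epoch %d: train CE %.4f, val CE %.4f",
                      epoch, ep_loss / ep_n, val_loss))
    }
  }
  best_model <- model; best_model$params <- best$params
  best_model$vocab_hash <- tokens$vocab_hash
  final_model <- model; final_model$params <- params
  final_model$vocab_hash <- tokens$vocab_hash
  structure(list(model = best_model, final_model = final_model,
                 log = dplyr::bind_rows(log), best_epoch = best$epoch,
                 config = config),
            class = "pretrain_result")
}

#' Fine-tune the Transformer for phenotype regression
#'
#' Supervised stage: the encoder is initialised from a pre-trained
#' checkpoint (or trained from scratch when `model` comes straight from
#' [init_model()]), the `[CLS]` regression head minimises mean squared
#' error on the standardised training phenotypes, model selection and
#' early stopping use the validation coefficient of determination, and the
#' weights of the best validation epoch are returned.  Validation and test
#' data never contribute gradients.
#'
#' @param model a `snpformer_model` (pre-trained or freshly initialised).
#' @param tokens a `tokenized_batch` covering all individuals.
#' @param y named numeric vector of phenotypes (names matching the row
#'   names of `tokens$input_ids`).
#' @param split list with `train` and `validation` character vectors of
#'   ids (e.g. from [forward_split()]).
#' @param config a [finetune_config()].
#' @param verbose print per-epoch metrics.
#' @return A `finetune_result`: `model` (best-epoch weights, carrying the
#'   phenotype standardisation so [predict()] returns the original
#'   scale), `log` tibble (epoch, train_mse, val_r2, lr, seconds),
#'   `best_epoch`, `stopped_early`.
#' @export
finetune <- function(model, tokens, y, split,
                     config = finetune_config(), verbose = FALSE) {
  stopifnot(inherits(model, "snpformer_model"),
            inherits(tokens, "tokenized_batch"))
  ids_all <- rownames(tokens$input_ids)
  if (is.null(ids_all)) abort("tokens must carry sample ids as row names")
  train_rows <- match(split$train, ids_all)
  val_rows <- match(split$validation, ids_all)
  if (anyNA(train_rows) || anyNA(val_rows)) {
    abort("split ids missing from token batch")
  }
  if (length(intersect(train_rows, val_rows))) {
    abort("train and validation overlap")
  }
  if (length(val_rows) < 2) abort("need at least 2 validation individuals")
  y_train <- y[split$train]; y_val <- y[split$validation]
  if (anyNA(y_train) || anyNA(y_val)) abort("missing phenotypes in split")
  y_center <- mean(y_train); y_scale <- sd(y_train)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  ys <- (y_train - y_center) / y_scale

  params <- model$params
  cfg_list <- unclass(model$config)
  state <- adamw_init(params)
  n_batches <- ceiling(length(train_rows) / config$batch_size)
  total_steps <- max(config$total_epochs * n_batches, 1)
  best <- list(r2 = -Inf, params = params, epoch = 0L)
  log <- list()
  step <- 0L
  stalled <- 0L
  stopped_early <- FALSE
  eval_model <- model
  for (epoch in seq_len(config$total_epochs)) {
    t0 <- proc.time()[3]
    ord <- with_seed(derive_seed(config$seed, 20, epoch),
                     sample(seq_along(train_rows)))
    ep_loss <- 0; ep_n <- 0
    for (b in seq_len(n_batches)) {
      sel <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size,
                                                       length(ord))]
      rr <- train_rows[sel]
      sl <- batch_slices(tokens$input_ids, tokens$attention_mask, rr)
      storage.mode(sl$ids) <- "integer"
      step <- step + 1L
      out <- cpp_tf_reg(params, sl$ids,
                        matrix(as.numeric(sl$mask), nrow(sl$mask)),
                        ys[sel], cfg_list, train = TRUE,
                        seed = derive_seed(config$seed, 21, step),
                        want_grads = TRUE, single = use_single(cfg_list))
      lr <- lr_at_step(step, total_steps, config$lr, config$warmup_steps,
                       config$schedule)
      res <- adamw_step(params, out$grads, state, lr, config$weight_decay)
      params <- res$params; state <- res$state
      ep_loss <- ep_loss + out$loss * length(sel)
      ep_n <- ep_n + length(sel)
    }
    eval_model$params <- params
    pv <- regress_from_cls(eval_model,
                           tokens$input_ids[val_rows, , drop = FALSE],
                           tokens$attention_mask[val_rows, , drop = FALSE],
                           batch_size = config$batch_size)
    val_r2 <- tryCatch(
      compute_metrics(y_val, pv * y_scale + y_center)$r2,
      error = function(e) -Inf)
    if (!is.finite(val_r2)) val_r2 <- -Inf
    log[[epoch]] <- tibble::tibble(
      epoch = epoch, train_mse = ep_loss / ep_n, val_r2 = val_r2,
      lr = lr_at_step(step, total_steps, config$lr, config$warmup_steps,
                      config$schedule),
      seconds = proc.time()[3] - t0)
    if (verbose) {
      message(sprintf("epoch %d: train MSE %.4f, val R2 %.4f",
                      epoch, ep_loss / ep_n, val_r2))
    }
    if (val_r2 > best$r2) {
      best <- list(r2 = val_r2, params = params, epoch = epoch)
      stalled <- 0L
    } else {
      stalled <- stalled + 1L
      if (stalled >= config$early_stopping_patience) {
        stopped_early <- TRUE
        break
      }
    }
  }
  fit <- model
  fit$params <- best$params
  fit$y_center <- y_center
  fit$y_scale <- y_scale
  structure(list(model = fit, log = dplyr::bind_rows(log),
                 best_epoch = best$epoch, best_val_r2 = best$r2,
                 stopped_early = stopped_early, config = config),
            class = "finetune_result")
}

#' Predict phenotypes with a fine-tuned model
#'
#' @param object a `finetune_result`.
#' @param tokens a `tokenized_batch`.
#' @param ids optional character vector restricting prediction to these
#'   individuals.
#' @param ... unused.
#' @return Named numeric vector of predictions on the phenotype scale.
#' @export
predict.finetune_result <- function(object, tokens, ids = NULL, ...) {
  rows <- if (is.null(ids)) seq_len(nrow(tokens$input_ids)) else {
    match(ids, rownames(tokens$input_ids))
  }
  if (anyNA(rows)) abort("prediction ids missing from token batch")
  regress_from_cls(object$model,
                   tokens$input_ids[rows, , drop = FALSE],
                   tokens$attention_mask[rows, , drop = FALSE])
}

#' Exhaustive grid search over fine-tuning hyperparameters
#'
#' Evaluates every combination in `grid` with [finetune()] on the
#' train/validation split and selects the configuration with the highest
#' validation coefficient of determination.  The test set is never
#' touched: the function only receives training and validation ids.
#' Non-finite validation scores (diverged runs) rank below every finite
#' one.
#'
#' @param model starting `snpformer_model` (shared across combinations).
#' @inheritParams finetune
#' @param grid named list of parameter vectors; names must be
#'   [finetune_config()] arguments (e.g. `list(lr = c(1e-4, 5e-4))`).
#' @param base_config the [finetune_config()] whose fields the grid
#'   overrides.
#' @return A list with `best_config` (a [finetune_config()]),
#'   `best_result` (its `finetune_result`) and `results` (tibble of
#'   combinations and validation scores).
#' @export
grid_search <- function(model, tokens, y, split, grid,
                        base_config = finetune_config()) {
  if (!length(grid)) abort("empty hyperparameter grid")
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  combos <- unique(combos)
  results <- vector("list", nrow(combos))
  fits <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- base_config
    for (nm in names(combos)) cfg[[nm]] <- combos[[nm]][i]
    fit <- finetune(model, tokens, y, split, config = cfg)
    fits[[i]] <- fit
    results[[i]] <- tibble::tibble(combos[i, , drop = FALSE],
                                   val_r2 = fit$best_val_r2)
  }
  results <- dplyr::bind_rows(results)
  scores <- ifelse(is.finite(results$val_r2), results$val_r2, -Inf)
  best_i <- which.max(scores)
  cfg <- base_config
  for (nm in names(combos)) cfg[[nm]] <- combos[[nm]][best_i]
  list(best_config = cfg, best_result = fits[[best_i]], results = results)
}

#' @export
tidy.pretrain_result <- function(x, ...) x$log

#' @export
tidy.finetune_result <- function(x, ...) x$log

#' @export
glance.pretrain_result <- function(x, ...) {
  tibble::tibble(best_epoch = x$best_epoch,
                 best_val_loss = min(x$log$val_loss),
                 final_val_loss = x$log$val_loss[nrow(x$log)],
                 epochs_run = nrow(x$log))
}

#' @export
glance.finetune_result <- function(x, ...) {
  tibble::tibble(best_epoch = x$best_epoch, best_val_r2 = x$best_val_r2,
                 stopped_early = x$stopped_early, epochs_run = nrow(x$log))
}
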