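#' Transformer model configuration
#'
#' The default matches the full-scale architecture (12 layers, hidden size
#' 768, 12 attention heads, feed-forward size 3072, dropout 0.1, up to
#' 10,240 genomic tokens plus `[CLS]`); the `"tiny"` preset (2 layers,
#' hidden 64, 4 heads, feed-forward 128) is sized for CPU-scale experiments
#' and tests.
#'
#' @param preset `"full"` (the full-scale configuration) or `"tiny"`.
#' @param precision floating-point precision of the compiled forward and
#'   backward passes: `"single"` (default, faster) or `"double"` (used for
#'   finite-difference gradient verification).
#' @param n_layers,d_model,n_heads,ffn_size,dropout,max_positions,vocab_size
#'   individual overrides; `d_model` must be divisible by `n_heads`.
#' @return A `model_config` list.
#' @export
model_config <- function(preset = c("full", "tiny"), n_layers = NULL,
                         d_model = NULL, n_heads = NULL, ffn_size = NULL,
                         dropout = NULL, max_positions = NULL,
                         vocab_size = 732L,
                         precision = c("single", "double")) {
  preset <- match.arg(preset)
  precision <- match.arg(precision)
  base <- if (preset == "full") {
    list(n_layers = 12L, d_model = 768L, n_heads = 12L, ffn_size = 3072L,
         dropout = 0.1, max_positions = 10241L)
  } else {
    list(n_layers = 2L, d_model = 64L, n_heads = 4L, ffn_size = 128L,
         dropout = 0.1, max_positions = 512L)
  }
  cfg <- modifyList(base, Filter(Negate(is.null), list(
    n_layers = n_layers, d_model = d_model, n_heads = n_heads,
    ffn_size = ffn_size, dropout = dropout, max_positions = max_positions)))
  cfg$vocab_size <- as.integer(vocab_size)
  cfg$precision <- precision
  check_scalar(cfg$dropout, "dropout", 0, 1, closed_upper = FALSE)
  if (cfg$d_model %% cfg$n_heads != 0) {
    abort("d_model must be divisible by n_heads")
  }
  cfg[c("n_layers", "d_model", "n_heads", "ffn_size", "max_positions",
        "vocab_size")] <-
    lapply(cfg[c("n_layers", "d_model", "n_heads", "ffn_size",
                 "max_positions", "vocab_size")], as.integer)
  structure(cfg, class = "model_config")
}

# Truncated-normal init (+/- 2 sd), the masked-LM lineage convention.
trunc_normal <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  qnorm(runif(n, lo, hi)) * sd
}

#' Initialise Transformer weights
#'
#' Embeddings and linear maps are truncated-normal (sd 0.02); LayerNorm
#' gains are 1 and all biases 0.  Deterministic given `seed`.
#'
#' @param config a [model_config()].
#' @param seed integer seed.
#' @return A `snpformer_model`: list with `params` (named list of matrices
#'   and vectors), `config`, and `vocab_hash` (set when trained).
#' @export
init_model <- function(config = model_config("tiny"), seed = 42) {
  stopifnot(inherits(config, "model_config"))
  d <- config$d_model; f <- config$ffn_size; V <- config$vocab_size
  with_seed(derive_seed(seed, 4), {
    tn <- function(r, c) matrix(trunc_normal(r * c), r, c)
    p <- list(
      tok_emb = tn(V, d),
      pos_emb = tn(config$max_positions, d),
      emb_ln_g = rep(1, d), emb_ln_b = rep(0, d)
    )
    for (l in seq_len(config$n_layers)) {
      nm <- function(s) sprintf("l%d_%s", l, s)
      p[[nm("Wq")]] <- tn(d, d); p[[nm("bq")]] <- rep(0, d)
      p[[nm("Wk")]] <- tn(d, d); p[[nm("bk")]] <- rep(0, d)
      p[[nm("Wv")]] <- tn(d, d); p[[nm("bv")]] <- rep(0, d)
      p[[nm("Wo")]] <- tn(d, d); p[[nm("bo")]] <- rep(0, d)
      p[[nm("ln1_g")]] <- rep(1, d); p[[nm("ln1_b")]] <- rep(0, d)
      p[[nm("W1")]] <- tn(d, f); p[[nm("b1")]] <- rep(0, f)
      p[[nm("W2")]] <- tn(f, d); p[[nm("b2")]] <- rep(0, d)
      p[[nm("ln2_g")]] <- rep(1, d); p[[nm("ln2_b")]] <- rep(0, d)
    }
    p$mlm_W <- tn(d, V); p$mlm_b <- rep(0, V)
    p$cls_W1 <- tn(d, d); p$cls_b1 <- rep(0, d)
    p$cls_w2 <- trunc_normal(d)
    p$cls_ln_g <- rep(1, d); p$cls_ln_b <- rep(0, d)
    p$cls_b2 <- 0
    structure(list(params = p, config = config, vocab_hash = NULL),
              class = "snpformer_model")
  })
}

#' @export
print.snpformer_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<snpformer_model> L=%d d_model=%d H=%d ffn=%d (%s parameters)\n",
    cfg$n_layers, cfg$d_model, cfg$n_heads, cfg$ffn_size,
    format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count model parameters
#'
#' @param model a `snpformer_model`.
#' @return Total number of scalar parameters.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 1L))
}

use_single <- function(config) !identical(config$precision, "double")

# Subset the batch matrices the C++ core consumes, trimming padding columns
# to the longest realised sequence to avoid wasted compute.
batch_slices <- function(input_ids, attention_mask, rows = NULL,
                         labels = NULL) {
  if (!is.null(rows)) {
    input_ids <- input_ids[rows, , drop = FALSE]
    attention_mask <- attention_mask[rows, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[rows, , drop = FALSE]
  }
  used <- max(which(colSums(attention_mask) > 0))
  list(ids = input_ids[, seq_len(used), drop = FALSE],
       mask = attention_mask[, seq_len(used), drop = FALSE],
       labels = if (!is.null(labels)) labels[, seq_len(used), drop = FALSE])
}

#' Run the encoder forward
#'
#' Evaluation-mode forward pass (dropout off), optionally retaining the
#' per-layer attention tensors.
#'
#' @param model a `snpformer_model`.
#' @param input_ids integer matrix of 0-based token ids (individuals x
#'   positions), `[CLS]` first.
#' @param attention_mask binary matrix of the same shape.
#' @param retain_attention keep attention probabilities (arrays of
#'   dimension positions x positions x heads x individuals, one per
#'   layer).
#' @return A list with `hidden` (a `B x T x d_model` array) and, when
#'   requested, `attention`.
#' @export
forward_encoder <- function(model, input_ids, attention_mask,
                            retain_attention = FALSE) {
  stopifnot(inherits(model, "snpformer_model"))
  storage.mode(input_ids) <- "integer"
  out <- cpp_tf_encode(model$params, input_ids,
                       matrix(as.numeric(attention_mask),
                              nrow(attention_mask)),
                       unclass(model$config), retain_attention,
                       single = use_single(model$config))
  B <- out$B; T <- out$T
  hidden <- aperm(array(t(out$hidden), c(model$config$d_model, T, B)),
                  c(3, 2, 1))
  res <- list(hidden = hidden)
  if (retain_attention) res$attention <- out$attention
  res
}

#' Masked-token cross-entropy
#'
#' Mean cross-entropy of the vocabulary logits at labeled positions
#' (labels equal to [IGNORE_LABEL] are skipped); evaluation mode.
#'
#' @param model a `snpformer_model`.
#' @param masked a `masked_batch` from [apply_masking()].
#' @return A list with `loss` and `n_labeled`.
#' @export
mlm_loss <- function(model, masked) {
  sl <- batch_slices(masked$input_ids, masked$attention_mask,
                     labels = masked$labels)
  storage.mode(sl$ids) <- "integer"
  storage.mode(sl$labels) <- "integer"
  out <- cpp_tf_mlm(model$params, sl$ids,
                    matrix(as.numeric(sl$mask), nrow(sl$mask)),
                    sl$labels, unclass(model$config),
                    train = FALSE, seed = 1L, want_grads = FALSE,
                    single = use_single(model$config))
  list(loss = out$loss, n_labeled = out$n_labeled)
}

#' Predict phenotypes from the `[CLS]` representation
#'
#' Evaluation-mode regression head: `linear(d -> d) + tanh + linear(d ->
#' 1)` applied to the final `[CLS]` hidden state.  Predictions are on the
#' model's internal (standardised) scale unless the model carries
#' fine-tuning scale information (see [finetune()]).
#'
#' @param model a `snpformer_model`.
#' @inheritParams forward_encoder
#' @param batch_size individuals per forward pass.
#' @return Numeric vector of predictions.
#' @export
regress_from_cls <- function(model, input_ids, attention_mask,
                             batch_size = 64) {
  stopifnot(inherits(model, "snpformer_model"))
  n <- nrow(input_ids)
  preds <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    rows <- start:min(start + batch_size - 1, n)
    sl <- batch_slices(input_ids, attention_mask, rows)
    storage.mode(sl$ids) <- "integer"
    out <- cpp_tf_reg(model$params, sl$ids,
                      matrix(as.numeric(sl$mask), nrow(sl$mask)),
                      numeric(0), unclass(model$config),
                      train = FALSE, seed = 1L, want_grads = FALSE,
                      single = use_single(model$config))
    preds[rows] <- out$preds
  }
  if (!is.null(model$y_center)) {
    preds <- preds * model$y_scale + model$y_center
  }
  names(preds) <- rownames(input_ids)
  preds
}

#' Save and load model checkpoints
#'
#' A checkpoint stores the configuration, all weights and the hash of the
#' vocabulary the model was trained with; loading verifies vocabulary
#' compatibility so a model is never silently applied to tokens from a
#' different alphabet.
#'
#' @param model a `snpformer_model`.
#' @param path checkpoint file path (RDS).
#' @return `save_model()` the path, invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "snpformer_model"))
  saveRDS(list(params = model$params, config = model$config,
               vocab_hash = model$vocab_hash,
               y_center = model$y_center, y_scale = model$y_scale,
               package_version = "0.1.0"), path)
  invisible(path)
}

#' @rdname save_model
#' @param vocab if supplied, the checkpoint's vocabulary hash must match
#'   this vocabulary.
#' @export
load_model <- function(path, vocab = NULL) {
  ck <- readRDS(path)
  if (!is.null(vocab) && !is.null(ck$vocab_hash) &&
      ck$vocab_hash != vocab_hash(vocab)) {
    abort("checkpoint was trained with a different vocabulary")
  }
  structure(list(params = ck$params, config = ck$config,
                 vocab_hash = ck$vocab_hash,
                 y_center = ck$y_center, y_scale = ck$y_scale),
            class = "snpformer_model")
}
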