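#' End-to-end model comparison on simulated data
#'
#' Runs the full comparison protocol on a synthetic population, once per
#' seed: simulate -> QC -> impute -> tokenize -> forward split ->
#' \{GBLUP, Lasso, Transformer from scratch, pre-trained Transformer\} ->
#' test-set metrics.  Pre-training uses all genotypes without labels;
#' fine-tuning and baselines see only the training and validation splits.
#'
#' @param sim a [sim_config()] describing the population and trait (its
#'   `seed` field is replaced by each element of `seeds`).
#' @param seeds integer vector of replicate seeds.
#' @param models character subset of
#'   `c("gblup", "lasso", "transformer_scratch", "transformer_pretrained")`.
#' @param model_config Transformer architecture, default the tiny preset.
#' @param pretrain_cfg,finetune_cfg training configurations; defaults are
#'   scaled for desk-size runs.
#' @param vocab token vocabulary.
#' @param phenotyped_generations generation indices carrying phenotypes
#'   (`NULL` = every individual).  Restricting labels to the younger
#'   generations reproduces the realistic setting where unlabelled
#'   genotypes outnumber phenotype records: pre-training always uses all
#'   genotypes, while fine-tuning and the baselines see only the
#'   phenotyped subset.
#' @param verbose print progress.
#' @return A `benchmark_result`: tibble `results` (model, seed, r2,
#'   r2_pearson, mse) and tibble `summary` (mean and sd of R2 per model).
#' @export
run_benchmark <- function(sim = sim_config(),
                          seeds = 1:3,
                          models = c("gblup", "lasso",
                                     "transformer_scratch",
                                     "transformer_pretrained"),
                          model_config = snpformer::model_config("tiny"),
                          pretrain_cfg = pretrain_config(
                            total_epochs = 12, warmup_steps = 20,
                            lr = 3e-4, batch_size = 64),
                          finetune_cfg = finetune_config(
                            total_epochs = 20, warmup_steps = 10,
                            lr = 1e-3, batch_size = 64,
                            early_stopping_patience = 20),
                          vocab = build_vocabulary(),
                          phenotyped_generations = NULL,
                          verbose = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  rows <- list()
  for (seed in seeds) {
    cfg <- sim; cfg$seed <- as.integer(seed)
    if (verbose) message(sprintf("seed %d: simulating...", seed))
    out <- simulate_population(cfg)
    qc <- apply_qc(recode_to_minor(out$genotypes))
    imp <- impute_and_discretize(qc$table)
    ph_ids <- rownames(qc$table$dosages)
    if (!is.null(phenotyped_generations)) {
      keep <- out$pedigree$id[out$pedigree$generation %in%
                                phenotyped_generations]
      ph_ids <- intersect(ph_ids, keep)
    }
    split <- forward_split(out$pedigree, ids = ph_ids)
    y <- stats::setNames(out$phenotypes$value, out$phenotypes$id)
    y <- y[rownames(qc$table$dosages)]
    test_ids <- split$test

    add_row <- function(model_name, preds) {
      m <- compute_metrics(y[test_ids], preds[test_ids])
      rows[[length(rows) + 1]] <<- dplyr::mutate(m, model = model_name,
                                                 seed = seed,
                                                 .before = 1)
    }

    if ("gblup" %in% models) {
      G <- compute_grm(imp$mean)
      gb <- fit_gblup(G, y[split$train], method = "reml")
      add_row("gblup", predict(gb, G, ids = test_ids))
    }
    if ("lasso" %in% models) {
      la <- fit_lasso(imp$mean[split$train, , drop = FALSE], y[split$train],
                      imp$mean[split$validation, , drop = FALSE],
                      y[split$validation])
      add_row("lasso", predict(la, imp$mean[test_ids, , drop = FALSE]))
    }
    if (any(grepl("transformer", models))) {
      tokens <- tokenize_genotypes(imp$integer, vocab, max_len = NULL,
                                   snps = qc$table$snps)
      fcfg <- finetune_cfg; fcfg$seed <- derive_seed(seed, 31)
      if ("transformer_scratch" %in% models) {
        if (verbose) message("  transformer (scratch)...")
        m0 <- init_model(model_config, seed = derive_seed(seed, 32))
        fs <- finetune(m0, tokens, y, split, config = fcfg)
        add_row("transformer_scratch", predict(fs, tokens, ids = test_ids))
      }
      if ("transformer_pretrained" %in% models) {
        if (verbose) message("  transformer (pre-trained)...")
        m0 <- init_model(model_config, seed = derive_seed(seed, 32))
        pcfg <- pretrain_cfg; pcfg$seed <- derive_seed(seed, 33)
        pt <- pretrain(m0, tokens, masking_spec(), pcfg, vocab)
        fp <- finetune(pt$model, tokens, y, split, config = fcfg)
        add_row("transformer_pretrained", predict(fp, tokens,
                                                  ids = test_ids))
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$model),
    mean_r2 = mean(.data$r2), sd_r2 = sd(.data$r2),
    mean_mse = mean(.data$mse), n_seeds = dplyr::n(), .groups = "drop")
  structure(list(results = results, summary = summary,
                 sim = sim, seeds = seeds),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d model(s) x %d seed(s)\n",
              nrow(x$summary), length(x$seeds)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.benchmark_result <- function(x, ...) x$results

#' @export
glance.benchmark_result <- function(x, ...) x$summary
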