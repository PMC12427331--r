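# ggplot2 displays for the result objects.

#' @export
autoplot.pretrain_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "cross_entropy")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$cross_entropy,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(title = "Masked 6-mer pre-training",
                  y = "cross-entropy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.finetune_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_mse", "val_r2"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2,
                        colour = "grey50") +
    ggplot2::labs(title = "Fine-tuning dynamics") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.attention_summary <- function(object, ...) {
  ggplot2::ggplot(object$regions,
                  ggplot2::aes(.data$token_index, .data$score)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(title = "[CLS] attention over genomic tokens",
                  x = "token index", y = "attention score") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.benchmark_result <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(.data$model, .data$r2)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(title = "Test-set accuracy by model",
                  y = expression(R^2), x = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.qc_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$snp_stats,
                            c("call_rate", "maf", "hwe_p"),
                            names_to = "stat", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~stat, scales = "free") +
    ggplot2::labs(title = "Per-SNP QC statistics") +
    ggplot2::theme_minimal()
}

#' Token-by-token attention heatmap for one individual
#'
#' @param model a `snpformer_model`.
#' @param tokens a `tokenized_batch`.
#' @param individual row index or sample id.
#' @param layer layer index (default last).
#' @param head head index or `"mean"`.
#' @return A ggplot object.
#' @export
plot_attention_map <- function(model, tokens, individual = 1,
                               layer = NULL, head = "mean") {
  if (is.character(individual)) {
    individual <- match(individual, rownames(tokens$input_ids))
  }
  sl <- batch_slices(tokens$input_ids, tokens$attention_mask, individual)
  enc <- forward_encoder(model, sl$ids, sl$mask, retain_attention = TRUE)
  layer <- layer %||% model$config$n_layers
  A <- enc$attention[[layer]]
  M <- if (identical(head, "mean")) {
    apply(A[,, , 1, drop = FALSE], c(1, 2), mean)
  } else {
    A[, , head, 1]
  }
  df <- expand.grid(query = seq_len(nrow(M)), key = seq_len(ncol(M)))
  df$weight <- as.vector(M)
  ggplot2::ggplot(df, ggplot2::aes(.data$key, .data$query,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("Attention map (layer %d)", layer),
                  x = "key token", y = "query token") +
    ggplot2::theme_minimal()
}
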