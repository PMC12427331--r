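#' Attention-based importance scores for token regions
#'
#' Aggregates the encoder's self-attention into one nonnegative score per
#' genomic token: by default the attention from the `[CLS]` query to each
#' genomic token, averaged over the heads of the last layer and over the
#' supplied individuals (layer choice and a cohort average reduce
#' per-individual noise).  Because attention rows are softmax-normalised,
#' scores lie in the unit interval and sum to at most 1 over genomic tokens (the
#' remainder sits on `[CLS]` itself).  Token `i` maps back to the window
#' of `k` consecutive SNPs recorded in the tokenizer's `window_map`, so
#' importance is resolved at the token-region level, not individual SNPs.
#'
#' @param model a `snpformer_model` (typically fine-tuned).
#' @param tokens a `tokenized_batch` for the cohort to average over
#'   (e.g. the test set).
#' @param layers integer vector of layer indices to average; default the
#'   last layer.
#' @param head_reduction currently `"mean"` over heads.
#' @param batch_size individuals per forward pass.
#' @return An `attention_summary`: tibble `regions` with `token_index`,
#'   `chrom`, `start`, `end`, `score`, `rank`, plus the aggregation
#'   settings.
#' @export
attention_region_scores <- function(model, tokens, layers = NULL,
                                    head_reduction = "mean",
                                    batch_size = 32) {
  stopifnot(inherits(model, "snpformer_model"),
            inherits(tokens, "tokenized_batch"))
  if (head_reduction != "mean") abort("only head_reduction = 'mean' is implemented")
  L <- model$config$n_layers
  layers <- layers %||% L
  if (any(layers < 1 | layers > L)) abort("layer index out of range")
  n <- nrow(tokens$input_ids)
  ng <- tokens$n_genomic
  if (is.null(ng) || ng < 1) abort("token batch has no genomic tokens")
  acc <- numeric(ng)
  for (start in seq(1, n, by = batch_size)) {
    rows <- start:min(start + batch_size - 1, n)
    sl <- batch_slices(tokens$input_ids, tokens$attention_mask, rows)
    enc <- forward_encoder(model, sl$ids, sl$mask, retain_attention = TRUE)
    for (l in layers) {
      A <- enc$attention[[l]]          # T x T x H x B
      # CLS query row -> genomic key columns, averaged over heads
      cls_rows <- A[1, 1 + seq_len(ng), , , drop = FALSE]
      acc <- acc + apply(cls_rows, 2, sum) / (dim(A)[3] * length(layers))
    }
  }
  scores <- acc / n
  wm <- tokens$window_map
  regions <- tibble::tibble(
    token_index = seq_len(ng),
    chrom = if (!is.null(wm)) wm$chrom else NA_character_,
    start = if (!is.null(wm)) wm$start else NA_integer_,
    end = if (!is.null(wm)) wm$end else NA_integer_,
    score = scores
  )
  regions$rank <- rank(-regions$score, ties.method = "first")
  structure(list(regions = regions, layers = layers,
                 head_reduction = head_reduction, n_individuals = n),
            class = "attention_summary")
}

#' @export
print.attention_summary <- function(x, ...) {
  cat(sprintf(
    "<attention_summary> %d tokens, layers {%s}, averaged over %d individuals\n",
    nrow(x$regions), paste(x$layers, collapse = ","), x$n_individuals))
  print(head(dplyr::arrange(x$regions, .data$rank), 5))
  invisible(x)
}

#' @export
tidy.attention_summary <- function(x, ...) x$regions

#' Top-scoring attention regions, merged when adjacent
#'
#' Selects tokens with score at or above the `(1 - q)` quantile and merges
#' runs of adjacent selected tokens into contiguous genomic regions.
#'
#' @param summary an `attention_summary`.
#' @param q fraction of tokens to keep (q = 1 keeps all).
#' @return A tibble of regions: `chrom`, `start`, `end`, `n_tokens`,
#'   `score` (mean over merged tokens), `token_start`, `token_end`.
#' @export
top_regions <- function(summary, q = 0.05) {
  stopifnot(inherits(summary, "attention_summary"))
  check_scalar(q, "q", 0, 1, closed_lower = FALSE)
  r <- summary$regions
  thr <- quantile(r$score, 1 - q, type = 7)
  sel <- r[r$score >= thr, ]
  if (!nrow(sel)) return(sel[0, ])
  sel <- sel[order(sel$token_index), ]
  grp <- cumsum(c(1, diff(sel$token_index) != 1 |
                    (if (!is.null(sel$chrom)) head(sel$chrom, -1) != tail(sel$chrom, -1) else FALSE)))
  dplyr::summarise(
    dplyr::group_by(sel, grp = grp),
    chrom = dplyr::first(.data$chrom),
    start = min(.data$start), end = max(.data$end),
    n_tokens = dplyr::n(), score = mean(.data$score),
    token_start = min(.data$token_index),
    token_end = max(.data$token_index), .groups = "drop"
  )[, -1]
}

#' Export attention regions as BED
#'
#' Converts internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param regions a tibble from [top_regions()] (or
#'   `attention_summary$regions`).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = sprintf("region%03d", seq_len(nrow(regions))),
                    score = signif(regions$score, 6))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
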