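#' Build the genotype 6-mer vocabulary
#'
#' Three reserved special tokens (`[CLS]` = 0, `[PAD]` = 1, `[MASK]` = 2)
#' followed by all `3^k` genotype k-mers over the alphabet \{0, 1, 2\} in
#' lexicographic order — 732 tokens for the default k = 6.  Token ids are
#' contiguous 0-based integers.
#'
#' @param k k-mer width (number of consecutive SNP dosages per token).
#' @return A `vocabulary` list with `tokens` (character vector indexed by
#'   id + 1), `k`, `n_special`, `size`, and `genomic_ids` (the non-special
#'   ids).
#' @export
build_vocabulary <- function(k = 6) {
  check_scalar(k, "k", 1, 12, integerish = TRUE)
  specials <- c("[CLS]", "[PAD]", "[MASK]")
  grid <- expand.grid(rep(list(0:2), k))[, k:1, drop = FALSE]  # lexicographic
  kmers <- apply(grid, 1, paste, collapse = "")
  tokens <- c(specials, kmers)
  structure(list(
    tokens = tokens,
    k = as.integer(k),
    n_special = 3L,
    size = length(tokens),
    genomic_ids = seq(3L, length(tokens) - 1L),
    cls_id = 0L, pad_id = 1L, mask_id = 2L
  ), class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d tokens (%d genomic %d-mers + %d specials)\n",
              x$size, length(x$genomic_ids), x$k, x$n_special))
  invisible(x)
}

#' Look up token ids and strings
#'
#' @param vocab a [build_vocabulary()] object.
#' @param token character token string(s).
#' @param id integer token id(s), 0-based.
#' @return `token_id()` integer ids; `id_token()` token strings.
#' @export
token_id <- function(vocab, token) {
  i <- match(token, vocab$tokens)
  if (anyNA(i)) abort(sprintf("unknown token '%s'", token[is.na(i)][1]))
  i - 1L
}

#' @rdname token_id
#' @export
id_token <- function(vocab, id) {
  if (any(id < 0 | id >= vocab$size)) abort("token id out of range")
  vocab$tokens[id + 1L]
}

# Vectorised k-mer encoding of a dosage matrix: rows are individuals,
# genotypes in {0,1,2}; returns an integer matrix of 0-based token ids.
encode_kmers <- function(mat, vocab) {
  k <- vocab$k
  n_tok <- floor(ncol(mat) / k)
  if (n_tok == 0) {
    return(matrix(integer(0), nrow(mat), 0))
  }
  if (any(!(mat[, seq_len(n_tok * k)] %in% 0:2))) {
    abort("genotype values outside {0,1,2}; impute/discretize first")
  }
  ids <- matrix(0L, nrow(mat), n_tok)
  for (j in seq_len(k)) {
    ids <- ids + mat[, seq(j, by = k, length.out = n_tok), drop = FALSE] *
      3L^(k - j)
  }
  ids + vocab$n_special
}

#' Tokenize one individual's genotype sequence
#'
#' Consecutive non-overlapping windows of `k` genotypes become vocabulary
#' tokens; a trailing remainder shorter than `k` is dropped; at most
#' `max_len` genomic tokens are kept (truncated from the tail).  A `[CLS]`
#' token is prepended (not counted against `max_len`) and the sequence is
#' padded with `[PAD]` to fixed length `1 + max_len` with a matching binary
#' attention mask.
#'
#' @param genotypes integer vector with values in \{0, 1, 2\}.
#' @param vocab a [build_vocabulary()].
#' @param max_len maximum number of genomic tokens (default 10240).
#' @param snps optional marker-map tibble (`snp_id`, `chrom`, `pos`) used
#'   to build the token-to-window coordinate map.
#' @param sample_id sample identifier.
#' @return A `tokenized_individual` list: `token_ids` (0-based, length
#'   `1 + max_len`), `attention_mask`, `n_genomic`, `window_map` (tibble of
#'   token index, chrom, start, end), `sample_id`.
#' @export
tokenize <- function(genotypes, vocab = build_vocabulary(),
                     max_len = 10240L, snps = NULL, sample_id = "ind1") {
  genotypes <- as.integer(genotypes)
  b <- tokenize_genotypes(matrix(genotypes, nrow = 1,
                                 dimnames = list(sample_id, NULL)),
                          vocab = vocab, max_len = max_len, snps = snps)
  structure(list(
    sample_id = sample_id,
    token_ids = b$input_ids[1, ],
    attention_mask = b$attention_mask[1, ],
    n_genomic = b$n_genomic,
    window_map = b$window_map
  ), class = "tokenized_individual")
}

#' Tokenize a whole genotype matrix
#'
#' Matrix version of [tokenize()]: all individuals share the same marker
#' order, so tokenization is vectorised into two aligned integer matrices.
#'
#' @param mat integer matrix (individuals x SNPs) with values in
#'   \{0, 1, 2\}, e.g. the `integer` matrix from
#'   [impute_and_discretize()]; or a [genotype_table()] without missing
#'   calls.
#' @inheritParams tokenize
#' @param max_len maximum number of genomic tokens; `NULL` pads only to
#'   the realised token count.
#' @return A `tokenized_batch` list: `input_ids` and `attention_mask`
#'   (individuals x (1 + max_len) integer/binary matrices, ids 0-based),
#'   `n_genomic`, `window_map`, `vocab_hash`.
#' @export
tokenize_genotypes <- function(mat, vocab = build_vocabulary(),
                               max_len = 10240L, snps = NULL) {
  if (inherits(mat, "genotype_table")) {
    snps <- snps %||% mat$snps
    mat <- mat$dosages
    if (anyNA(mat)) abort("genotype table has missing calls; impute first")
  }
  k <- vocab$k
  ids <- encode_kmers(mat, vocab)
  n_tok_full <- ncol(ids)
  if (is.null(max_len)) max_len <- n_tok_full
  check_scalar(max_len, "max_len", 1, integerish = TRUE)
  n_genomic <- min(n_tok_full, max_len)
  ids <- ids[, seq_len(n_genomic), drop = FALSE]
  n <- nrow(mat)
  input_ids <- matrix(vocab$pad_id, n, 1L + max_len)
  input_ids[, 1] <- vocab$cls_id
  if (n_genomic > 0) input_ids[, 1 + seq_len(n_genomic)] <- ids
  attention_mask <- matrix(0L, n, 1L + max_len)
  attention_mask[, seq_len(1 + n_genomic)] <- 1L
  storage.mode(input_ids) <- "integer"
  rownames(input_ids) <- rownames(mat)
  wm <- NULL
  if (!is.null(snps) && n_genomic > 0) {
    starts <- (seq_len(n_genomic) - 1L) * k + 1L
    ends <- starts + k - 1L
    wm <- tibble::tibble(
      token_index = seq_len(n_genomic),
      chrom = snps$chrom[starts],
      start = snps$pos[starts],
      end = snps$pos[ends],
      snp_start = starts,
      snp_end = ends
    )
  }
  structure(list(input_ids = input_ids, attention_mask = attention_mask,
                 n_genomic = n_genomic, window_map = wm,
                 vocab_hash = vocab_hash(vocab)),
            class = "tokenized_batch")
}

vocab_hash <- function(vocab) {
  sum(utf8ToInt(paste(vocab$tokens, collapse = "")) *
        (seq_len(nchar(paste(vocab$tokens, collapse = ""))) %% 97)) %% 1e9
}

#' Recover the genotype sequence from a tokenized individual
#'
#' Inverse of [tokenize()] up to the dropped remainder and truncation.
#'
#' @param t a `tokenized_individual`.
#' @param vocab the vocabulary used to tokenize.
#' @return Integer vector of genotypes.
#' @export
detokenize <- function(t, vocab = build_vocabulary()) {
  stopifnot(inherits(t, "tokenized_individual"))
  gen <- t$token_ids[1 + seq_len(t$n_genomic)]
  if (!length(gen)) return(integer(0))
  strs <- id_token(vocab, gen)
  as.integer(unlist(strsplit(paste(strs, collapse = ""), "")))
}

#' Masking specification for masked 6-mer prediction
#'
#' In each sequence, `select_rate` of the genomic tokens are selected for
#' prediction; of these, `mask_frac` are replaced with `[MASK]`,
#' `random_frac` with a uniformly drawn genomic token, and `keep_frac` are
#' left unchanged.  Counts are exact (half-up rounding, remainder to the
#' unchanged group) rather than per-token Bernoulli draws.
#'
#' @param select_rate fraction of genomic tokens selected for prediction.
#' @param mask_frac,random_frac,keep_frac partition of the selected
#'   tokens; must sum to 1.
#' @param seed integer seed for position/replacement draws.
#' @return A `masking_spec` list.
#' @export
masking_spec <- function(select_rate = 0.15, mask_frac = 0.8,
                         random_frac = 0.1, keep_frac = 0.1, seed = 42) {
  check_scalar(select_rate, "select_rate", 0, 1)
  check_scalar(mask_frac, "mask_frac", 0, 1)
  check_scalar(random_frac, "random_frac", 0, 1)
  check_scalar(keep_frac, "keep_frac", 0, 1)
  if (abs(mask_frac + random_frac + keep_frac - 1) > 1e-9) {
    abort("mask_frac + random_frac + keep_frac must equal 1")
  }
  structure(list(select_rate = select_rate, mask_frac = mask_frac,
                 random_frac = random_frac, keep_frac = keep_frac,
                 seed = as.integer(seed)), class = "masking_spec")
}

#' Label sentinel for unselected positions
#' @export
IGNORE_LABEL <- -100L

#' Apply masked-token corruption to a tokenized batch
#'
#' Implements the masked 6-mer prediction (M6P) corruption: per sequence,
#' exactly `round(select_rate * n_genomic)` genomic positions are selected
#' uniformly without replacement; exactly `round(mask_frac * n_sel)` become
#' `[MASK]`, exactly `round(random_frac * n_sel)` a random genomic token,
#' and the remainder stay unchanged.  Labels carry the original token id at
#' every selected position and [IGNORE_LABEL] elsewhere; `[CLS]`/`[PAD]`
#' are never selected and the attention mask is untouched.
#'
#' @param batch a `tokenized_batch` (or single `tokenized_individual`).
#' @param spec a [masking_spec()].
#' @param vocab the vocabulary.
#' @param seed overrides `spec$seed` when given (used by the training loop
#'   to resample masks every epoch).
#' @return A `masked_batch` list: `input_ids`, `attention_mask`, `labels`.
#' @export
apply_masking <- function(batch, spec = masking_spec(),
                          vocab = build_vocabulary(), seed = NULL) {
  if (inherits(batch, "tokenized_individual")) {
    batch <- structure(list(
      input_ids = matrix(batch$token_ids, 1,
                         dimnames = list(batch$sample_id, NULL)),
      attention_mask = matrix(batch$attention_mask, 1),
      n_genomic = batch$n_genomic), class = "tokenized_batch")
  }
  stopifnot(inherits(batch, "tokenized_batch"),
            inherits(spec, "masking_spec"))
  ids <- batch$input_ids
  labels <- matrix(IGNORE_LABEL, nrow(ids), ncol(ids))
  genomic <- vocab$genomic_ids
  with_seed(derive_seed(seed %||% spec$seed, 3), {
    for (i in seq_len(nrow(ids))) {
      pos <- which(batch$attention_mask[i, ] == 1L & ids[i, ] != vocab$cls_id)
      n_sel <- round_half_up(spec$select_rate * length(pos))
      if (n_sel < 1) next
      sel <- pos[sample.int(length(pos), n_sel)]
      labels[i, sel] <- ids[i, sel]
      n_mask <- round_half_up(spec$mask_frac * n_sel)
      n_rand <- round_half_up(spec$random_frac * n_sel)
      n_mask <- min(n_mask, n_sel)
      n_rand <- min(n_rand, n_sel - n_mask)
      # order of roles over the (already random) selected positions
      if (n_mask > 0) ids[i, sel[seq_len(n_mask)]] <- vocab$mask_id
      if (n_rand > 0) {
        ids[i, sel[n_mask + seq_len(n_rand)]] <-
          sample(genomic, n_rand, replace = TRUE)
      }
    }
  })
  structure(list(input_ids = ids, attention_mask = batch$attention_mask,
                 labels = labels), class = "masked_batch")
}
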