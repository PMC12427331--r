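test_that("vocabulary enumerates 3 specials plus all 729 6-mers bijectively", {
  v <- build_vocabulary()
  expect_equal(v$size, 732)
  expect_equal(length(v$genomic_ids), 729)
  expect_equal(token_id(v, c("[CLS]", "[PAD]", "[MASK]")), 0:2)
  expect_true(all(c("000000", "222222") %in% v$tokens))
  expect_false(token_id(v, "000000") == token_id(v, "222222"))
  # id -> string -> id identity over the whole vocabulary
  ids <- 0:(v$size - 1)
  expect_equal(token_id(v, id_token(v, ids)), ids)
  expect_equal(anyDuplicated(v$tokens), 0)
  # lexicographic order of the genomic block
  expect_equal(id_token(v, 3:5), c("000000", "000001", "000002"))
})

test_that("tokenization windows, truncation and padding follow the contract", {
  v <- build_vocabulary()
  t1 <- tokenize(as.integer(strsplit("010201120210", "")[[1]]), v,
                 max_len = 4)
  expect_equal(t1$n_genomic, 2)
  expect_equal(id_token(v, t1$token_ids[2:3]), c("010201", "120210"))
  expect_equal(t1$token_ids[1], v$cls_id)
  expect_equal(t1$token_ids[4:5], rep(v$pad_id, 2))
  expect_equal(t1$attention_mask, c(1, 1, 1, 0, 0))
  expect_equal(length(t1$token_ids), 1 + 4)

  # a 65,000-SNP genome exceeds the cap: floor(65000/6) = 10833 candidate
  # tokens, 10240 kept
  long <- tokenize(sample(0:2, 65000, replace = TRUE), v)
  expect_equal(long$n_genomic, 10240)
  expect_equal(length(long$token_ids), 10241)
  expect_equal(sum(long$attention_mask), 10241)

  # a 52,842-SNP array: 8807 genomic tokens, no truncation, padded
  chip <- tokenize(sample(0:2, 52842, replace = TRUE), v)
  expect_equal(chip$n_genomic, floor(52842 / 6))
  expect_equal(chip$n_genomic, 8807)
  expect_equal(sum(chip$attention_mask), 1 + 8807)
  expect_equal(length(chip$token_ids), 10241)

  expect_error(tokenize(c(0L, 1L, 3L, 0L, 1L, 2L), v), "outside")
})

test_that("detokenization inverts tokenization up to remainder and truncation", {
  v <- build_vocabulary()
  s <- sample(0:2, 60, replace = TRUE)
  expect_equal(detokenize(tokenize(s, v, max_len = 10), v), s)
  # trailing remainder dropped
  s13 <- sample(0:2, 13, replace = TRUE)
  expect_equal(detokenize(tokenize(s13, v, max_len = 10), v), s13[1:12])
  # empty input
  t0 <- tokenize(integer(0), v, max_len = 4)
  expect_equal(t0$n_genomic, 0)
  expect_equal(detokenize(t0, v), integer(0))
  # truncation keeps the head
  s30 <- sample(0:2, 30, replace = TRUE)
  expect_equal(detokenize(tokenize(s30, v, max_len = 3), v), s30[1:18])
})

test_that("window map ties tokens back to SNP coordinates", {
  out <- tiny_sim(seed = 16, n_founders = 10, offspring = 5, n_blocks = 3)
  tk <- tokenize_genotypes(out$genotypes, max_len = NULL)
  wm <- tk$window_map
  expect_equal(nrow(wm), 3)
  expect_equal(wm$snp_start, c(1L, 7L, 13L))
  expect_equal(wm$snp_end, c(6L, 12L, 18L))
  expect_equal(wm$start, out$genotypes$snps$pos[wm$snp_start])
  expect_equal(wm$end, out$genotypes$snps$pos[wm$snp_end])
})

test_that("masking selects exact counts with the 80/10/10 partition", {
  v <- build_vocabulary()
  set.seed(2)
  geno <- matrix(sample(0:2, 6000, replace = TRUE), 1)
  tk <- tokenize_genotypes(geno, v, max_len = NULL)
  expect_equal(tk$n_genomic, 1000)
  mk <- apply_masking(tk, masking_spec(), v, seed = 9)
  sel <- which(mk$labels[1, ] != IGNORE_LABEL)
  expect_equal(length(sel), 150)
  masked <- sum(mk$input_ids[1, sel] == v$mask_id)
  unchanged <- sum(mk$input_ids[1, sel] == tk$input_ids[1, sel])
  randomized <- 150 - masked - unchanged
  expect_equal(masked, 120)
  # a random replacement can coincide with the original token (1/729), so
  # the unchanged count is >= the 15 kept positions
  expect_gte(unchanged, 15)
  expect_lte(randomized, 15)
  expect_true(all(mk$input_ids[1, sel] != v$cls_id))
  expect_true(all(mk$input_ids[1, sel] != v$pad_id))
  # labels carry the original ids
  expect_equal(mk$labels[1, sel], tk$input_ids[1, sel])
  # non-selected positions untouched
  expect_equal(mk$input_ids[1, -sel], tk$input_ids[1, -sel])
})

test_that("masking never touches specials, padding or the attention mask", {
  v <- build_vocabulary()
  geno <- matrix(sample(0:2, 5 * 60, replace = TRUE), 5)
  tk <- tokenize_genotypes(geno, v, max_len = 15)   # 10 genomic + 5 pads
  mk <- apply_masking(tk, masking_spec(select_rate = 0.5), v, seed = 4)
  expect_identical(mk$attention_mask, tk$attention_mask)
  expect_true(all(mk$labels[, 1] == IGNORE_LABEL))
  expect_true(all(mk$input_ids[, 1] == v$cls_id))
  pads <- tk$attention_mask == 0
  expect_true(all(mk$input_ids[pads] == v$pad_id))
  expect_true(all(mk$labels[pads] == IGNORE_LABEL))
  # select_rate 0: nothing selected, input unchanged
  mk0 <- apply_masking(tk, masking_spec(select_rate = 0), v, seed = 4)
  expect_identical(mk0$input_ids, tk$input_ids)
  expect_true(all(mk0$labels == IGNORE_LABEL))
  # determinism
  expect_identical(apply_masking(tk, masking_spec(), v, seed = 11),
                   apply_masking(tk, masking_spec(), v, seed = 11))
  expect_false(identical(apply_masking(tk, masking_spec(), v, seed = 11),
                         apply_masking(tk, masking_spec(), v, seed = 12)))
})

test_that("selection positions are uniform over genomic tokens", {
  v <- build_vocabulary()
  geno <- matrix(sample(0:2, 1200, replace = TRUE), 1)
  tk <- tokenize_genotypes(geno, v, max_len = NULL)  # 200 genomic tokens
  reps <- 300
  counts <- numeric(200)
  for (r in seq_len(reps)) {
    mk <- apply_masking(tk, masking_spec(), v, seed = 1000 + r)
    sel <- which(mk$labels[1, ] != IGNORE_LABEL) - 1   # genomic index
    counts[sel] <- counts[sel] + 1
  }
  freq <- counts / reps
  expect_equal(mean(freq), 0.15, tolerance = 1e-12)  # exact-count selection
  se <- sqrt(0.15 * 0.85 / reps)
  expect_lt(max(abs(freq - 0.15)), 4.5 * se)
})
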