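dbl_cfg <- function(...) {
  model_config("tiny", n_layers = 2, d_model = 16, n_heads = 2,
               ffn_size = 24, dropout = 0, max_positions = 16,
               precision = "double", ...)
}

small_batch <- function(n = 3, snps = 48, max_len = 10, seed = 21) {
  set.seed(seed)
  v <- build_vocabulary()
  g <- matrix(sample(0:2, n * snps, replace = TRUE), n,
              dimnames = list(paste0("s", seq_len(n)), NULL))
  list(vocab = v, tokens = tokenize_genotypes(g, v, max_len = max_len))
}

test_that("encoder output shapes and eval-mode determinism hold", {
  b <- small_batch()
  m <- init_model(dbl_cfg(), seed = 1)
  enc1 <- forward_encoder(m, b$tokens$input_ids, b$tokens$attention_mask)
  expect_equal(dim(enc1$hidden), c(3, 11, 16))
  enc2 <- forward_encoder(m, b$tokens$input_ids, b$tokens$attention_mask)
  expect_identical(enc1$hidden, enc2$hidden)
  expect_error(
    forward_encoder(m, matrix(0L, 1, 20), matrix(1, 1, 20)),
    "max_positions")
  expect_error(
    forward_encoder(m, matrix(900L, 1, 4), matrix(1, 1, 4)),
    "out of range")
})

test_that("attention rows are normalised and ignore padded keys", {
  b <- small_batch()
  m <- init_model(dbl_cfg(), seed = 2)
  enc <- forward_encoder(m, b$tokens$input_ids, b$tokens$attention_mask,
                         retain_attention = TRUE)
  ng <- b$tokens$n_genomic
  for (l in 1:2) {
    A <- enc$attention[[l]]
    sums <- apply(A, c(1, 3, 4), sum)
    expect_true(all(abs(sums - 1) < 1e-5))
    # no mass on padded keys
    expect_true(all(A[, (2 + ng):11, , ] < 1e-12))
  }
})

test_that("padding does not perturb the [CLS] representation or predictions", {
  v <- build_vocabulary()
  set.seed(3)
  g <- matrix(sample(0:2, 2 * 48, replace = TRUE), 2,
              dimnames = list(c("a", "b"), NULL))
  m <- init_model(dbl_cfg(), seed = 3)
  tk1 <- tokenize_genotypes(g, v, max_len = 8)    # no padding
  tk2 <- tokenize_genotypes(g, v, max_len = 13)   # 5 extra pads
  h1 <- forward_encoder(m, tk1$input_ids, tk1$attention_mask)$hidden
  h2 <- forward_encoder(m, tk2$input_ids, tk2$attention_mask)$hidden
  expect_lt(max(abs(h1[, 1, ] - h2[, 1, ])), 1e-5)
  p1 <- regress_from_cls(m, tk1$input_ids, tk1$attention_mask)
  p2 <- regress_from_cls(m, tk2$input_ids, tk2$attention_mask)
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("parameter count matches the analytic formula", {
  count_for <- function(cfg) {
    d <- cfg$d_model; f <- cfg$ffn_size; V <- cfg$vocab_size
    P <- cfg$max_positions; L <- cfg$n_layers
    V * d + P * d + 2 * d +                      # embeddings + LN
      L * (4 * (d * d + d) +                     # Q,K,V,O projections
             4 * d +                             # two LayerNorms
             d * f + f + f * d + d) +            # FFN
      d * V + V +                                # MLM head
      2 * d + (d * d + d) + (d + 1)              # CLS head (LN + MLP)
  }
  for (cfg in list(dbl_cfg(), model_config("tiny"))) {
    expect_equal(n_parameters(init_model(cfg, seed = 4)), count_for(cfg))
  }
  # the full-scale architecture, computed without instantiating it
  expect_equal(count_for(model_config("full")), 94639069)
})

test_that("a zeroed MLM head scores exactly at uniform-guessing entropy", {
  b <- small_batch()
  m <- init_model(dbl_cfg(), seed = 5)
  m$params$mlm_W[] <- 0
  m$params$mlm_b[] <- 0
  mk <- apply_masking(b$tokens, masking_spec(select_rate = 0.5), b$vocab,
                      seed = 6)
  res <- mlm_loss(m, mk)
  expect_equal(res$loss, log(732), tolerance = 1e-9)
  # all-ignore labels are a contract violation, not a silent zero
  mk$labels[] <- IGNORE_LABEL
  expect_error(mlm_loss(m, mk), "no labeled positions")
})

test_that("a zeroed regression head predicts exactly zero", {
  b <- small_batch()
  m <- init_model(dbl_cfg(), seed = 7)
  m$params$cls_w2[] <- 0
  m$params$cls_b2 <- 0
  p <- regress_from_cls(m, b$tokens$input_ids, b$tokens$attention_mask)
  expect_equal(unname(p), rep(0, 3))
})

test_that("analytic gradients agree with finite differences for both heads", {
  b <- small_batch(n = 3, snps = 36, max_len = 7)
  m <- init_model(dbl_cfg(), seed = 8)
  cc <- unclass(m$config)
  mk <- apply_masking(b$tokens, masking_spec(select_rate = 0.4), b$vocab,
                      seed = 9)
  ids <- mk$input_ids; storage.mode(ids) <- "integer"
  am <- matrix(as.numeric(mk$attention_mask), nrow(ids))
  lb <- mk$labels; storage.mode(lb) <- "integer"
  out <- snpformer:::cpp_tf_mlm(m$params, ids, am, lb, cc, train = FALSE,
                                seed = 1, want_grads = TRUE, single = FALSE)
  eps <- 1e-5
  num_grad <- function(fun, nm, idx) {
    p <- m$params
    p[[nm]][idx] <- p[[nm]][idx] + eps; up <- fun(p)
    p[[nm]][idx] <- p[[nm]][idx] - 2 * eps; dn <- fun(p)
    (up - dn) / (2 * eps)
  }
  mlm_fun <- function(p) {
    snpformer:::cpp_tf_mlm(p, ids, am, lb, cc, FALSE, 1, FALSE, FALSE)$loss
  }
  for (nm in names(m$params)) {
    gmat <- out$grads[[nm]]
    idx <- which(abs(gmat) == max(abs(gmat)))[1]
    expect_equal(gmat[idx], num_grad(mlm_fun, nm, idx),
                 tolerance = 1e-4, label = paste("MLM grad", nm))
  }
  y <- rnorm(3)
  outr <- snpformer:::cpp_tf_reg(m$params, ids, am, y, cc, train = FALSE,
                                 seed = 1, want_grads = TRUE, single = FALSE)
  reg_fun <- function(p) {
    snpformer:::cpp_tf_reg(p, ids, am, y, cc, FALSE, 1, FALSE, FALSE)$loss
  }
  for (nm in c("tok_emb", "pos_emb", "l1_Wq", "l2_W2", "cls_W1", "cls_w2",
               "cls_b2", "emb_ln_g", "l1_ln1_b")) {
    gmat <- outr$grads[[nm]]
    idx <- which(abs(gmat) == max(abs(gmat)))[1]
    expect_equal(gmat[idx], num_grad(reg_fun, nm, idx),
                 tolerance = 1e-4, label = paste("reg grad", nm))
  }
  # [PAD] embedding receives no gradient from the CLS prediction (padded
  # positions are masked out as keys)
  v <- build_vocabulary()
  expect_equal(max(abs(outr$grads$tok_emb[v$pad_id + 1, ])), 0)
})

test_that("single and double precision agree to float tolerance", {
  b <- small_batch()
  cfg_s <- dbl_cfg(); cfg_s$precision <- "single"
  m_d <- init_model(dbl_cfg(), seed = 10)
  m_s <- m_d; m_s$config <- cfg_s
  pd <- regress_from_cls(m_d, b$tokens$input_ids, b$tokens$attention_mask)
  ps <- regress_from_cls(m_s, b$tokens$input_ids, b$tokens$attention_mask)
  expect_equal(pd, ps, tolerance = 1e-4)
})
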