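test_that("simulated populations have the configured shape and alphabet", {
  out <- tiny_sim(seed = 3)
  d <- out$genotypes$dosages
  expect_equal(dim(d), c(40 + 2 * 60, 20 * 6))
  expect_true(all(d %in% 0:2))
  expect_equal(out$pedigree$generation,
               rep(0:2, c(40, 60, 60)))
  founders <- out$pedigree$generation == 0
  expect_true(all(is.na(out$pedigree$sire[founders])))
  expect_true(all(!is.na(out$pedigree$sire[!founders])))
  # same seed, byte-identical output
  out2 <- tiny_sim(seed = 3)
  expect_identical(out$genotypes$dosages, out2$genotypes$dosages)
  expect_identical(out$phenotypes$value, out2$phenotypes$value)
  # different seed differs
  expect_false(identical(out$genotypes$dosages,
                         tiny_sim(seed = 4)$genotypes$dosages))
})

test_that("zero-heritability traits are pure noise", {
  out <- tiny_sim(seed = 5, h2_additive = 0, dominance_frac = 0,
                  epistasis_frac = 0)
  expect_true(all(out$true_genetic_values == 0))
  expect_equal(out$realized_h2, 0)
  expect_gt(var(out$phenotypes$value), 0)
})

test_that("variance fractions are hit exactly in-sample", {
  out <- tiny_sim(seed = 6, n_founders = 100, offspring = 200,
                  h2_additive = 0.62)
  expect_equal(out$realized_h2, 0.62, tolerance = 1e-12)
  expect_equal(var(out$components$additive) / var(out$phenotypes$value),
               0.62, tolerance = 1e-12)
  # mixed architecture: each component variance matches its fraction
  out <- tiny_sim(seed = 7, n_founders = 100, offspring = 200,
                  h2_additive = 0.3, dominance_frac = 0.1,
                  epistasis_frac = 0.2, n_causal_pairs = 15)
  vy <- var(out$phenotypes$value)
  expect_equal(var(out$components$additive) / vy, 0.3, tolerance = 1e-12)
  expect_equal(var(out$components$dominance) / vy, 0.1, tolerance = 1e-12)
  expect_equal(var(out$components$epistasis) / vy, 0.2, tolerance = 1e-12)
  expect_equal(out$realized_h2, 0.6, tolerance = 1e-10)
})

test_that("impossible variance budgets and causal counts are rejected", {
  expect_error(sim_config(h2_additive = 0.7, epistasis_frac = 0.4),
               "budget")
  expect_error(sim_config(n_blocks = 2, block_size = 3, n_causal_add = 7),
               "range")
  expect_error(simulate_population(
    sim_config(h2_additive = 0.3, n_causal_add = 0)), "n_causal_add")
})

test_that("offspring block haplotypes are exact parental copies", {
  out <- tiny_sim(seed = 8, recomb_prob = 0.5)
  ped <- out$pedigree
  ids <- ped$id
  for (i in which(ped$generation > 0)) {
    si <- match(ped$sire[i], ids)
    di <- match(ped$dam[i], ids)
    # gamete 1 from sire, gamete 2 from dam, block by block
    for (k in seq_len(dim(out$haplotypes)[2])) {
      expect_true(out$haplotypes[i, k, 1] %in% out$haplotypes[si, k, ])
      expect_true(out$haplotypes[i, k, 2] %in% out$haplotypes[di, k, ])
    }
  }
})

test_that("two founder haplotypes without recombination give perfect within-block LD", {
  out <- tiny_sim(seed = 9, n_founders = 80, offspring = 100,
                  haplotypes_per_block = 2, recomb_prob = 0,
                  n_blocks = 10)
  d <- out$genotypes$dosages
  # brute-force r^2 between segregating SNP pairs inside each block
  for (k in 1:10) {
    cols <- ((k - 1) * 6 + 1):(k * 6)
    pool <- out$block_pools[[k]]$alleles
    seg <- cols[pool[1, ] != pool[2, ]]   # SNPs that differ between the
    if (length(seg) < 2) next             # two founder haplotypes
    for (a in seg[-1]) {
      r2 <- suppressWarnings(cor(d[, seg[1]], d[, a])^2)
      expect_equal(r2, 1, tolerance = 1e-12)
    }
  }
})

test_that("injected missingness is deterministic, targeted and QC-visible", {
  out <- tiny_sim(seed = 10)
  gt <- out$genotypes
  expect_identical(inject_missingness(gt, snp_rate = 0)$dosages, gt$dosages)
  a <- inject_missingness(gt, snp_rate = 0.5, seed = 3)
  b <- inject_missingness(gt, snp_rate = 0.5, seed = 3)
  expect_identical(a$dosages, b$dosages)
  expect_gt(mean(is.na(a$dosages)), 0.4)
  expect_lt(mean(is.na(a$dosages)), 0.6)
  # concentrated on one SNP: pushes its call rate under the QC threshold
  big <- tiny_sim(seed = 11, n_founders = 200, offspring = 400)
  target <- colnames(big$genotypes$dosages)[5]
  m <- inject_missingness(big$genotypes, snp_rate = 0.08, seed = 4,
                          snps = target)
  st <- snp_stats(m)
  expect_lt(st$call_rate[st$snp_id == target], 0.95)
  qc <- apply_qc(recode_to_minor(m))
  expect_false(target %in% qc$table$snps$snp_id)
  expect_equal(unname(qc$report$removed_by_rule[["call_rate"]]), 1)
})

test_that("GBLUP accuracy across replicate simulations stays near the simulated heritability", {
  # additive trait at h2 = 0.4; mean test R2 over many replicate seeds must
  # not exceed the heritability by more than 0.05
  r2 <- vapply(1:50, function(seed) {
    out <- simulate_population(sim_config(
      n_founders = 200, n_generations = 3, offspring_per_generation = 200,
      n_blocks = 50, block_size = 6, h2_additive = 0.4,
      n_causal_add = 100, seed = seed))
    y <- stats::setNames(out$phenotypes$value, out$phenotypes$id)
    split <- forward_split(out$pedigree)
    G <- compute_grm(impute_and_discretize(recode_to_minor(out$genotypes))$mean)
    gb <- fit_gblup(G, y[split$train], method = "reml")
    compute_metrics(y[split$test], predict(gb, G, ids = split$test))$r2
  }, 1)
  expect_lte(mean(r2), 0.45)
  expect_gt(mean(r2), 0.1)   # and it does pick up real signal
})
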