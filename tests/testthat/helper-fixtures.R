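# Shared fixture builders; everything is generated in code.

tiny_sim <- function(seed = 1, n_founders = 40, n_generations = 2,
                     offspring = 60, n_blocks = 20, block_size = 6, ...) {
  extra <- list(...)
  if (is.null(extra$n_causal_add)) {
    extra$n_causal_add <- max(2, floor(n_blocks * block_size / 3))
  }
  args <- c(list(
    n_founders = n_founders, n_generations = n_generations,
    offspring_per_generation = offspring, n_blocks = n_blocks,
    block_size = block_size, seed = seed), extra)
  simulate_population(do.call(sim_config, args))
}

# handcrafted 3-sample VCF with a phased record, a missing call and a
# multi-allelic record
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "1|0", "./.", "0|0", sep = "\t"),
    paste("2", "50", "rs3", "G", "A,T", ".", "PASS", ".", "GT",
          "0/1", "1/2", "0/0", sep = "\t")
  ), path)
  path
}

# genotype table with known planted QC violations (see test-qc.R)
planted_qc_table <- function(n = 200) {
  set.seed(77)
  m <- 10
  d <- matrix(rbinom(n * m, 2, 0.3), n, m)
  # SNP 2: call rate 0.94 (< 0.95)
  d[1:12, 2] <- NA
  # SNP 4: monomorphic (MAF 0)
  d[, 4] <- 0L
  # SNP 6: every call heterozygous (extreme HWE violation)
  d[, 6] <- 1L
  # individual 1: missing at 2 of the 7 surviving SNPs (> 10%)
  d[1, c(8, 9)] <- NA
  genotype_table(d, sample_ids = sprintf("i%03d", seq_len(n)))
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
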