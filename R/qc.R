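#' Quality-control thresholds
#'
#' Standard array-QC cutoffs: SNPs are removed when call rate < 95%
#' (missing rate > 5%), minor allele frequency < 1%, or the Hardy-Weinberg
#' chi-square test gives p < 1e-6; individuals are then removed when more
#' than 10% of their genotypes (over surviving SNPs) are missing.  All
#' inequalities are strict.
#'
#' @param min_call_rate minimum per-SNP call rate.
#' @param min_maf minimum minor allele frequency.
#' @param hwe_p_floor minimum Hardy-Weinberg equilibrium p-value.
#' @param max_ind_missing maximum per-individual missing fraction.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.01,
                          hwe_p_floor = 1e-6, max_ind_missing = 0.10) {
  check_scalar(min_call_rate, "min_call_rate", 0, 1, closed_lower = FALSE,
               closed_upper = FALSE)
  check_scalar(min_maf, "min_maf", 0, 1, closed_lower = FALSE,
               closed_upper = FALSE)
  check_scalar(hwe_p_floor, "hwe_p_floor", 0, 1, closed_lower = FALSE,
               closed_upper = FALSE)
  check_scalar(max_ind_missing, "max_ind_missing", 0, 1,
               closed_lower = FALSE, closed_upper = FALSE)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_p_floor = hwe_p_floor,
                 max_ind_missing = max_ind_missing),
            class = "qc_thresholds")
}

#' Per-SNP quality-control statistics
#'
#' Computes, for each SNP of a minor-allele-coded table: call rate
#' (non-missing / total), minor allele frequency among non-missing calls,
#' and a 1-degree-of-freedom chi-square goodness-of-fit test of observed
#' genotype counts against Hardy-Weinberg expectations (no continuity
#' correction).  Monomorphic SNPs get chi-square 0 and p = 1; SNPs with no
#' observed calls get call rate 0 and `NA` statistics.
#'
#' @param table a [genotype_table()].
#' @return A tibble with columns `snp_id`, `call_rate`, `maf`,
#'   `hwe_chisq`, `hwe_p`, `n_obs`.
#' @export
snp_stats <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  d <- table$dosages
  n <- nrow(d)
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  nobs <- n0 + n1 + n2
  call_rate <- nobs / n
  p <- ifelse(nobs > 0, (2 * n2 + n1) / (2 * nobs), NA_real_)  # counted allele
  maf <- pmin(p, 1 - p)
  q <- 1 - p
  e0 <- nobs * q^2; e1 <- nobs * 2 * p * q; e2 <- nobs * p^2
  chisq <- rep(NA_real_, length(nobs))
  poly <- !is.na(p) & p > 0 & p < 1
  chisq[poly] <- (n0[poly] - e0[poly])^2 / e0[poly] +
    (n1[poly] - e1[poly])^2 / e1[poly] +
    (n2[poly] - e2[poly])^2 / e2[poly]
  mono <- !is.na(p) & (p == 0 | p == 1)
  chisq[mono] <- 0
  hwe_p <- ifelse(is.na(chisq), NA_real_,
                  pchisq(chisq, df = 1, lower.tail = FALSE))
  tibble::tibble(snp_id = colnames(d), call_rate = unname(call_rate),
                 maf = unname(maf), hwe_chisq = unname(chisq),
                 hwe_p = unname(hwe_p), n_obs = unname(nobs))
}

#' Apply quality control to a genotype table
#'
#' Single pass in the conventional order: SNP-level filters first (call
#' rate, then MAF, then HWE, each SNP attributed to the first rule it
#' violates, all computed on the full individual set), then the
#' per-individual missingness filter evaluated on the surviving SNPs.  Set
#' `individuals_first = TRUE` for the alternative order (per-SNP statistics
#' then reflect the filtered individual set).
#'
#' @param table a [genotype_table()], minor-allele coded.
#' @param thresholds a [qc_thresholds()].
#' @param individuals_first apply the individual filter before SNP filters.
#' @return A list with elements `table` (filtered [genotype_table()]) and
#'   `report` (a `qc_report`: counts per rule plus the per-SNP stats
#'   tibble).
#' @export
apply_qc <- function(table, thresholds = qc_thresholds(),
                     individuals_first = FALSE) {
  stopifnot(inherits(table, "genotype_table"),
            inherits(thresholds, "qc_thresholds"))
  th <- thresholds
  ind_filter <- function(tab) {
    miss <- rowMeans(is.na(tab$dosages))
    drop <- miss > th$max_ind_missing
    list(keep = !drop, n_removed = sum(drop))
  }
  n_ind_in <- n_samples(table); n_snp_in <- n_snps(table)
  removed_ind_pre <- 0L
  if (individuals_first) {
    f <- ind_filter(table)
    removed_ind_pre <- f$n_removed
    table$dosages <- table$dosages[f$keep, , drop = FALSE]
  }
  stats <- snp_stats(table)
  rule <- rep(NA_character_, nrow(stats))
  rule[is.na(rule) & stats$call_rate < th$min_call_rate] <- "call_rate"
  rule[is.na(rule) & (is.na(stats$maf) | stats$maf < th$min_maf)] <- "maf"
  rule[is.na(rule) & stats$hwe_p < th$hwe_p_floor] <- "hwe"
  keep_snp <- is.na(rule)
  tab2 <- table
  tab2$dosages <- tab2$dosages[, keep_snp, drop = FALSE]
  tab2$snps <- tab2$snps[keep_snp, , drop = FALSE]
  if (ncol(tab2$dosages) == 0) abort("all SNPs filtered by QC")
  removed_ind <- removed_ind_pre
  if (!individuals_first) {
    f <- ind_filter(tab2)
    removed_ind <- f$n_removed
    tab2$dosages <- tab2$dosages[f$keep, , drop = FALSE]
  }
  if (nrow(tab2$dosages) == 0) abort("all individuals filtered by QC")
  report <- structure(list(
    n_snps_in = n_snp_in, n_snps_out = ncol(tab2$dosages),
    n_ind_in = n_ind_in, n_ind_out = nrow(tab2$dosages),
    removed_by_rule = c(call_rate = sum(rule == "call_rate", na.rm = TRUE),
                        maf = sum(rule == "maf", na.rm = TRUE),
                        hwe = sum(rule == "hwe", na.rm = TRUE),
                        individual = removed_ind),
    snp_stats = dplyr::mutate(stats, removed_by = rule),
    thresholds = th
  ), class = "qc_report")
  list(table = tab2, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> SNPs %d -> %d, individuals %d -> %d\n",
              x$n_snps_in, x$n_snps_out, x$n_ind_in, x$n_ind_out))
  r <- x$removed_by_rule
  cat(sprintf("  removed: call rate %d, MAF %d, HWE %d, individuals %d\n",
              r[["call_rate"]], r[["maf"]], r[["hwe"]], r[["individual"]]))
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) x$snp_stats

#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(n_snps_in = x$n_snps_in, n_snps_out = x$n_snps_out,
                 n_ind_in = x$n_ind_in, n_ind_out = x$n_ind_out,
                 removed_call_rate = x$removed_by_rule[["call_rate"]],
                 removed_maf = x$removed_by_rule[["maf"]],
                 removed_hwe = x$removed_by_rule[["hwe"]],
                 removed_individual = x$removed_by_rule[["individual"]])
}

#' Mean-impute missing genotypes and discretize for tokenization
#'
#' Missing entries are replaced by the SNP's mean dosage over observed
#' calls (`mean` matrix, used by GBLUP/Lasso); the `integer` matrix
#' additionally rounds imputed values half-up to the nearest of \{0, 1, 2\}
#' (tokens need a discrete alphabet).  Observed genotypes are never
#' altered.
#'
#' @param table a post-QC [genotype_table()].
#' @return A list with `mean` (numeric matrix) and `integer` (integer
#'   matrix).
#' @export
impute_and_discretize <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  d <- table$dosages
  mu <- colMeans(d, na.rm = TRUE)
  if (anyNA(mu)) abort("SNP with zero observed calls; run apply_qc() first")
  mean_mat <- d
  storage.mode(mean_mat) <- "double"
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) {
    mean_mat[idx] <- mu[idx[, 2]]
  }
  int_mat <- d
  if (nrow(idx)) {
    int_mat[idx] <- as.integer(pmin(2, pmax(0, round_half_up(mu[idx[, 2]]))))
  }
  list(mean = mean_mat, integer = int_mat)
}
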