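#' Configuration for the synthetic population simulator
#'
#' Defines an LD-block genotype model (founder haplotype pools per block,
#' between-block recombination, no within-block recombination), a random-
#' mating multi-generation pedigree, and a quantitative trait with additive,
#' dominance and epistatic components whose in-sample variance fractions are
#' hit exactly by construction.
#'
#' `h2_additive`, `dominance_frac` and `epistasis_frac` are fractions of
#' *phenotypic* variance; their sum is the broad-sense heritability and must
#' not exceed 1.  The default additive heritability sits in the 0.07--0.62
#' range typical of pig production traits.
#'
#' @param n_founders number of generation-0 individuals.
#' @param n_generations number of descendant generations.
#' @param offspring_per_generation individuals born per generation.
#' @param n_blocks number of LD blocks.
#' @param block_size SNPs per block (within-block haplotypes are inherited
#'   intact).
#' @param haplotypes_per_block founder haplotype diversity per block (>= 2).
#' @param recomb_prob probability of switching parental chromosome between
#'   consecutive blocks when forming a gamete.
#' @param maf_bounds length-2 numeric; founder blocks are resampled until
#'   every SNP's minor allele frequency (implied by haplotype frequencies)
#'   falls inside this interval.
#' @param h2_additive,dominance_frac,epistasis_frac phenotypic-variance
#'   fractions of the additive, dominance and (pairwise) epistatic
#'   components; sum must be <= 1.
#' @param n_causal_add number of additive causal SNPs (dominance effects are
#'   drawn at the same loci); default half the SNPs, capped at 100.
#' @param n_causal_pairs number of epistatic locus pairs.
#' @param epistasis_pairing `"within_block"` draws both members of a pair
#'   from the same LD block (local, haplotype-borne interactions);
#'   `"random"` pairs loci genome-wide.
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 100,
                       n_generations = 3,
                       offspring_per_generation = 300,
                       n_blocks = 100,
                       block_size = 6,
                       haplotypes_per_block = 4,
                       recomb_prob = 0.5,
                       maf_bounds = c(0.05, 0.5),
                       h2_additive = 0.4,
                       dominance_frac = 0,
                       epistasis_frac = 0,
                       n_causal_add = NULL,
                       n_causal_pairs = 20,
                       epistasis_pairing = c("within_block", "random"),
                       seed = 42) {
  check_scalar(n_founders, "n_founders", 2, integerish = TRUE)
  check_scalar(n_generations, "n_generations", 0, integerish = TRUE)
  check_scalar(offspring_per_generation, "offspring_per_generation", 1,
               integerish = TRUE)
  check_scalar(n_blocks, "n_blocks", 1, integerish = TRUE)
  check_scalar(block_size, "block_size", 1, integerish = TRUE)
  check_scalar(haplotypes_per_block, "haplotypes_per_block", 2,
               integerish = TRUE)
  check_scalar(recomb_prob, "recomb_prob", 0, 1)
  stopifnot(length(maf_bounds) == 2, maf_bounds[1] > 0,
            maf_bounds[2] <= 0.5, maf_bounds[1] <= maf_bounds[2])
  check_scalar(h2_additive, "h2_additive", 0, 1)
  check_scalar(dominance_frac, "dominance_frac", 0, 1)
  check_scalar(epistasis_frac, "epistasis_frac", 0, 1)
  if (h2_additive + dominance_frac + epistasis_frac > 1 + 1e-12) {
    abort("variance budget impossible: h2_additive + dominance_frac + epistasis_frac > 1")
  }
  if (dominance_frac + epistasis_frac > 1 + 1e-12) {
    abort("dominance_frac + epistasis_frac > 1")
  }
  if (is.null(n_causal_add)) {
    n_causal_add <- min(100, max(2, floor(n_blocks * block_size / 2)))
  }
  check_scalar(n_causal_add, "n_causal_add", 0, n_blocks * block_size,
               integerish = TRUE)
  check_scalar(n_causal_pairs, "n_causal_pairs", 0, integerish = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  structure(list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    offspring_per_generation = as.integer(offspring_per_generation),
    n_blocks = as.integer(n_blocks),
    block_size = as.integer(block_size),
    haplotypes_per_block = as.integer(haplotypes_per_block),
    recomb_prob = recomb_prob,
    maf_bounds = maf_bounds,
    h2_additive = h2_additive,
    dominance_frac = dominance_frac,
    epistasis_frac = epistasis_frac,
    n_causal_add = as.integer(n_causal_add),
    n_causal_pairs = as.integer(n_causal_pairs),
    epistasis_pairing = match.arg(epistasis_pairing),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Draw one founder block: haplotype alleles (H x block_size in {0,1}) and
# Dirichlet(1) haplotype frequencies, resampled until all implied MAFs fall
# inside maf_bounds.
draw_block <- function(cfg) {
  for (try in 1:1000) {
    alleles <- matrix(
      as.integer(runif(cfg$haplotypes_per_block * cfg$block_size) < 0.5),
      nrow = cfg$haplotypes_per_block
    )
    w <- stats::rexp(cfg$haplotypes_per_block)
    w <- w / sum(w)
    p <- as.numeric(crossprod(alleles, w))  # allele-1 frequency per SNP
    maf <- pmin(p, 1 - p)
    if (all(maf >= cfg$maf_bounds[1] & maf <= cfg$maf_bounds[2])) {
      return(list(alleles = alleles, w = w))
    }
  }
  abort("could not draw a founder block satisfying maf_bounds in 1000 tries")
}

# Gamete = vector of block-level haplotype pool indices copied from one
# parent; recombination only at block boundaries.
make_gamete <- function(parent_haps, recomb_prob) {
  parent_haps <- matrix(parent_haps, ncol = 2)  # blocks x 2 pool indices
  K <- nrow(parent_haps)
  chrom <- integer(K)
  chrom[1] <- sample.int(2, 1)
  if (K > 1) {
    switches <- runif(K - 1) < recomb_prob
    for (k in 2:K) chrom[k] <- if (switches[k - 1]) 3L - chrom[k - 1] else chrom[k - 1]
  }
  parent_haps[cbind(seq_len(K), chrom)]
}

#' Simulate a synthetic population with LD blocks and a quantitative trait
#'
#' Generates founder genotypes from per-block haplotype pools, drops gametes
#' through a random-mating multi-generation pedigree (recombination only
#' between blocks, so every inherited block haplotype is an exact copy of a
#' parental one), and builds a phenotype
#' `y = g_add + g_dom + g_epi + e` whose component variances match the
#' configured phenotypic fractions exactly in-sample: raw component vectors
#' are orthogonalised (residualised against the preceding components) and
#' rescaled.
#'
#' @param config a [sim_config()].
#' @param trait name of the simulated trait.
#' @return A `sim_output` list: `genotypes` ([genotype_table()]),
#'   `pedigree`, `phenotypes` (tibbles), `true_genetic_values`,
#'   `realized_h2` (broad-sense, exact in-sample), `causal_effects`
#'   (tibble), plus `haplotypes` (individual x block x 2 pool indices) and
#'   `block_pools` for Mendelian-consistency checks.
#' @export
simulate_population <- function(config = sim_config(), trait = "trait1") {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(derive_seed(cfg$seed, 1), {
    n_total <- cfg$n_founders + cfg$n_generations * cfg$offspring_per_generation
    n_snps <- cfg$n_blocks * cfg$block_size
    pools <- lapply(seq_len(cfg$n_blocks), function(k) draw_block(cfg))

    # haplotype pool indices: n_total x n_blocks x 2
    haps <- array(NA_integer_, c(n_total, cfg$n_blocks, 2))
    ids <- sprintf("ind%05d", seq_len(n_total))
    sire <- rep(NA_character_, n_total)
    dam <- rep(NA_character_, n_total)
    gen <- integer(n_total)

    for (i in seq_len(cfg$n_founders)) {
      for (k in seq_len(cfg$n_blocks)) {
        haps[i, k, ] <- sample.int(cfg$haplotypes_per_block, 2,
                                   replace = TRUE, prob = pools[[k]]$w)
      }
    }
    idx <- cfg$n_founders
    prev <- seq_len(cfg$n_founders)
    for (g in seq_len(cfg$n_generations)) {
      cur <- integer(0)
      for (o in seq_len(cfg$offspring_per_generation)) {
        idx <- idx + 1
        par <- sample(prev, 2, replace = FALSE)
        haps[idx, , 1] <- make_gamete(haps[par[1], , , drop = TRUE],
                                      cfg$recomb_prob)
        haps[idx, , 2] <- make_gamete(haps[par[2], , , drop = TRUE],
                                      cfg$recomb_prob)
        sire[idx] <- ids[par[1]]
        dam[idx] <- ids[par[2]]
        gen[idx] <- g
        cur <- c(cur, idx)
      }
      prev <- cur
    }

    # dosage matrix from pool lookups, block by block
    dos <- matrix(0L, n_total, n_snps)
    for (k in seq_len(cfg$n_blocks)) {
      cols <- ((k - 1) * cfg$block_size + 1):(k * cfg$block_size)
      A <- pools[[k]]$alleles
      dos[, cols] <- A[haps[, k, 1], , drop = FALSE] +
        A[haps[, k, 2], , drop = FALSE]
    }

    snps <- tibble::tibble(
      snp_id = sprintf("b%03d_s%02d", rep(seq_len(cfg$n_blocks),
                                          each = cfg$block_size),
                       rep(seq_len(cfg$block_size), cfg$n_blocks)),
      chrom = "1",
      pos = seq_len(n_snps) * 1000L
    )
    gt <- genotype_table(dos, sample_ids = ids, snps = snps)

    # ---- trait architecture ----------------------------------------------
    Xc <- scale(dos, center = TRUE, scale = FALSE)
    causal_add <- if (cfg$n_causal_add > 0) {
      sort(sample.int(n_snps, cfg$n_causal_add))
    } else integer(0)

    raw_add <- raw_dom <- raw_epi <- rep(0, n_total)
    add_eff <- dom_eff <- numeric(0)
    pair_tbl <- NULL

    if (cfg$h2_additive > 0) {
      if (!length(causal_add)) abort("h2_additive > 0 needs n_causal_add > 0")
      add_eff <- rnorm(length(causal_add))
      raw_add <- as.numeric(Xc[, causal_add, drop = FALSE] %*% add_eff)
    }
    # project a raw component off the additive span of a set of loci, so
    # the non-additive variance components are orthogonal to anything a
    # linear model on dosages could tag through those loci
    ortho_to_additive <- function(v, loci, fallback) {
      loci <- unique(loci)
      # keep the projection well-posed when the locus set approaches the
      # sample size
      if (length(loci) > 0.5 * n_total) loci <- unique(fallback)
      qr.resid(qr(cbind(1, Xc[, loci, drop = FALSE])), v)
    }
    block_of <- function(idx) (idx - 1L) %/% cfg$block_size + 1L
    block_members <- function(idx) {
      blocks <- unique(block_of(idx))
      as.integer(outer(seq_len(cfg$block_size),
                       (blocks - 1L) * cfg$block_size, `+`))
    }

    if (cfg$dominance_frac > 0) {
      if (!length(causal_add)) abort("dominance_frac > 0 needs n_causal_add > 0")
      H <- scale((dos[, causal_add, drop = FALSE] == 1L) * 1,
                 center = TRUE, scale = FALSE)
      dom_eff <- rnorm(length(causal_add))
      raw_dom <- ortho_to_additive(as.numeric(H %*% dom_eff),
                                   block_members(causal_add), causal_add)
    }
    if (cfg$epistasis_frac > 0) {
      if (cfg$n_causal_pairs < 1) abort("epistasis_frac > 0 needs n_causal_pairs > 0")
      pairs <- matrix(NA_integer_, cfg$n_causal_pairs, 2)
      if (cfg$epistasis_pairing == "within_block" && cfg$block_size >= 2) {
        blocks <- sample.int(cfg$n_blocks, cfg$n_causal_pairs, replace = TRUE)
        for (p in seq_len(cfg$n_causal_pairs)) {
          within <- sample.int(cfg$block_size, 2, replace = FALSE)
          pairs[p, ] <- (blocks[p] - 1L) * cfg$block_size + sort(within)
        }
      } else {
        for (p in seq_len(cfg$n_causal_pairs)) {
          pairs[p, ] <- sort(sample.int(n_snps, 2, replace = FALSE))
        }
      }
      epi_eff <- rnorm(cfg$n_causal_pairs)
      terms <- Xc[, pairs[, 1], drop = FALSE] * Xc[, pairs[, 2], drop = FALSE]
      terms <- scale(terms, center = TRUE, scale = FALSE)
      raw_epi <- ortho_to_additive(as.numeric(terms %*% epi_eff),
                                   block_members(as.integer(pairs)),
                                   as.integer(pairs))
      pair_tbl <- tibble::tibble(
        component = "epistasis",
        snp_a = snps$snp_id[pairs[, 1]],
        snp_b = snps$snp_id[pairs[, 2]],
        effect = epi_eff
      )
    }

    # Orthogonalise and rescale so in-sample variance fractions are exact.
    scale_to <- function(v, target_var) {
      if (target_var <= 0) return(rep(0, length(v)))
      s <- stats::var(v)
      if (s < 1e-300) abort("degenerate component: zero raw variance with positive target")
      v * sqrt(target_var / s)
    }
    residualise <- function(v, basis) {
      v <- v - mean(v)
      for (b in basis) {
        if (any(b != 0)) v <- v - b * sum(v * b) / sum(b * b)
      }
      v
    }
    g_add <- scale_to(residualise(raw_add, list()), cfg$h2_additive)
    g_dom <- scale_to(residualise(raw_dom, list(g_add)), cfg$dominance_frac)
    g_epi <- scale_to(residualise(raw_epi, list(g_add, g_dom)),
                      cfg$epistasis_frac)
    e_frac <- 1 - cfg$h2_additive - cfg$dominance_frac - cfg$epistasis_frac
    e <- scale_to(residualise(rnorm(n_total), list(g_add, g_dom, g_epi)),
                  e_frac)
    g_total <- g_add + g_dom + g_epi
    y <- g_total + e
    vy <- stats::var(y)
    realized_h2 <- if (vy > 0) stats::var(g_total) / vy else 0

    eff <- tibble::tibble(
      component = character(0), snp_a = character(0),
      snp_b = character(0), effect = numeric(0)
    )
    if (length(add_eff)) {
      eff <- dplyr::bind_rows(eff, tibble::tibble(
        component = "additive", snp_a = snps$snp_id[causal_add],
        snp_b = NA_character_, effect = add_eff))
    }
    if (length(dom_eff)) {
      eff <- dplyr::bind_rows(eff, tibble::tibble(
        component = "dominance", snp_a = snps$snp_id[causal_add],
        snp_b = NA_character_, effect = dom_eff))
    }
    if (!is.null(pair_tbl)) eff <- dplyr::bind_rows(eff, pair_tbl)

    structure(list(
      genotypes = gt,
      pedigree = tibble::tibble(id = ids, sire = sire, dam = dam,
                                generation = gen),
      phenotypes = tibble::tibble(id = ids, trait = trait, value = y),
      true_genetic_values = stats::setNames(g_total, ids),
      realized_h2 = realized_h2,
      components = tibble::tibble(id = ids, additive = g_add,
                                  dominance = g_dom, epistasis = g_epi,
                                  environment = e),
      causal_effects = eff,
      haplotypes = haps,
      block_pools = pools,
      config = cfg
    ), class = "sim_output")
  })
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf(
    "<sim_output> %d individuals (%d founders + %d generations), %d SNPs; realized H2 = %.3f\n",
    nrow(x$genotypes$dosages), x$config$n_founders, x$config$n_generations,
    ncol(x$genotypes$dosages), x$realized_h2))
  invisible(x)
}

#' Inject missing calls into a genotype table
#'
#' Test-fixture generator: entries are set to `NA` independently with the
#' given rates, deterministically for a given seed.  `snp_rate` applies to
#' the selected SNP columns, `ind_rate` additionally to the selected
#' individuals' rows.
#'
#' @param genotypes a [genotype_table()].
#' @param snp_rate per-entry missingness probability over `snps` columns.
#' @param ind_rate per-entry missingness probability over `individuals`
#'   rows.
#' @param seed integer seed.
#' @param snps SNP ids (or column indices) the `snp_rate` applies to;
#'   default all.
#' @param individuals sample ids (or row indices) the `ind_rate` applies
#'   to; default all.
#' @return A [genotype_table()] copy with missing entries.
#' @export
inject_missingness <- function(genotypes, snp_rate = 0, ind_rate = 0,
                               seed = 1, snps = NULL, individuals = NULL) {
  stopifnot(inherits(genotypes, "genotype_table"))
  check_scalar(snp_rate, "snp_rate", 0, 1, closed_upper = FALSE)
  check_scalar(ind_rate, "ind_rate", 0, 1, closed_upper = FALSE)
  d <- genotypes$dosages
  with_seed(derive_seed(seed, 2), {
    if (snp_rate > 0) {
      cols <- if (is.null(snps)) seq_len(ncol(d)) else {
        if (is.character(snps)) match(snps, colnames(d)) else snps
      }
      sub <- matrix(runif(nrow(d) * length(cols)) < snp_rate,
                    nrow(d), length(cols))
      d[, cols][sub] <- NA_integer_
    }
    if (ind_rate > 0) {
      rows <- if (is.null(individuals)) seq_len(nrow(d)) else {
        if (is.character(individuals)) match(individuals, rownames(d)) else individuals
      }
      sub <- matrix(runif(length(rows) * ncol(d)) < ind_rate,
                    length(rows), ncol(d))
      d[rows, ][sub] <- NA_integer_
    }
  })
  genotypes$dosages <- d
  genotypes
}
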