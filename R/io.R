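#' Construct a genotype table
#'
#' The central genotype container: an individuals-by-SNPs matrix of allele
#' dosages in \{0, 1, 2\} with `NA` marking missing calls, plus a marker map
#' (SNP id, chromosome, 1-based position).  SNP columns are stored sorted by
#' `(chrom, pos)`.
#'
#' @param dosages integer matrix, individuals in rows, SNPs in columns;
#'   values 0/1/2 or `NA`.  Row names (if present) become sample ids.
#' @param sample_ids character vector of unique sample ids.
#' @param snps a data frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based).  Defaults to a single pseudo-chromosome with unit spacing.
#' @return An object of class `genotype_table`: a list with elements
#'   `dosages` (integer matrix with dimnames) and `snps` (tibble).
#' @export
genotype_table <- function(dosages,
                           sample_ids = rownames(dosages),
                           snps = NULL) {
  if (!is.matrix(dosages)) abort("`dosages` must be a matrix")
  storage.mode(dosages) <- "integer"
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(sample_ids)) sample_ids <- sprintf("ind%04d", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) abort("`sample_ids` length must match nrow(dosages)")
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids")
  if (is.null(snps)) {
    ids <- colnames(dosages) %||% sprintf("snp%05d", seq_len(m))
    snps <- tibble::tibble(snp_id = ids, chrom = "1", pos = seq_len(m))
  }
  snps <- tibble::as_tibble(snps)
  if (!all(c("snp_id", "chrom", "pos") %in% names(snps))) {
    abort("`snps` needs columns snp_id, chrom, pos")
  }
  if (nrow(snps) != m) abort("`snps` must have one row per dosage column")
  if (anyDuplicated(snps$snp_id)) abort("duplicate SNP ids")
  if (any(snps$pos < 1, na.rm = TRUE)) abort("positions must be >= 1 (1-based)")
  bad <- dosages[!is.na(dosages) & !(dosages %in% 0:2)]
  if (length(bad)) {
    abort(sprintf("dosages outside {0,1,2}: e.g. %s", bad[1]))
  }
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  dimnames(dosages) <- list(sample_ids, snps$snp_id)
  structure(list(dosages = dosages, snps = snps), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosages)

n_samples <- function(x) nrow(x$dosages)
n_snps <- function(x) ncol(x$dosages)

#' Read a diploid VCF into a genotype table
#'
#' Reads GT fields of a VCF 4.x file (optionally gzip-compressed) and maps
#' genotypes `0/0`, `0/1`, `1/1`, `./.` to alternate-allele counts
#' 0, 1, 2, `NA`; phased separators (`|`) are accepted.  Multi-allelic
#' records are skipped with a warning.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @return A [genotype_table()] of alt-allele dosages (see
#'   [recode_to_minor()] for minor-allele coding).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  rlang::check_installed("vcfR")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) abort(sprintf("no records in VCF %s", path))
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warn(sprintf("skipping %d multi-allelic record(s) in %s",
                 sum(multi), path))
  }
  keep <- !multi
  if (!any(keep)) abort("all records multi-allelic; nothing to read")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  core <- substr(gsub("\\|", "/", gt), 1, 3)
  dos <- matrix(NA_integer_, nrow(core), ncol(core))
  dos[core == "0/0"] <- 0L
  dos[core == "0/1" | core == "1/0"] <- 1L
  dos[core == "1/1"] <- 2L
  unparsed <- !is.na(core) & is.na(dos) & core != "./."
  if (any(unparsed)) {
    i <- which(unparsed, arr.ind = TRUE)[1, ]
    abort(sprintf("malformed GT '%s' at record %d (%s)",
                  core[i[1], i[2]], i[1], fix$ID[i[1]]))
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  genotype_table(
    t(dos),
    sample_ids = colnames(gt),
    snps = tibble::tibble(snp_id = ids, chrom = fix$CHROM,
                          pos = as.integer(fix$POS))
  )
}

#' Write a genotype table as a minimal GT-only VCF
#'
#' @param table a [genotype_table()] (dosages interpreted as alt-allele
#'   counts).
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(table$dosages)), collapse = "\t")
  ), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  d <- table$dosages
  for (j in seq_len(ncol(d))) {
    g <- d[, j]
    gt <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
    writeLines(paste(c(table$snps$chrom[j], table$snps$pos[j],
                       table$snps$snp_id[j], "A", "B", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Recode dosages so that 2 counts minor-allele homozygotes
#'
#' For each SNP, if the sample frequency of the counted allele exceeds 0.5
#' the coding is complemented (`d -> 2 - d`, missing preserved), so 0/1/2
#' always mean major-homozygote / heterozygote / minor-homozygote.  Exact
#' ties (frequency 0.5) leave the coding unchanged; the operation is an
#' involution on SNPs with frequency different from 0.5.
#'
#' @param table a [genotype_table()].
#' @return A [genotype_table()] with the same dimensions.
#' @export
recode_to_minor <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  d <- table$dosages
  freq <- colMeans(d, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) d[, flip] <- 2L - d[, flip]
  table$dosages <- d
  table
}

#' Read and write dosage matrices as TSV
#'
#' Plain-text interchange: a header row of SNP ids, first column `id`, one
#' row per individual, dosages 0/1/2 with `NA` for missing.  The round trip
#' `read_dosage_tsv(write_dosage_tsv(t))` is lossless up to SNP coordinates
#' (TSV carries no marker map; positions default to column order).
#'
#' @param path file path (gzip accepted on read when suffixed `.gz`).
#' @param table a [genotype_table()].
#' @param snps optional marker map to attach on read (as in
#'   [genotype_table()]).
#' @return `read_dosage_tsv()` a [genotype_table()];
#'   `write_dosage_tsv()` the path, invisibly.
#' @export
read_dosage_tsv <- function(path, snps = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2) abort("dosage TSV needs a header and at least one row")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1) {
    abort(sprintf("ragged dosage TSV: line %d has %d fields, expected %d",
                  which(widths != widths[1])[1], widths[widths != widths[1]][1],
                  widths[1]))
  }
  header <- parts[[1]]
  if (header[1] != "id") abort("first header field must be 'id'")
  snp_ids <- header[-1]
  body <- parts[-1]
  ids <- vapply(body, `[`, "", 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate sample id '%s'", ids[duplicated(ids)][1]))
  }
  vals <- vapply(body, function(r) suppressWarnings(as.integer(r[-1])),
                 integer(length(snp_ids)))
  m <- matrix(t(vals), nrow = length(ids), ncol = length(snp_ids))
  raw <- vapply(body, function(r) r[-1], character(length(snp_ids)))
  bad <- is.na(m) & !(t(raw) %in% c("NA", "."))
  if (any(bad)) abort("non-numeric dosage entries")
  genotype_table(m, sample_ids = ids,
                 snps = snps %||% tibble::tibble(
                   snp_id = snp_ids, chrom = "1",
                   pos = seq_along(snp_ids)))
}

#' @rdname read_dosage_tsv
#' @export
write_dosage_tsv <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  d <- table$dosages
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", colnames(d)), collapse = "\t"), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(rownames(d)[i], ifelse(is.na(d[i, ]), "NA", d[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a pedigree table
#'
#' Expects a TSV with header `id`, `sire`, `dam` and optionally
#' `generation`; unknown parents are `NA`, `0` or `.`.  The pedigree is
#' checked for acyclicity (no individual is its own ancestor).
#'
#' @param path file path.
#' @return A tibble with columns `id`, `sire`, `dam` (character, `NA` for
#'   unknown) and `generation` if present.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.delim(path, colClasses = "character")
  if (!all(c("id", "sire", "dam") %in% names(ped))) {
    abort("pedigree needs columns id, sire, dam")
  }
  ped <- tibble::as_tibble(ped)
  for (col in c("sire", "dam")) {
    ped[[col]][ped[[col]] %in% c("", "0", ".", "NA")] <- NA_character_
  }
  if ("generation" %in% names(ped)) {
    ped$generation <- as.integer(ped$generation)
  }
  if (anyDuplicated(ped$id)) abort("duplicate individual ids in pedigree")
  generation_order(ped)   # raises on cycles
  ped
}

#' Read a long-format phenotype table
#'
#' Expects a TSV with header `id`, `trait`, `value`; `(id, trait)` pairs
#' must be unique.
#'
#' @param path file path.
#' @return A tibble with columns `id` (character), `trait` (character),
#'   `value` (numeric).
#' @export
read_phenotypes <- function(path) {
  ph <- tibble::as_tibble(utils::read.delim(path, colClasses = "character"))
  if (!all(c("id", "trait", "value") %in% names(ph))) {
    abort("phenotype file needs columns id, trait, value")
  }
  ph$value <- as.numeric(ph$value)
  dup <- duplicated(ph[, c("id", "trait")])
  if (any(dup)) {
    abort(sprintf("duplicated (id, trait) pair: (%s, %s)",
                  ph$id[dup][1], ph$trait[dup][1]))
  }
  ph
}

#' @rdname read_pedigree
#' @param pedigree a pedigree tibble.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.table(pedigree, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname read_phenotypes
#' @param phenotypes a phenotype tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
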