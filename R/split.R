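#' Order individuals by pedigree generation
#'
#' Generation index: 0 for founders (no known parent in the table), else
#' `1 + max(parents' indices)`.  The returned ordering is by
#' `(generation, id)` with a stable id tie-break; a cyclic pedigree raises
#' an error.
#'
#' @param pedigree tibble with columns `id`, `sire`, `dam` (`NA` for
#'   unknown parents).
#' @return A tibble with columns `id`, `generation`, sorted in the order
#'   used for forward splitting.
#' @export
generation_order <- function(pedigree) {
  ped <- tibble::as_tibble(pedigree)
  if (!all(c("id", "sire", "dam") %in% names(ped))) {
    abort("pedigree needs columns id, sire, dam")
  }
  ids <- as.character(ped$id)
  if (anyDuplicated(ids)) abort("duplicate ids in pedigree")
  sire <- match(as.character(ped$sire), ids)
  dam <- match(as.character(ped$dam), ids)
  n <- length(ids)
  gen <- rep(NA_integer_, n)
  known <- !is.na(ped$sire) & is.na(sire) | !is.na(ped$dam) & is.na(dam)
  # parents absent from the table count as unknown
  remaining <- n
  repeat {
    assignable <- which(is.na(gen))
    progressed <- FALSE
    for (i in assignable) {
      ps <- c(sire[i], dam[i])
      ps <- ps[!is.na(ps)]
      if (!length(ps)) {
        gen[i] <- 0L
        progressed <- TRUE
      } else if (!anyNA(gen[ps])) {
        gen[i] <- 1L + max(gen[ps])
        progressed <- TRUE
      }
    }
    if (all(!is.na(gen))) break
    if (!progressed) {
      abort("pedigree contains a cycle (an individual is its own ancestor)")
    }
  }
  out <- tibble::tibble(id = ids, generation = gen)
  out[order(out$generation, out$id), ]
}

#' Forward-validation split specification
#'
#' @param fractions train/validation/test fractions; must sum to 1.
#' @param keep_full_sibs_together snap partition boundaries forward so no
#'   full-sib family (same sire and dam, both known) straddles a boundary.
#' @return A `split_spec` list.
#' @export
split_spec <- function(fractions = c(train = 0.8, validation = 0.1,
                                     test = 0.1),
                       keep_full_sibs_together = TRUE) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-9) {
    abort("fractions must be three numbers summing to 1")
  }
  structure(list(fractions = fractions,
                 keep_full_sibs_together = keep_full_sibs_together),
            class = "split_spec")
}

#' Pedigree-based forward-validation split
#'
#' Orders phenotyped individuals by generation (oldest first) and cuts at
#' the 80% and 90% quantile indices: the oldest fraction trains, the next
#' validates, the youngest tests, so no information from descendants is
#' used for training.  When `keep_full_sibs_together` is set, any full-sib
#' family straddling a boundary is moved entirely into the later
#' partition, so counts deviate from the exact fractions by at most a
#' family.  Splitting is deterministic.
#'
#' @param pedigree tibble with `id`, `sire`, `dam`.
#' @param ids character vector of phenotyped ids to split (must appear in
#'   the pedigree).
#' @param spec a [split_spec()].
#' @return A `data_split` list with character vectors `train`,
#'   `validation`, `test` and the `generation` tibble.
#' @export
forward_split <- function(pedigree, ids = pedigree$id,
                          spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  ids <- as.character(ids)
  ord <- generation_order(pedigree)
  if (!all(ids %in% ord$id)) abort("phenotyped ids missing from pedigree")
  ord <- ord[ord$id %in% ids, ]
  n <- nrow(ord)
  if (n < 10) abort("need at least 10 individuals for an 80/10/10 split")
  cut1 <- floor(spec$fractions[1] * n)
  cut2 <- floor(sum(spec$fractions[1:2]) * n)
  part <- rep(3L, n)
  part[seq_len(cut2)] <- 2L
  part[seq_len(cut1)] <- 1L
  if (spec$keep_full_sibs_together) {
    ped <- tibble::as_tibble(pedigree)
    key <- ifelse(is.na(ped$sire) | is.na(ped$dam),
                  paste0("solo:", ped$id),
                  paste0(ped$sire, "x", ped$dam))
    fam <- key[match(ord$id, ped$id)]
    latest <- tapply(part, fam, max)
    part <- as.integer(latest[fam])
  }
  structure(list(train = ord$id[part == 1L],
                 validation = ord$id[part == 2L],
                 test = ord$id[part == 3L],
                 generation = ord),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> train %d / validation %d / test %d\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Write and read a data split as JSON
#'
#' @param split a `data_split`.
#' @param path JSON file path.
#' @return `write_split()` the path invisibly; `read_split()` a
#'   `data_split`.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(split[c("train", "validation", "test")], path)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train = as.character(s$train),
                 validation = as.character(s$validation),
                 test = as.character(s$test), generation = NULL),
            class = "data_split")
}

#' Prediction accuracy metrics
#'
#' Headline metric is the coefficient of determination
#' `R2 = 1 - SSE / SST` (the proportion of phenotypic variance predicted;
#' can be negative for predictions worse than the mean); the squared
#' Pearson correlation is reported secondarily, along with the mean
#' squared error.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2);
#'   `var(y_true)` must be positive.
#' @return A one-row tibble with `r2`, `r2_pearson`, `mse`, `n`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) abort("length mismatch")
  if (length(y_true) < 2) abort("need at least 2 observations")
  if (anyNA(y_true) || anyNA(y_pred)) abort("missing values in metrics input")
  sst <- sum((y_true - mean(y_true))^2)
  if (sst <= 0) abort("zero variance in y_true; R2 undefined")
  sse <- sum((y_true - y_pred)^2)
  r2p <- if (sd(y_pred) > 0) cor(y_true, y_pred)^2 else 0
  tibble::tibble(r2 = 1 - sse / sst, r2_pearson = r2p,
                 mse = mean((y_true - y_pred)^2),
                 n = length(y_true))
}
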