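# Exhaustive k-locus interaction scanning and max-statistic permutation
# inference. The per-combination tabulation runs in C++ (scan_core.cpp); the
# R-level build_contingency_table()/compute_gids() pair is the reference path
# it is tested against.

encode_classes <- function(classes) {
  labels <- sort(unique(classes))
  if (length(labels) < 2L) stop("phenotype must have at least two classes")
  list(y = match(classes, labels) - 1L, labels = labels, J = length(labels))
}

# n x C(p,k) matrix of mixed-radix genotype cell indices, one column per
# combination; NA where a sample misses a genotype in that combination.
combination_cells <- function(genotypes, combos) {
  k <- nrow(combos)
  n <- nrow(genotypes)
  cells <- matrix(0L, n, ncol(combos))
  for (m in seq_len(k)) {
    cells <- cells * 3L + genotypes[, combos[m, ], drop = FALSE]
  }
  storage.mode(cells) <- "integer"
  cells
}

#' Exhaustively score all k-SNP combinations
#'
#' Builds the `3^k x J` contingency table for every one of the `C(p, k)` SNP
#' combinations and scores it with GIDS (or the Pearson chi-squared baseline).
#' A larger score means a stronger genomic association; results are returned
#' sorted by score, ties broken by the lexicographically smallest SNP tuple.
#'
#' @param genotypes n x p matrix of minor-allele counts in `{0, 1, 2}`
#'   (`NA` = missing; samples are excluded per combination).
#' @param classes length-n phenotype class vector (`J >= 2` distinct labels).
#' @param k interaction order (number of loci per combination).
#' @param statistic `"gids"` (default) or `"chisq"`.
#' @return A data frame of class `gids_scan` with columns `snp1..snpk`
#'   (column indices into `genotypes`), the score column (`gids` or `chisq`),
#'   and `rank`; attributes `k`, `statistic`, `snp_names`.
#' @export
#' @examples
#' g <- simulate_genotypes(100, 4, maf = 0.5, seed = 1)
#' cls <- ifelse(g[, 1] + g[, 2] >= 2, 2, 1)
#' scan_order(g, cls, k = 2)
scan_order <- function(genotypes, classes, k,
                       statistic = c("gids", "chisq")) {
  statistic <- match.arg(statistic)
  genotypes <- as.matrix(genotypes)
  p <- ncol(genotypes)
  if (k < 1L || k > p) stop("'k' must be between 1 and the number of SNPs")
  if (length(classes) != nrow(genotypes)) {
    stop("'classes' must have one entry per sample")
  }
  check_genotype_codes(genotypes)
  enc <- encode_classes(classes)
  combos <- combn(p, k)
  cells <- combination_cells(genotypes, combos)
  values <- scan_statistic_cpp(cells, enc$y, 3L^k, enc$J,
                               if (statistic == "gids") 0L else 1L)
  res <- as.data.frame(t(combos))
  names(res) <- paste0("snp", seq_len(k))
  res[[statistic]] <- values
  ord <- do.call(order, c(list(-values), res[seq_len(k)]))
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  structure(res, k = k, statistic = statistic,
            snp_names = colnames(genotypes),
            class = c("gids_scan", "data.frame"))
}

#' Max-statistic permutation null distribution for one interaction order
#'
#' Repeatedly permutes the phenotype vector against the fixed genotype rows
#' (breaking all genotype-phenotype linkage while preserving the genotype
#' correlation structure), rescans all `C(p, k)` combinations, and records
#' the maximum score of each permuted dataset. The collection of maxima is
#' the null distribution used for multiplicity-adjusted p-values.
#'
#' @inheritParams scan_order
#' @param B number of permutations.
#' @param seed optional integer seed; permutations are drawn from R's RNG
#'   stream (current stream when `seed` is `NULL`).
#' @return Object of class `gids_null`: list with `values` (length `B`), `B`,
#'   `k`, `statistic`, `seed`.
#' @export
permutation_null <- function(genotypes, classes, k, B,
                             seed = NULL, statistic = c("gids", "chisq")) {
  statistic <- match.arg(statistic)
  if (B < 1L) stop("'B' must be at least 1")
  genotypes <- as.matrix(genotypes)
  check_genotype_codes(genotypes)
  enc <- encode_classes(classes)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  combos <- combn(ncol(genotypes), k)
  cells <- combination_cells(genotypes, combos)
  perms <- vapply(seq_len(B), function(b) sample.int(n) - 1L, integer(n))
  values <- permutation_max_cpp(cells, enc$y, perms, 3L^k, enc$J,
                                if (statistic == "gids") 0L else 1L)
  structure(list(values = values, B = B, k = k, statistic = statistic,
                 seed = seed),
            class = "gids_null")
}

#' Permutation p-value against a max-statistic null
#'
#' `p = (1 + #\{b : null_b >= observed\}) / (B + 1)`: the add-one rule, which
#' is a valid p-value (never exactly zero) and counts ties against the
#' observed statistic.
#'
#' @param observed observed statistic (vectorized).
#' @param null a `gids_null` from [permutation_null()], or a numeric vector
#'   of null maxima.
#' @return p-value(s) in `(0, 1]`.
#' @export
permutation_pvalue <- function(observed, null) {
  values <- if (inherits(null, "gids_null")) null$values else as.numeric(null)
  if (length(values) == 0L) stop("empty null distribution")
  vapply(observed,
         function(o) (1 + sum(values >= o)) / (length(values) + 1),
         numeric(1))
}

#' Select the best interaction model across orders
#'
#' For each requested order `k`, scans all combinations, takes the top-ranked
#' one, and assigns it a p-value against that order's own max-statistic
#' permutation null (nulls are never shared across orders, since the maximum
#' over `C(p, k)` combinations depends on `k`). The overall best model is the
#' one with the smallest p-value; ties are broken by the smaller order, then
#' the larger score.
#'
#' @inheritParams permutation_null
#' @param orders vector of interaction orders to compare, e.g. `1:3`.
#' @return Object of class `gids_best_model`: list with `per_order` (data
#'   frame: `order`, `snps`, score, `p_value`) and `best` (one row of it).
#' @export
select_best_model <- function(genotypes, classes, orders, B,
                              seed = NULL, statistic = c("gids", "chisq")) {
  statistic <- match.arg(statistic)
  if (length(orders) == 0L) stop("'orders' must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  null_seeds <- sample.int(.Machine$integer.max, length(orders))
  rows <- lapply(seq_along(orders), function(m) {
    k <- orders[m]
    scan <- scan_order(genotypes, classes, k, statistic)
    top <- scan[1L, ]
    null <- permutation_null(genotypes, classes, k, B,
                             seed = null_seeds[m], statistic = statistic)
    data.frame(order = k,
               snps = paste(unlist(top[seq_len(k)]), collapse = ","),
               value = top[[statistic]],
               p_value = permutation_pvalue(top[[statistic]], null))
  })
  per_order <- do.call(rbind, rows)
  names(per_order)[names(per_order) == "value"] <- statistic
  ord <- order(per_order$p_value, per_order$order, -per_order[[statistic]])
  best <- per_order[ord[1L], ]
  rownames(best) <- NULL
  structure(list(per_order = per_order, best = best, statistic = statistic),
            class = "gids_best_model")
}

#' @export
print.gids_best_model <- function(x, ...) {
  cat("Best interaction model across orders (", x$statistic, "):\n", sep = "")
  print(x$per_order, row.names = FALSE)
  cat(sprintf("best: order %d, SNPs (%s), %s = %.4f, p = %.4g\n",
              x$best$order, x$best$snps, x$statistic,
              x$best[[x$statistic]], x$best$p_value))
  invisible(x)
}
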