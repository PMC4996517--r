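#' Genotype-by-phenotype contingency table
#'
#' Light container for an I x J count matrix `n_ij` of multi-locus genotype
#' classes (rows) by phenotype outcome classes (columns), the basic object all
#' association measures in this package operate on.
#'
#' @param counts non-negative numeric matrix of counts with at least two
#'   columns and a positive total.
#' @param row_labels,col_labels optional dimension labels; default to the
#'   dimnames of `counts` or generated labels.
#' @param n_excluded number of samples dropped (e.g. for missing genotypes)
#'   while building the table; stored as an attribute for reporting.
#'
#' @return An object of class `gids_table`: the count matrix with attributes
#'   `n` (grand total) and `n_excluded`.
#' @seealso [build_contingency_table()], [compute_gids()]
#' @export
#' @examples
#' tab <- gids_table(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
#' compute_gids(tab)
gids_table <- function(counts, row_labels = NULL, col_labels = NULL,
                       n_excluded = 0L) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("'counts' must be a numeric matrix")
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("'counts' must be finite and non-missing")
  }
  if (any(counts < 0)) {
    stop("'counts' must be non-negative")
  }
  if (ncol(counts) < 2L) {
    stop("a contingency table needs at least two phenotype classes (columns)")
  }
  if (sum(counts) <= 0) {
    stop("table total must be positive")
  }
  if (is.null(row_labels)) {
    row_labels <- rownames(counts)
  }
  if (is.null(col_labels)) {
    col_labels <- colnames(counts)
  }
  if (is.null(row_labels)) row_labels <- paste0("g", seq_len(nrow(counts)))
  if (is.null(col_labels)) col_labels <- paste0("class", seq_len(ncol(counts)))
  dimnames(counts) <- list(row_labels, col_labels)
  structure(counts,
            n = sum(counts),
            n_excluded = as.integer(n_excluded),
            class = c("gids_table", "matrix", "array"))
}

as_gids_table <- function(x) {
  if (inherits(x, "gids_table")) x else gids_table(x)
}

#' @export
print.gids_table <- function(x, ...) {
  cat(sprintf("%d x %d genotype-by-phenotype table (n = %d",
              nrow(x), ncol(x), as.integer(attr(x, "n"))))
  excl <- attr(x, "n_excluded")
  if (!is.null(excl) && excl > 0L) cat(sprintf(", %d excluded", excl))
  cat(")\n")
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Expected counts under row/column independence
#'
#' @param table a [gids_table()] or plain count matrix.
#' @return Matrix of `E_ij = n_i. * n_.j / n`, same shape as the input.
#' @export
expected_counts <- function(table) {
  m <- as_gids_table(table)
  outer(rowSums(m), colSums(m)) / sum(m)
}

#' Tabulate a SNP combination against the phenotype classes
#'
#' Builds the `3^k x J` contingency table for one ordered combination of `k`
#' SNPs under additive minor-allele coding. A sample with genotype vector
#' `(g_1, ..., g_k)` is assigned to row `sum(g_m * 3^(k - m)) + 1`
#' (mixed-radix, first SNP most significant); columns follow the sorted order
#' of the distinct phenotype class labels. Samples with a missing genotype at
#' any of the chosen SNPs are excluded listwise; the excluded count is kept in
#' the `n_excluded` attribute of the result.
#'
#' @param genotypes n x p matrix of minor-allele counts in `{0, 1, 2}`
#'   (`NA` = missing).
#' @param combination ordered vector of SNP column indices (length `k >= 1`).
#' @param classes length-n phenotype class vector with at least two distinct
#'   labels (any atomic type; labels are sorted to fix column order).
#' @return A [gids_table()] with `3^k` rows.
#' @export
#' @examples
#' g <- cbind(c(0, 0, 2, 2), c(0, 0, 2, 2))
#' build_contingency_table(g, c(1, 2), c(1, 1, 2, 2))
build_contingency_table <- function(genotypes, combination, classes) {
  genotypes <- as.matrix(genotypes)
  k <- length(combination)
  if (k < 1L) stop("'combination' must contain at least one SNP index")
  if (any(combination < 1L) || any(combination > ncol(genotypes))) {
    stop("SNP index out of range")
  }
  if (length(classes) != nrow(genotypes)) {
    stop("'classes' must have one entry per sample")
  }
  if (anyNA(classes)) stop("missing phenotype class labels are not allowed")
  g <- genotypes[, combination, drop = FALSE]
  check_genotype_codes(g)
  keep <- !apply(is.na(g), 1L, any)
  if (!any(keep)) stop("all samples excluded for missing genotypes")
  g <- g[keep, , drop = FALSE]
  cls <- classes[keep]
  labels <- sort(unique(classes))
  if (length(labels) < 2L) stop("phenotype must have at least two classes")
  cell <- as.vector(g %*% 3^((k - 1):0))
  counts <- table(factor(cell, levels = 0:(3^k - 1)),
                  factor(cls, levels = labels))
  counts <- matrix(as.numeric(counts), nrow = 3^k,
                   dimnames = list(genotype_row_labels(k), as.character(labels)))
  gids_table(counts, n_excluded = sum(!keep))
}

genotype_row_labels <- function(k) {
  digits <- expand.grid(rep(list(0:2), k))[, k:1, drop = FALSE]
  apply(digits, 1L, paste, collapse = "")
}

check_genotype_codes <- function(g) {
  bad <- !(g %in% c(0, 1, 2)) & !is.na(g)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype code %s at sample %d, SNP column %d (expected 0/1/2/NA)",
                 format(g[idx[1L], idx[2L]]), idx[1L], idx[2L]))
  }
  invisible(TRUE)
}
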