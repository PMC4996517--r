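# Dataset container and delimited-text / PLINK .raw readers and writers.

#' Genotype + phenotype dataset container
#'
#' @param genotypes n x p matrix of minor-allele counts in `{0, 1, 2}`
#'   (`NA` = missing).
#' @param phenotype length-n class vector or quantitative trait.
#' @param sample_ids,snp_ids optional identifiers; SNP ids must be unique.
#' @return List of class `gids_dataset`.
#' @export
gids_dataset <- function(genotypes, phenotype, sample_ids = NULL,
                         snp_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  check_genotype_codes(genotypes)
  n <- nrow(genotypes)
  if (length(phenotype) != n) {
    stop("'phenotype' must have one entry per genotype row")
  }
  if (is.null(snp_ids)) {
    snp_ids <- colnames(genotypes)
    if (is.null(snp_ids)) snp_ids <- paste0("SNP", seq_len(ncol(genotypes)))
  }
  if (anyDuplicated(snp_ids)) stop("SNP ids must be unique")
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  if (length(sample_ids) != n) stop("'sample_ids' must have one entry per sample")
  colnames(genotypes) <- snp_ids
  structure(list(genotypes = genotypes, phenotype = phenotype,
                 sample_ids = sample_ids, snp_ids = snp_ids),
            class = "gids_dataset")
}

#' @export
print.gids_dataset <- function(x, ...) {
  cat(sprintf("gids_dataset: %d samples x %d SNPs, phenotype: %s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              if (is.numeric(x$phenotype) &&
                  any(x$phenotype != round(x$phenotype))) "quantitative"
              else paste0(length(unique(x$phenotype)), " classes")))
  invisible(x)
}

#' Write a dataset as delimited text
#'
#' One row per sample: the SNP columns (coded 0/1/2, `NA` for missing)
#' followed by a `phenotype` column. Tab-separated for `.tsv`/`.txt`,
#' comma-separated for `.csv`.
#'
#' @param dataset a [gids_dataset()].
#' @param path output file.
#' @export
write_dataset <- function(dataset, path) {
  if (!inherits(dataset, "gids_dataset")) stop("not a gids_dataset")
  df <- as.data.frame(dataset$genotypes)
  df$phenotype <- dataset$phenotype
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dataset from delimited text or PLINK .raw
#'
#' The delimited format is one header row then one row per sample, SNP
#' columns coded 0/1/2 (`NA` = missing) plus a phenotype column. The PLINK
#' `.raw` additive dialect has the six fixed fields
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP; the
#' phenotype is taken from `PHENOTYPE` and sample ids from `IID`. Genotype
#' codes outside `{0, 1, 2, NA}` raise an error naming the offending row and
#' column.
#'
#' @param path input file.
#' @param format `"auto"` (by extension/header), `"csv"` (any delimited
#'   text), or `"plink_raw"`.
#' @param phenotype_column phenotype column name for the delimited format.
#' @return A [gids_dataset()].
#' @export
read_dataset <- function(path, format = c("auto", "csv", "plink_raw"),
                         phenotype_column = "phenotype") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), "[,\t ]+")[[1]]
  if (format == "auto") {
    format <- if (identical(header[1:6],
                            c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")))
      "plink_raw" else "csv"
  }
  sep <- if (grepl("\\.csv$", path) ||
             grepl(",", readLines(path, n = 1L))) "," else ""
  df <- read.table(path, header = TRUE, sep = sep, na.strings = c("NA", ""),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "plink_raw") {
    if (ncol(df) < 7L) stop("PLINK .raw file has no SNP columns")
    pheno <- df[["PHENOTYPE"]]
    ids <- as.character(df[["IID"]])
    g <- as.matrix(df[, -(1:6), drop = FALSE])
  } else {
    if (!phenotype_column %in% names(df)) {
      stop(sprintf("phenotype column '%s' not found", phenotype_column))
    }
    pheno <- df[[phenotype_column]]
    ids <- NULL
    g <- as.matrix(df[, setdiff(names(df), phenotype_column), drop = FALSE])
  }
  if (anyNA(pheno)) stop("missing phenotype values are not allowed")
  storage.mode(g) <- "double"
  check_genotype_codes(g)
  storage.mode(g) <- "integer"
  gids_dataset(g, pheno, sample_ids = ids, snp_ids = colnames(g))
}

#' Write scan results as tab-separated text
#'
#' Columns `SNP1..SNPk` (SNP names when the scanned genotype matrix had
#' column names, otherwise indices), the score column (`GIDS` or `CHISQ`),
#' `rank`, and `p_value` when present.
#'
#' @param scan a [scan_order()] result, optionally with a `p_value` column.
#' @param path output file.
#' @export
write_scan_results <- function(scan, path) {
  k <- attr(scan, "k")
  statistic <- attr(scan, "statistic")
  snp_names <- attr(scan, "snp_names")
  out <- scan
  class(out) <- "data.frame"
  if (!is.null(snp_names)) {
    for (m in seq_len(k)) out[[m]] <- snp_names[out[[m]]]
  }
  names(out)[seq_len(k)] <- paste0("SNP", seq_len(k))
  names(out)[names(out) == statistic] <- toupper(statistic)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
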