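#' Generalized index of dissimilarity (GIDS)
#'
#' Measures the association between genotype rows and phenotype columns of a
#' contingency table as the total absolute deviation from the independence
#' expectation, normalized by its maximum attainable value:
#' \deqn{GIDS = \frac{\frac{1}{2}\sum_j \sum_i |n_{ij} - E_{ij}|}
#'                   {\sum_j n P_{.j}(1 - P_{.j})}}
#' with \eqn{E_{ij} = n_{i.} n_{.j} / n} and \eqn{P_{.j} = n_{.j}/n}. GIDS is
#' 0 exactly when every cell equals its expectation (no association) and 1
#' for maximal unevenness (e.g. each row holding one class only). Unlike the
#' balanced accuracy of classical MDR it requires no per-genotype risk status,
#' so any number of outcome classes `J >= 2` is handled.
#'
#' @param table a [gids_table()] or count matrix with at least two non-empty
#'   phenotype columns.
#' @return A single number in `[0, 1]`.
#' @export
#' @examples
#' compute_gids(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))  # 1
#' compute_gids(matrix(c(4, 6, 2, 3), 2, byrow = TRUE))    # 0
#' compute_gids(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))    # 0.5
compute_gids <- function(table) {
  m <- as_gids_table(table)
  n <- sum(m)
  p_col <- colSums(m) / n
  denom <- sum(n * p_col * (1 - p_col))
  if (denom <= 0) {
    stop("degenerate phenotype: all samples fall in a single class")
  }
  num <- sum(abs(m - expected_counts(m))) / 2
  num / denom
}

#' Index of dissimilarity (IDS) for two outcome classes
#'
#' The classical segregation measure
#' \eqn{IDS = \frac{1}{2}\sum_i |n_{i1}/n_{.1} - n_{i2}/n_{.2}|}: the
#' proportion of either group that would have to move across genotype rows to
#' equalize the two column distributions. Equals [compute_gids()] when
#' `J = 2`, and `2 * BA - 1` for the balanced accuracy of [compute_ba()].
#'
#' @inheritParams compute_gids
#' @return A single number in `[0, 1]`.
#' @export
compute_ids <- function(table) {
  m <- as_gids_table(table)
  if (ncol(m) != 2L) stop("IDS is defined for exactly two phenotype classes")
  tot <- colSums(m)
  if (any(tot == 0)) stop("both phenotype classes must be non-empty")
  sum(abs(m[, 1L] / tot[1L] - m[, 2L] / tot[2L])) / 2
}

resolve_case_column <- function(m, case_column) {
  if (ncol(m) != 2L) stop("risk statuses require exactly two phenotype classes")
  if (is.null(case_column)) {
    # default to the higher sorted label: the 1 = control / 2 = case convention
    return(2L)
  }
  if (is.numeric(case_column) && case_column %in% c(1, 2)) {
    return(as.integer(case_column))
  }
  j <- match(as.character(case_column), colnames(m))
  if (is.na(j)) stop(sprintf("case column '%s' not found", case_column))
  j
}

#' Assign high/low risk statuses to genotype rows
#'
#' Row `i` is HIGH when its case/control ratio is at least the overall ratio:
#' `n_i^case / n_i^control >= n^case / n^control`, evaluated as the integer
#' cross-product `n_i^case * n^control >= n_i^control * n^case` so that rows
#' with zero controls are well defined and ties go to HIGH.
#'
#' @inheritParams compute_gids
#' @param case_column label or index (1 or 2) of the case column; defaults to
#'   the second (higher-sorted) class label.
#' @return Character vector over `{"H", "L"}`, one status per genotype row.
#' @export
assign_risk_status <- function(table, case_column = NULL) {
  m <- as_gids_table(table)
  j_case <- resolve_case_column(m, case_column)
  j_ctrl <- 3L - j_case
  tot <- colSums(m)
  if (any(tot == 0)) stop("both phenotype classes must be non-empty")
  high <- m[, j_case] * tot[j_ctrl] >= m[, j_ctrl] * tot[j_case]
  setNames(ifelse(high, "H", "L"), rownames(m))
}

#' Confusion-matrix counts from risk statuses
#'
#' Pools HIGH-risk rows as predicted cases and LOW-risk rows as predicted
#' controls: `TP` = cases in HIGH rows, `TN` = controls in LOW rows,
#' `FN` = cases in LOW rows, `FP` = controls in HIGH rows.
#'
#' @inheritParams assign_risk_status
#' @param risk risk-status vector as returned by [assign_risk_status()];
#'   recomputed from the table when omitted.
#' @return Named numeric vector with elements `TP`, `TN`, `FN`, `FP`.
#' @export
confusion_counts <- function(table, risk = NULL, case_column = NULL) {
  m <- as_gids_table(table)
  j_case <- resolve_case_column(m, case_column)
  j_ctrl <- 3L - j_case
  if (is.null(risk)) risk <- assign_risk_status(m, case_column)
  if (length(risk) != nrow(m)) stop("'risk' must have one status per row")
  high <- risk == "H"
  c(TP = sum(m[high, j_case]), TN = sum(m[!high, j_ctrl]),
    FN = sum(m[!high, j_case]), FP = sum(m[high, j_ctrl]))
}

#' Balanced accuracy of the pooled high/low-risk classifier
#'
#' `BA = (sensitivity + specificity) / 2` of the classifier that predicts
#' "case" for HIGH-risk genotype rows (see [assign_risk_status()]). Under that
#' conventional risk rule `BA` lies in `[0.5, 1]` and satisfies the identity
#' `IDS = 2 * BA - 1`, which is why GIDS can be read as a generalized balanced
#' accuracy for multi-class phenotypes.
#'
#' @inheritParams assign_risk_status
#' @return A single number in `[0.5, 1]`.
#' @export
compute_ba <- function(table, case_column = NULL) {
  cc <- confusion_counts(table, case_column = case_column)
  unname((cc["TP"] / (cc["TP"] + cc["FN"]) + cc["TN"] / (cc["TN"] + cc["FP"])) / 2)
}

#' Pearson chi-squared statistic (baseline comparator)
#'
#' Raw statistic \eqn{\sum (n_{ij} - E_{ij})^2 / E_{ij}} over cells with
#' positive expected count (cells with `E_ij = 0` contribute nothing). Used
#' as a ranking baseline against GIDS; no degrees-of-freedom p-value is
#' attached.
#'
#' @inheritParams compute_gids
#' @return Non-negative number.
#' @export
chi_square_statistic <- function(table) {
  m <- as_gids_table(table)
  e <- expected_counts(m)
  ok <- e > 0
  sum((m[ok] - e[ok])^2 / e[ok])
}
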