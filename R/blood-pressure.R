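#' JNC7 composite blood-pressure classification
#'
#' Bands systolic pressure at (120, 140) mmHg and diastolic pressure at
#' (80, 90) mmHg, and combines the two 3-level bands into the nine-class
#' composite phenotype `class = 3 * SBP_band + DBP_band + 1` (bands counted
#' from 0). Classes map to the clinical labels normal (1), prehypertension
#' (2, 4, 5) and hypertension (3, 6, 7, 8, 9).
#'
#' @param sbp,dbp systolic and diastolic pressures in mmHg (finite, positive;
#'   vectorized).
#' @return Data frame with columns `class` (integer 1..9) and `label`.
#' @export
#' @examples
#' classify_blood_pressure(c(115, 130, 145), c(85, 95, 75))
classify_blood_pressure <- function(sbp, dbp) {
  if (length(sbp) != length(dbp)) stop("'sbp' and 'dbp' must have equal length")
  if (any(!is.finite(sbp)) || any(!is.finite(dbp))) {
    stop("blood pressures must be finite")
  }
  if (any(sbp <= 0) || any(dbp <= 0)) stop("blood pressures must be positive")
  sbp_band <- findInterval(sbp, c(120, 140))
  dbp_band <- findInterval(dbp, c(80, 90))
  cls <- 3L * sbp_band + dbp_band + 1L
  labels <- c("normal", "prehypertension", "hypertension",
              "prehypertension", "prehypertension", "hypertension",
              "hypertension", "hypertension", "hypertension")
  data.frame(class = cls, label = labels[cls])
}

#' Compose several categorical phenotypes into one multi-class trait
#'
#' Treats the component class vectors as digits of a mixed-radix code
#' (row-major over the components in the given order), yielding a single
#' composite phenotype with `prod(J_m)` possible classes — e.g. two 3-class
#' traits give up to nine composite states, analyzable directly since the
#' association measure places no limit on the number of classes.
#'
#' @param class_vectors list of equal-length categorical vectors (each coded
#'   `1..J_m` or with arbitrary sortable labels).
#' @return Integer composite class vector in `1..prod(J_m)`.
#' @export
#' @examples
#' compose_phenotypes(list(c(1, 2, 3), c(1, 1, 2)))
compose_phenotypes <- function(class_vectors) {
  if (!is.list(class_vectors) || length(class_vectors) == 0L) {
    stop("'class_vectors' must be a non-empty list")
  }
  n <- unique(lengths(class_vectors))
  if (length(n) != 1L) stop("component vectors must have equal length")
  idx <- rep(0L, n)
  for (v in class_vectors) {
    if (anyNA(v)) stop("missing class labels are not allowed")
    labels <- sort(unique(v))
    idx <- idx * length(labels) + (match(v, labels) - 1L)
  }
  as.integer(idx + 1L)
}
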