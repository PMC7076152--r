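#' Standardize an ROI time-series matrix
#'
#' Centers every column (ROI) to zero mean and rescales it to unit Euclidean
#' norm. Regression-based network estimators in this package assume this
#' normalization: it removes baseline offsets and puts the penalty weights on
#' a comparable scale across data sets. The operation is idempotent.
#'
#' @param x Numeric matrix, `T` rows (time points) x `N` columns (ROIs).
#' @return Matrix of the same shape with zero-mean, unit-norm columns.
#' @examples
#' standardize_ts(matrix(rnorm(40), 10, 4))
#' @export
standardize_ts <- function(x) {
  x <- as_ts_matrix(x)
  x <- sweep(x, 2L, colMeans(x), "-")
  nrm <- sqrt(colSums(x^2))
  bad <- which(nrm < 1e-12)
  if (length(bad)) {
    stop("constant column(s) (zero variance) at ROI index: ",
         paste(bad, collapse = ", "))
  }
  sweep(x, 2L, nrm, "/")
}

## Validate a time-series matrix: numeric, T >= 2, N >= 2, finite entries.
as_ts_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("time-series matrix must have at least 2 time points and 2 ROIs, got ",
         nrow(x), " x ", ncol(x))
  }
  if (!all(is.finite(x))) stop("time-series matrix contains non-finite entries")
  x
}

## Validate a cohort: list of T x N matrices sharing N.
as_cohort_list <- function(cohort) {
  if (is.matrix(cohort)) cohort <- list(cohort)
  stopifnot(is.list(cohort), length(cohort) >= 1L)
  cohort <- lapply(cohort, as_ts_matrix)
  ns <- vapply(cohort, ncol, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("all subjects must share the same number of ROIs; got N = ",
         paste(unique(ns), collapse = ", "))
  }
  cohort
}
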