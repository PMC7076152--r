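#' Pearson-correlation network
#'
#' The baseline full-correlation estimator: edge (i, j) is the sample
#' correlation of the two ROI signals; the diagonal (self-correlation) is
#' set to zero.
#'
#' @param x `T x N` time-series matrix (standardized internally).
#' @return Symmetric `N x N` matrix with zero diagonal, entries in [-1, 1].
#' @export
pearson_network <- function(x) {
  x <- standardize_ts(x)
  W <- crossprod(x)          # unit-norm columns: cross-products = correlations
  W <- pmin(pmax(W, -1), 1)
  diag(W) <- 0
  dimnames(W) <- NULL
  W
}

#' Keep the strongest edges of a network
#'
#' Retains the top `ceiling(sparsity_keep * P)` off-diagonal edges by
#' absolute weight (`P = N(N-1)/2` upper-triangle entries) and zeroes the
#' rest, preserving the kept values and symmetry. A sparsity level of 0.9
#' filters out the weakest 10% of edges. Ties are broken deterministically
#' by (|w| descending, i ascending, j ascending).
#'
#' @param W symmetric `N x N` network matrix.
#' @param sparsity_keep fraction of edges to keep, in (0, 1].
#' @return Thresholded symmetric matrix.
#' @export
threshold_network <- function(W, sparsity_keep) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (!is.numeric(sparsity_keep) || length(sparsity_keep) != 1L ||
      sparsity_keep <= 0 || sparsity_keep > 1) {
    stop("sparsity_keep must lie in (0, 1]")
  }
  if (max(abs(W - t(W))) > 1e-8) stop("threshold_network expects a symmetric matrix")
  pairs <- upper_pairs(nrow(W))
  v <- upper_vec(W)
  P <- length(v)
  keep_n <- ceiling(sparsity_keep * P)
  ord <- order(-abs(v), pairs[, 1], pairs[, 2])
  drop_idx <- ord[-seq_len(keep_n)]
  v[drop_idx] <- 0
  out <- upper_unvec(v, nrow(W))
  diag(out) <- diag(W)
  out
}

#' Symmetrize an estimated network
#'
#' Regression-based estimates are asymmetric; the finalized network is the
#' nearest symmetric matrix in Frobenius norm, `(W + W') / 2`, with the
#' diagonal forced to zero. Applied after optimization so that the solver
#' minimizes the stated objective.
#'
#' @param W `N x N` matrix.
#' @return Symmetric matrix with zero diagonal.
#' @export
finalize_network <- function(W) {
  S <- (W + t(W)) / 2
  diag(S) <- 0
  S
}

#' Sparse-representation (l1-penalized regression) network
#'
#' Solves `min_W ||X - X W||_F^2 + lambda ||W||_1  s.t. diag(W) = 0` by
#' proximal gradient descent: each ROI's signal is regressed on all others
#' with an l1 penalty, a sparse surrogate for partial correlation.
#'
#' @param x `T x N` time-series matrix.
#' @param cfg [solver_config()]; `lambda_sparse` is the penalty weight.
#' @return `N x N` coefficient matrix (zero diagonal; symmetrize with
#'   [finalize_network()]), with attribute `"diagnostics"` holding the
#'   solver state.
#' @export
estimate_sr <- function(x, cfg = solver_config()) {
  cfg <- as_solver_config(cfg)
  x <- standardize_ts(x)
  st <- prox_solve(list(x), cfg, list(l1 = cfg$lambda_sparse))
  out <- st$W[, , 1]
  attr(out, "diagnostics") <- st[c("objective", "objective_init",
                                   "iterations", "converged")]
  out
}

#' Sparse low-rank network (l1 + matrix trace norm)
#'
#' As [estimate_sr()] with an additional matrix trace-norm penalty
#' (`gamma_lowrank`), applied by singular-value soft-thresholding inside the
#' proximal iteration; encodes a modularity-like low-rank prior on a single
#' subject's network.
#'
#' @inheritParams estimate_sr
#' @return `N x N` coefficient matrix with solver diagnostics attached.
#' @export
estimate_slr <- function(x, cfg = solver_config()) {
  cfg <- as_solver_config(cfg)
  x <- standardize_ts(x)
  st <- prox_solve(list(x), cfg,
                   list(l1 = cfg$lambda_sparse, trace_matrix = cfg$gamma_lowrank))
  out <- st$W[, , 1]
  attr(out, "diagnostics") <- st[c("objective", "objective_init",
                                   "iterations", "converged")]
  out
}

#' Group-sparse (l2,1) joint network estimation
#'
#' Minimizes `sum_k ||X_k - X_k W_k||_F^2 + lambda_group ||W||_{2,1}` where
#' each group is one connection (i, j) taken across all subjects. At
#' convergence the edge supports are identical across subjects: a connection
#' is removed for everyone or kept for everyone.
#'
#' @param cohort list of `T x N` time-series matrices sharing `N`.
#' @param cfg [solver_config()]; `lambda_group` is the penalty weight.
#' @return `N x N x K` array with solver diagnostics attached.
#' @export
estimate_gsr <- function(cohort, cfg = solver_config()) {
  cfg <- as_solver_config(cfg)
  cohort <- lapply(as_cohort_list(cohort), standardize_ts)
  st <- prox_solve(cohort, cfg, list(l21 = cfg$lambda_group))
  out <- st$W
  attr(out, "diagnostics") <- st[c("objective", "objective_init",
                                   "iterations", "converged")]
  out
}

#' Tensor low-rank joint network estimation
#'
#' The group-similarity estimator with no sparsity term: the stacked
#' `N x N x K` coefficient tensor is penalized by the CP-based tensor trace
#' norm, shrinking the cohort toward a shared low-rank backbone while
#' keeping per-subject data-fit terms.
#'
#' @inheritParams estimate_gsr
#' @return `N x N x K` array with solver diagnostics attached.
#' @export
estimate_tlr <- function(cohort, cfg = solver_config()) {
  cfg <- as_solver_config(cfg)
  cfg$lambda_sparse <- 0
  estimate_stlr(cohort, cfg)
}

#' Sparse plus tensor low-rank (STLR) joint network estimation
#'
#' The full group-similarity model:
#' `min_W sum_k ||X_k - X_k W_k||_F^2 + lambda_sparse ||W||_1 +
#' gamma_lowrank ||W||_*` with the tensor trace norm realized by CP/PARAFAC
#' weight shrinkage. Solved by the proximal-gradient loop: line-searched
#' gradient step, tensor trace-norm shrinkage, elementwise
#' soft-thresholding, diagonal re-zeroing, until the relative Frobenius
#' change of the tensor falls below `tol`.
#'
#' @inheritParams estimate_gsr
#' @return `N x N x K` array; attribute `"diagnostics"` holds the objective
#'   trace, iteration count and convergence flag.
#' @export
estimate_stlr <- function(cohort, cfg = solver_config()) {
  cfg <- as_solver_config(cfg)
  cohort <- lapply(as_cohort_list(cohort), standardize_ts)
  st <- prox_solve(cohort, cfg,
                   list(l1 = cfg$lambda_sparse,
                        trace_tensor = cfg$gamma_lowrank))
  out <- st$W
  attr(out, "diagnostics") <- st[c("objective", "objective_init",
                                   "iterations", "converged")]
  out
}

#' Estimate networks for a cohort with any supported method
#'
#' One front door over all estimators. Single-subject methods (`pc`,
#' `pc_thresh`, `sr`, `slr`) are applied per subject; group methods (`gsr`,
#' `tlr`, `stlr`) solve one joint problem. Results are returned as an
#' `N x N x K` array of raw (asymmetric, for regression methods) networks;
#' apply [finalize_network()] slice-wise before downstream analysis.
#'
#' @param cohort list of `T x N` time-series matrices.
#' @param method one of `"pc"`, `"pc_thresh"`, `"sr"`, `"slr"`, `"gsr"`,
#'   `"tlr"`, `"stlr"`.
#' @param cfg [solver_config()] for the regularized methods.
#' @param sparsity_keep edge fraction kept by `"pc_thresh"`.
#' @return `N x N x K` array of estimated networks.
#' @export
estimate_cohort <- function(cohort, method, cfg = solver_config(),
                            sparsity_keep = 1.0) {
  method <- match.arg(method,
                      c("pc", "pc_thresh", "sr", "slr", "gsr", "tlr", "stlr"))
  cohort <- as_cohort_list(cohort)
  K <- length(cohort)
  N <- ncol(cohort[[1]])
  per_subject <- function(f) {
    out <- array(0, dim = c(N, N, K))
    for (k in seq_len(K)) out[, , k] <- f(cohort[[k]])
    out
  }
  switch(method,
    pc        = per_subject(pearson_network),
    pc_thresh = per_subject(function(x)
                  threshold_network(pearson_network(x), sparsity_keep)),
    sr        = per_subject(function(x) estimate_sr(x, cfg)),
    slr       = per_subject(function(x) estimate_slr(x, cfg)),
    gsr       = estimate_gsr(cohort, cfg),
    tlr       = estimate_tlr(cohort, cfg),
    stlr      = estimate_stlr(cohort, cfg))
}
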