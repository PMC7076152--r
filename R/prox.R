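#' Gradient of the regression data-fit term
#'
#' For the partial-correlation data-fit `1/2 ||X - X W||_F^2` the gradient
#' with respect to `W` is `X'X W - X'X`. The 1/2 scaling is fixed so that
#' the gradient takes exactly this form.
#'
#' @param X standardized `T x N` time-series matrix.
#' @param W current `N x N` coefficient matrix.
#' @return `N x N` gradient matrix.
#' @export
grad_fit <- function(X, W) {
  if (ncol(X) != nrow(W) || nrow(W) != ncol(W)) {
    stop("shape mismatch: X is ", nrow(X), "x", ncol(X),
         ", W is ", nrow(W), "x", ncol(W))
  }
  G <- crossprod(X)
  G %*% W - G
}

## Data-fit value 1/2 sum_k ||X_k - X_k W_k||_F^2 over a list of subjects
## and a 3-way coefficient array (N x N x K).
fit_value <- function(Xlist, W) {
  K <- length(Xlist)
  s <- 0
  for (k in seq_len(K)) {
    R <- Xlist[[k]] - Xlist[[k]] %*% W[, , k]
    s <- s + sum(R^2)
  }
  s / 2
}

#' Elementwise soft-thresholding (proximal operator of the l1 norm)
#'
#' @param W numeric matrix or array.
#' @param tau nonnegative threshold.
#' @return Same-shape object with `sign(w) * max(|w| - tau, 0)` applied
#'   elementwise.
#' @export
prox_l1 <- function(W, tau) {
  stopifnot(tau >= 0)
  sign(W) * pmax(abs(W) - tau, 0)
}

#' Group soft-thresholding across subjects (proximal operator of the l2,1 norm)
#'
#' Each connection (i, j) forms one group: the vector of its weights across
#' the K subjects (third array dimension). Groups whose l2 norm falls below
#' `tau` are zeroed jointly; the rest are shrunk by `1 - tau / norm`. This is
#' the joint-feature-selection construction used by group-sparse network
#' estimation: an edge survives for all subjects or for none.
#'
#' @param W `N x N x K` array.
#' @param tau nonnegative threshold.
#' @return Array of the same shape.
#' @export
prox_group_l21 <- function(W, tau) {
  stopifnot(length(dim(W)) == 3L, tau >= 0)
  norms <- sqrt(apply(W^2, c(1, 2), sum))
  scale <- ifelse(norms > 0, pmax(1 - tau / norms, 0), 0)
  W * array(scale, dim = dim(W))
}

#' Singular-value soft-thresholding (proximal operator of the matrix trace norm)
#'
#' @param W numeric matrix.
#' @param tau nonnegative threshold applied to each singular value.
#' @return Matrix `U max(S - tau, 0) V'` from the SVD of `W`.
#' @export
prox_trace_matrix <- function(W, tau) {
  stopifnot(is.matrix(W), tau >= 0)
  sv <- svd(W)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(W), ncol(W)))
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

## ---- CP / PARAFAC decomposition ------------------------------------------

## Mode-n unfolding of a 3-way array (column-major pairing of the other
## modes, matching the Khatri-Rao construction below).
unfold3 <- function(A, mode) {
  d <- dim(A)
  switch(mode,
    `1` = matrix(A, d[1], d[2] * d[3]),
    `2` = matrix(aperm(A, c(2, 1, 3)), d[2], d[1] * d[3]),
    `3` = matrix(aperm(A, c(3, 1, 2)), d[3], d[1] * d[2]),
    stop("mode must be 1, 2 or 3"))
}

## Columnwise Khatri-Rao product: column r is kron(A[, r], B[, r]).
khatri_rao <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  A[rep(seq_len(n), each = m), , drop = FALSE] *
    B[rep.int(seq_len(m), n), , drop = FALSE]
}

## Leading eigenvectors of M M' (for HOSVD-style CP initialization),
## padded with seeded random unit columns when rank exceeds the mode size.
mode_singular_vectors <- function(M, rank) {
  S <- tcrossprod(M)
  ev <- eigen(S, symmetric = TRUE)
  r0 <- min(rank, ncol(ev$vectors))
  V <- ev$vectors[, seq_len(r0), drop = FALSE]
  if (rank > r0) {
    extra <- matrix(stats::rnorm(nrow(M) * (rank - r0)), nrow(M))
    extra <- sweep(extra, 2L, sqrt(colSums(extra^2)), "/")
    V <- cbind(V, extra)
  }
  V
}

normalize_cols <- function(A) {
  nrm <- sqrt(colSums(A^2))
  nrm[nrm < 1e-300] <- 1
  list(A = sweep(A, 2L, nrm, "/"), norms = nrm)
}

## Ridge-stabilized solve of the ALS normal equations.
solve_gram <- function(G, RHS) {
  eps <- 1e-10 * max(1, max(abs(diag(G))))
  t(solve(G + diag(eps, nrow(G)), t(RHS)))
}

#' CP/PARAFAC decomposition of a 3-way tensor
#'
#' Alternating least squares fit of a rank-`rank` CP model
#' `sum_r lambda_r a_r o b_r o c_r` with unit-norm factor columns and
#' nonnegative weights sorted in descending order. The first initialization
#' is deterministic (leading singular vectors of each unfolding); the
#' remaining `n_init - 1` restarts use seeded random factors, and the fit
#' with the smallest residual wins. Sign indeterminacy is resolved by making
#' the first nonzero entry of each column of the first two factors positive
#' (flips absorbed pairwise into the third factor), so the result is
#' deterministic given `(tensor, rank, seed)`.
#'
#' @param A numeric 3-way array.
#' @param rank CP rank (number of rank-1 components), >= 1.
#' @param seed integer seed for the random restarts.
#' @param n_init number of initializations (first one is SVD-based).
#' @param max_iter maximum ALS sweeps per initialization.
#' @param tol relative-residual change tolerance for ALS convergence.
#' @param init optional list of three factor matrices used as the first
#'   initialization in place of the SVD one (warm start).
#' @return Object of class `cp_model`: list with `weights` (length `rank`),
#'   `factors` (list of three unit-column matrices), `rank`, `residual`
#'   (relative Frobenius reconstruction error), `converged`, and
#'   `raw_factors` (the factors before canonical sign/ordering, for warm
#'   starts).
#' @export
cp_decompose <- function(A, rank, seed = 0L, n_init = 3L, max_iter = 60L,
                         tol = 1e-8, init = NULL) {
  stopifnot(length(dim(A)) == 3L, rank >= 1L)
  d <- dim(A)
  nrmA <- fnorm(A)
  if (nrmA == 0) {
    factors <- lapply(d, function(n) {
      F0 <- diag(1, n, rank)
      if (rank > n) {
        F0 <- cbind(F0[, seq_len(n), drop = FALSE],
                    matrix(1 / sqrt(n), n, rank - n))
      }
      F0
    })
    return(structure(list(weights = rep(0, rank), factors = factors,
                          rank = rank, residual = 0, converged = TRUE),
                     class = "cp_model"))
  }
  X1 <- unfold3(A, 1); X2 <- unfold3(A, 2); X3 <- unfold3(A, 3)

  run_als <- function(Fs) {
    A1 <- Fs[[1]]; A2 <- Fs[[2]]; A3 <- Fs[[3]]
    res_prev <- Inf; converged <- FALSE
    for (it in seq_len(max_iter)) {
      A1 <- solve_gram(crossprod(A3) * crossprod(A2), X1 %*% khatri_rao(A3, A2))
      A1 <- normalize_cols(A1)$A
      A2 <- solve_gram(crossprod(A3) * crossprod(A1), X2 %*% khatri_rao(A3, A1))
      A2 <- normalize_cols(A2)$A
      A3 <- solve_gram(crossprod(A2) * crossprod(A1), X3 %*% khatri_rao(A2, A1))
      n3 <- normalize_cols(A3); A3 <- n3$A; lam <- n3$norms
      recon_nrm2 <- sum((crossprod(A1) * crossprod(A2) * crossprod(A3)) *
                          tcrossprod(lam))
      inner <- sum((X3 %*% khatri_rao(A2, A1)) * (A3 * rep(lam, each = d[3])))
      res <- sqrt(max(nrmA^2 - 2 * inner + recon_nrm2, 0)) / nrmA
      if (is.finite(res_prev) && abs(res_prev - res) < tol) {
        converged <- TRUE; res_prev <- res; break
      }
      res_prev <- res
    }
    list(factors = list(A1, A2, A3), weights = lam, residual = res_prev,
         converged = converged)
  }

  with_seed(seed, {
    best <- NULL
    for (i in seq_len(max(1L, n_init))) {
      Fs <- if (i == 1L && !is.null(init)) {
        init
      } else if (i == 1L) {
        list(mode_singular_vectors(X1, rank),
             mode_singular_vectors(X2, rank),
             mode_singular_vectors(X3, rank))
      } else {
        lapply(d, function(n) {
          normalize_cols(matrix(stats::rnorm(n * rank), n, rank))$A
        })
      }
      fit <- run_als(Fs)
      if (is.null(best) || fit$residual < best$residual - 1e-12) best <- fit
    }
    best
  }) -> best

  ## canonical form: nonnegative descending weights, pairwise sign fixing
  lam <- best$weights
  A1 <- best$factors[[1]]; A2 <- best$factors[[2]]; A3 <- best$factors[[3]]
  for (r in seq_len(rank)) {
    f1 <- which(abs(A1[, r]) > 1e-12)[1]
    if (!is.na(f1) && A1[f1, r] < 0) { A1[, r] <- -A1[, r]; A3[, r] <- -A3[, r] }
    f2 <- which(abs(A2[, r]) > 1e-12)[1]
    if (!is.na(f2) && A2[f2, r] < 0) { A2[, r] <- -A2[, r]; A3[, r] <- -A3[, r] }
  }
  ord <- order(lam, decreasing = TRUE)
  structure(list(weights = lam[ord],
                 factors = list(A1[, ord, drop = FALSE],
                                A2[, ord, drop = FALSE],
                                A3[, ord, drop = FALSE]),
                 rank = rank, residual = best$residual,
                 converged = best$converged),
            class = "cp_model")
}

#' Reconstruct a tensor from a CP model
#'
#' @param model `cp_model` from [cp_decompose()], optionally with modified
#'   weights.
#' @param weights optional replacement weight vector.
#' @return The 3-way array `sum_r w_r a_r o b_r o c_r`.
#' @export
cp_reconstruct <- function(model, weights = model$weights) {
  A1 <- model$factors[[1]]; A2 <- model$factors[[2]]; A3 <- model$factors[[3]]
  d <- c(nrow(A1), nrow(A2), nrow(A3))
  M1 <- A1 %*% (weights * t(khatri_rao(A3, A2)))
  array(M1, dim = d)
}

#' Tensor trace-norm shrinkage via CP weights
#'
#' The proximal shrinkage used for the tensor low-rank penalty: decompose the
#' stacked-network tensor by CP/PARAFAC, soft-threshold the CP weights
#' (`max(lambda_r - tau, 0)`), and reconstruct. With a single slice
#' (`K = 1`) the CP weights of a matrix coincide with its singular values, so
#' the operation reduces to matrix singular-value soft-thresholding, which is
#' applied directly in that case.
#'
#' @param W `N x N x K` array of stacked networks.
#' @param tau nonnegative shrinkage threshold.
#' @param rank CP rank; `"auto"` uses `min(N, K)` capped at 30.
#' @param seed seed forwarded to [cp_decompose()].
#' @param n_init CP initializations; the iterative solver uses 1 (the
#'   deterministic SVD-based initialization) so the prox map is a
#'   deterministic function of its input.
#' @return Array of the same shape; attribute `"cp_weights"` carries the
#'   shrunk weights.
#' @param init optional warm-start factors forwarded to [cp_decompose()];
#'   the fitted model is attached as attribute `"cp_model"` so iterative
#'   callers can chain warm starts.
#' @export
prox_trace_tensor <- function(W, tau, rank = "auto", seed = 0L, n_init = 3L,
                              init = NULL) {
  stopifnot(length(dim(W)) == 3L, tau >= 0)
  d <- dim(W)
  if (d[3] == 1L) {
    out <- array(prox_trace_matrix(W[, , 1], tau), dim = d)
    attr(out, "cp_weights") <- pmax(svd(W[, , 1])$d - tau, 0)
    return(out)
  }
  if (identical(rank, "auto")) rank <- min(d[1], d[3], 30L)
  model <- cp_decompose(W, rank = rank, seed = seed, n_init = n_init,
                        init = init)
  w <- pmax(model$weights - tau, 0)
  out <- if (all(w == 0)) array(0, dim = d) else cp_reconstruct(model, w)
  attr(out, "cp_weights") <- w
  attr(out, "cp_model") <- model
  out
}
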