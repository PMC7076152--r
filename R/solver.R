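#' Solver configuration for regularized network estimation
#'
#' Bundles the hyper-parameters and numerical controls shared by all
#' iterative estimators.
#'
#' @param lambda_sparse nonnegative weight of the elementwise l1 penalty.
#' @param gamma_lowrank nonnegative weight of the trace-norm (low-rank)
#'   penalty — the matrix trace norm for sparse low-rank estimation, the
#'   CP-based tensor trace norm for the group estimators.
#' @param lambda_group nonnegative weight of the l2,1 group-sparsity penalty
#'   (group-sparse estimation only).
#' @param step_init initial gradient step size `a_t` (default 0.001), adapted
#'   by backtracking line search.
#' @param max_iter maximum proximal-gradient iterations.
#' @param tol convergence tolerance on the relative Frobenius change of the
#'   iterate.
#' @param cp_rank CP rank for the tensor shrinkage; `"auto"` = `min(N, K)`
#'   capped at 30.
#' @param seed master seed for all randomness (CP restarts).
#' @return Object of class `solver_config` (a validated list).
#' @export
solver_config <- function(lambda_sparse = 0, gamma_lowrank = 0,
                          lambda_group = 0, step_init = 0.001,
                          max_iter = 100L, tol = 1e-5,
                          cp_rank = "auto", seed = 0L) {
  stopifnot(lambda_sparse >= 0, gamma_lowrank >= 0, lambda_group >= 0,
            step_init > 0, max_iter >= 1L, tol > 0)
  if (!identical(cp_rank, "auto")) stopifnot(cp_rank >= 1L)
  structure(list(lambda_sparse = lambda_sparse,
                 gamma_lowrank = gamma_lowrank,
                 lambda_group = lambda_group,
                 step_init = step_init,
                 max_iter = as.integer(max_iter),
                 tol = tol, cp_rank = cp_rank,
                 seed = as.integer(seed)),
            class = "solver_config")
}

as_solver_config <- function(cfg) {
  if (inherits(cfg, "solver_config")) return(cfg)
  do.call(solver_config, cfg)
}

#' Backtracking line-search gradient step
#'
#' Starting from the current step size, the candidate `W - a * G` is
#' accepted when it satisfies the quadratic upper-bound (Nemirovski-style)
#' condition `f(W - a G) <= f(W) - (a / 2) ||G||^2`, which both forces a
#' strict decrease of the data-fit term and keeps the accepted step inside
#' the `1/L` stability region of the gradient map; otherwise `a` is halved,
#' up to 30 times. When the very first candidate is accepted the step is
#' doubled for the next iteration (capped at 1.0). Thirty failed halvings
#' are treated as stationarity.
#'
#' @param fun data-fit function of the iterate.
#' @param W current iterate (matrix or array).
#' @param G gradient of `fun` at `W`, same shape.
#' @param step current step size.
#' @param f_cur optional precomputed `fun(W)`.
#' @param step_max upper bound for the doubled step (default 1.0).
#' @return List with `W` (accepted iterate), `a` (accepted step size),
#'   `step` (step size for the next iteration), `halvings`, `stalled` (TRUE
#'   when no decrease was found), `f` (data-fit at the accepted iterate).
#' @export
line_search_step <- function(fun, W, G, step, f_cur = fun(W), step_max = 1.0) {
  if (all(G == 0)) {
    return(list(W = W, a = step, step = step, halvings = 0L, stalled = FALSE,
                f = f_cur))
  }
  a <- min(step, step_max)
  g2 <- sum(G^2)
  for (h in 0:30) {
    cand <- W - a * G
    f_new <- fun(cand)
    if (f_new <= f_cur - a * g2 / 2) {
      step_next <- if (h == 0L) min(2 * a, step_max) else a
      return(list(W = cand, a = a, step = step_next, halvings = h,
                  stalled = FALSE, f = f_new))
    }
    a <- a / 2
  }
  list(W = W, a = step, step = step, halvings = 30L, stalled = TRUE, f = f_cur)
}

## Core proximal-gradient loop shared by all regularized estimators.
##
## Per iteration (the printed algorithm order): line-searched gradient step
## on the data-fit term, tensor/matrix trace-norm shrinkage, l1 (or group
## l2,1) soft-thresholding, diagonal re-zeroing. Penalty prox thresholds are
## scaled by the accepted step size (standard proximal-gradient scaling).
##
## penalties: list(l1 = , trace_tensor = , trace_matrix = , l21 = ), each 0
## to disable. X is a list of K standardized T x N matrices; the iterate is
## an N x N x K array (K = 1 for single-subject problems).
prox_solve <- function(Xlist, cfg, penalties) {
  cfg <- as_solver_config(cfg)
  p <- list(l1 = 0, trace_tensor = 0, trace_matrix = 0, l21 = 0)
  p[names(penalties)] <- penalties
  K <- length(Xlist)
  N <- ncol(Xlist[[1]])
  cp_rank <- if (identical(cfg$cp_rank, "auto")) min(N, K, 30L) else cfg$cp_rank

  W <- array(0, dim = c(N, N, K))
  grams <- lapply(Xlist, crossprod)

  ## gradient projected onto the zero-diagonal subspace: the step then stays
  ## feasible, the line-search decrease is monotone under the constraint, and
  ## stationarity means the *projected* gradient vanishes
  grad_all <- function(W) {
    G <- array(0, dim = dim(W))
    for (k in seq_len(K)) {
      Gk <- grams[[k]] %*% W[, , k] - grams[[k]]
      diag(Gk) <- 0
      G[, , k] <- Gk
    }
    G
  }
  fun <- function(W) fit_value(Xlist, W)

  penalty_value <- function(W, cp_w = NULL) {
    v <- p$l1 * sum(abs(W))
    if (p$trace_matrix > 0) v <- v + p$trace_matrix * sum(svd(W[, , 1])$d)
    if (p$trace_tensor > 0 && !is.null(cp_w)) {
      v <- v + p$trace_tensor * sum(cp_w)
    }
    if (p$l21 > 0) v <- v + p$l21 * sum(sqrt(apply(W^2, c(1, 2), sum)))
    v
  }

  step <- cfg$step_init
  step_cap <- 1.0   # shrink-only ceiling: a step size that once failed the
                    # line-search test is never attempted again, so the
                    # accepted step (and with it the prox thresholds)
                    # stabilizes instead of cycling
  f_cur <- fun(W)
  obj0 <- f_cur + penalty_value(W)
  obj_trace <- numeric(0)
  converged <- FALSE
  stalled <- FALSE
  iters <- 0L

  for (t in seq_len(cfg$max_iter)) {
    iters <- t
    W_prev <- W
    ls <- line_search_step(fun, W, grad_all(W), step, f_cur,
                           step_max = step_cap)
    if (ls$halvings > 0L && !ls$stalled) step_cap <- ls$a
    W <- ls$W; step <- ls$step; f_cur <- ls$f
    if (ls$stalled && p$l1 == 0 && p$trace_tensor == 0 &&
        p$trace_matrix == 0 && p$l21 == 0) {
      stalled <- TRUE
    }
    cp_w <- NULL
    a <- ls$a
    if (p$trace_tensor > 0) {
      ## deterministic CP (SVD-based init, fixed seed): the shrinkage is a
      ## deterministic function of the iterate, so the loop can settle at a
      ## fixed point; a fresh fit per iteration also avoids the slow weight
      ## inflation (CP degeneracy) that chained warm starts can accumulate
      W <- prox_trace_tensor(W, a * p$trace_tensor, rank = cp_rank,
                             seed = cfg$seed, n_init = 1L)
      cp_w <- attr(W, "cp_weights")
      attr(W, "cp_weights") <- NULL
      attr(W, "cp_model") <- NULL
    }
    if (p$trace_matrix > 0) {
      W[, , 1] <- prox_trace_matrix(W[, , 1], a * p$trace_matrix)
    }
    if (p$l1 > 0) W <- prox_l1(W, a * p$l1)
    if (p$l21 > 0) W <- prox_group_l21(W, a * p$l21)
    for (k in seq_len(K)) diag(W[, , k]) <- 0
    f_cur <- fun(W)
    obj <- f_cur + penalty_value(W, cp_w)
    obj_trace <- c(obj_trace, obj)
    if (!is.finite(obj)) stop("solver produced a non-finite objective")
    if (obj > 10 * max(obj0, 1e-12)) {
      stop("solver diverged: objective exceeded 10x its initial value")
    }
    delta <- fnorm(W - W_prev) / max(1, fnorm(W_prev))
    if (delta < cfg$tol || stalled) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("solver did not converge within ", cfg$max_iter, " iterations")
  }
  structure(list(W = W, objective = obj_trace, objective_init = obj0,
                 iterations = iters, converged = converged, step = step),
            class = "solver_state")
}
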