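test_that("pearson_network reproduces pairwise correlations", {
  x <- cbind(a = c(1, 2, 3, 5), b = c(1, 2, 3, 5), c = c(-1, 1, -1, 1))
  W <- pearson_network(x)
  expect_equal(W[1, 2], 1, tolerance = 1e-12)
  expect_equal(diag(W), rep(0, 3))
  y <- cbind(c(1, -1, 1, -1), c(-1, 1, -1, 1))
  expect_equal(pearson_network(y)[1, 2], -1, tolerance = 1e-12)
  # direct-formula oracle, seeded
  set.seed(13)
  z <- matrix(rnorm(15), 5, 3)
  W <- pearson_network(z)
  for (i in 1:3) for (j in 1:3) {
    if (i != j) {
      ci <- z[, i] - mean(z[, i]); cj <- z[, j] - mean(z[, j])
      r <- sum(ci * cj) / sqrt(sum(ci^2) * sum(cj^2))
      expect_equal(W[i, j], r, tolerance = 1e-12)
    }
  }
  expect_true(all(W >= -1 & W <= 1))
})

test_that("threshold_network keeps the strongest edges", {
  set.seed(4)
  W <- finalize_network(matrix(rnorm(100), 10))
  expect_equal(threshold_network(W, 1.0), W)

  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- 0.9
  W3[1, 3] <- W3[3, 1] <- 0.5
  W3[2, 3] <- W3[3, 2] <- 0.1
  out <- threshold_network(W3, 1 / 3)
  expect_equal(out[1, 2], 0.9)
  expect_equal(out[1, 3], 0)
  expect_equal(out[2, 3], 0)

  # sort oracle at 40% density
  out <- threshold_network(W, 0.4)
  v <- stlrnet:::upper_vec(out)
  expect_equal(sum(v != 0), ceiling(0.4 * 45))
  kept <- sort(abs(stlrnet:::upper_vec(W)), decreasing = TRUE)[seq_len(18)]
  expect_equal(sort(abs(v[v != 0]), decreasing = TRUE), kept)
  expect_equal(out, t(out))

  expect_error(threshold_network(W, 0), "\\(0, 1\\]")
  expect_error(threshold_network(W, 1.2), "\\(0, 1\\]")
})

test_that("finalize_network is the nearest symmetric zero-diagonal matrix", {
  S <- finalize_network(matrix(rnorm(16), 4))
  expect_equal(finalize_network(S), S)
  W <- matrix(0, 2, 2); W[1, 2] <- 0.4; W[2, 1] <- 0.2
  expect_equal(finalize_network(W)[1, 2], 0.3)
  # projection oracle: no random symmetric matrix is closer
  set.seed(6)
  W <- matrix(rnorm(25), 5)
  S <- finalize_network(W)
  diag(W) <- 0   # compare on the off-diagonal constraint set
  d0 <- stlrnet:::fnorm(S - W)
  for (r in 1:25) {
    C <- finalize_network(matrix(rnorm(25), 5))
    expect_gte(stlrnet:::fnorm(C - W), d0 - 1e-12)
  }
})

test_that("sparse regression matches the least-squares oracle at zero penalty", {
  set.seed(19)
  X <- matrix(rnorm(200 * 8), 200, 8)
  W <- estimate_sr(X, solver_config(lambda_sparse = 0, max_iter = 500, tol = 1e-9))
  expect_equal(unclass(W), ls_network_oracle(X),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(diag(W), rep(0, 8))
})

test_that("over-penalized sparse regression returns the empty network", {
  set.seed(20)
  X <- matrix(rnorm(50 * 6), 50, 6)
  W <- estimate_sr(X, solver_config(lambda_sparse = 1e6))
  expect_equal(unclass(W), matrix(0, 6, 6), ignore_attr = TRUE)
})

test_that("sparse regression satisfies optimality properties at moderate penalty", {
  set.seed(23)
  X <- standardize_ts(matrix(rnorm(150 * 8), 150, 8))
  lam <- 0.1
  W <- estimate_sr(X, solver_config(lambda_sparse = lam, max_iter = 400, tol = 1e-8))
  obj <- function(W) sum((X - X %*% W)^2) / 2 + lam * sum(abs(W))
  # better than the zero matrix and than the hard-thresholded LS solution
  expect_lt(obj(W), obj(matrix(0, 8, 8)))
  Wls <- ls_network_oracle(X)
  Wthr <- Wls * (abs(W) > 1e-8)
  expect_lte(obj(W), obj(Wthr) + 1e-8)
  # subgradient optimality residual
  G <- grad_fit(X, W); diag(G) <- 0
  active <- abs(W) > 1e-8
  expect_lt(max(abs(G[active] + lam * sign(W[active]))), 1e-3)
  expect_lt(max(abs(G[!active])) - lam, 1e-3)
})

test_that("sparse low-rank estimation reduces to its limiting cases", {
  set.seed(31)
  X <- matrix(rnorm(120 * 6), 120, 6)
  W00 <- estimate_slr(X, solver_config(max_iter = 300, tol = 1e-8))
  Wsr0 <- estimate_sr(X, solver_config(max_iter = 300, tol = 1e-8))
  expect_equal(unclass(W00), unclass(Wsr0), tolerance = 1e-6, ignore_attr = TRUE)
  Wg0 <- estimate_slr(X, solver_config(lambda_sparse = 0.1, max_iter = 300, tol = 1e-8))
  Wsr <- estimate_sr(X, solver_config(lambda_sparse = 0.1, max_iter = 300, tol = 1e-8))
  expect_equal(unclass(Wg0), unclass(Wsr), tolerance = 1e-5, ignore_attr = TRUE)
  Whuge <- estimate_slr(X, solver_config(gamma_lowrank = 1e6))
  expect_equal(unclass(Whuge), matrix(0, 6, 6), ignore_attr = TRUE)
})

test_that("group-sparse estimation on identical subjects matches scaled SR", {
  set.seed(37)
  X <- matrix(rnorm(100 * 6), 100, 6)
  K <- 4
  lam <- 0.08
  Wg <- estimate_gsr(rep(list(X), K),
                     solver_config(lambda_group = lam * sqrt(K),
                                   max_iter = 400, tol = 1e-9))
  Wsr <- estimate_sr(X, solver_config(lambda_sparse = lam,
                                      max_iter = 400, tol = 1e-9))
  for (k in seq_len(K)) {
    expect_equal(Wg[, , k], unclass(Wsr), tolerance = 1e-6, ignore_attr = TRUE)
  }
  # over-penalization zeroes the whole tensor
  Wz <- estimate_gsr(rep(list(X), 3), solver_config(lambda_group = 1e6))
  expect_equal(unclass(Wz), array(0, c(6, 6, 3)), ignore_attr = TRUE)
})

test_that("group-sparse supports are all-or-none across subjects", {
  # an edge present in half the subjects: at intermediate penalty it is
  # either kept for every subject or removed for every subject
  set.seed(43)
  co <- make_cohort(n_rois = 8, n_per_class = c(4, 4), n_time = 200,
                    jitter = 0.05, n_diff_edges = 4, effect_size = 0.5,
                    seed = 5)
  Wg <- estimate_gsr(co$signals, solver_config(lambda_group = 0.6,
                                               max_iter = 300, tol = 1e-8))
  supp <- abs(Wg) > 1e-8
  ref <- supp[, , 1]
  for (k in 2:dim(Wg)[3]) expect_identical(supp[, , k], ref)
  expect_gt(sum(ref), 0)   # not trivially empty
})

test_that("the reduction chain collapses to slice-wise least squares", {
  set.seed(47)
  co <- make_cohort(n_rois = 8, n_per_class = c(2, 2), n_time = 150, seed = 9)
  cfg <- solver_config(max_iter = 400, tol = 1e-9)
  Wstlr <- estimate_stlr(co$signals, cfg)
  Wtlr <- estimate_tlr(co$signals, cfg)
  expect_equal(unclass(Wstlr), unclass(Wtlr), tolerance = 1e-7,
               ignore_attr = TRUE)
  for (k in 1:4) {
    expect_equal(Wstlr[, , k], ls_network_oracle(co$signals[[k]]),
                 tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("tensor low-rank pulls subject networks toward each other", {
  set.seed(53)
  # cohort whose true slices are identical: group shrinkage should reduce
  # inter-subject spread relative to independent sparse regression
  truth <- make_group_networks(n_rois = 10, n_per_class = c(3, 3),
                               jitter = 0, n_diff_edges = 0, seed = 2)
  signals <- lapply(1:6, function(k) {
    simulate_bold(truth$networks[, , k], 120, seed = 100 + k)
  })
  Wt <- suppressWarnings(
    estimate_tlr(signals, solver_config(gamma_lowrank = 0.25)))
  Wsr <- estimate_cohort(signals, "sr", solver_config(lambda_sparse = 2^-4))
  expect_lt(mean_pairwise_frob(Wt), mean_pairwise_frob(Wsr))
})

test_that("estimators return zero diagonals and symmetric finalized output", {
  set.seed(59)
  co <- make_cohort(n_rois = 6, n_per_class = c(2, 2), n_time = 80, seed = 3)
  for (m in c("pc", "sr", "stlr")) {
    W <- suppressWarnings(
      estimate_cohort(co$signals, m,
                      solver_config(lambda_sparse = 0.1, gamma_lowrank = 0.05)))
    for (k in 1:4) {
      expect_equal(diag(W[, , k]), rep(0, 6))
      S <- finalize_network(W[, , k])
      expect_equal(S, t(S))
    }
  }
})
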