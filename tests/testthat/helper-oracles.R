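# Shared fixtures and independent oracles used across the test files.

# edge-support F1 of an estimated network stack against per-class truth
support_f1 <- function(W, cohort, eps = 1e-6) {
  K <- dim(W)[3]
  per <- vapply(seq_len(K), function(k) {
    v <- abs(stlrnet:::upper_vec(finalize_network(W[, , k]))) > eps
    truth <- if (cohort$labels[k] == 1) cohort$support$class1
             else cohort$support$class0
    tp <- sum(v & truth); fp <- sum(v & !truth); fn <- sum(!v & truth)
    if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(per)
}

mean_pairwise_frob <- function(W) {
  K <- dim(W)[3]
  d <- c()
  for (a in seq_len(K - 1)) {
    for (b in (a + 1):K) d <- c(d, sqrt(sum((W[, , a] - W[, , b])^2)))
  }
  mean(d)
}

# least-squares network oracle: column j regressed on the other columns via
# the normal equations, coefficient j fixed at zero
ls_network_oracle <- function(X) {
  X <- standardize_ts(X)
  N <- ncol(X)
  W <- matrix(0, N, N)
  for (j in seq_len(N)) {
    W[-j, j] <- solve(crossprod(X[, -j]), crossprod(X[, -j], X[, j]))
  }
  W
}

# brute-force graph oracles on adjacency matrices (N small)
oracle_clustering <- function(A) {
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) tri <- tri + (A[nb[a], nb[b]] != 0)
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
  mean(vals)
}

oracle_shortest_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A != 0] <- 1
  for (m in seq_len(n)) {          # Floyd-Warshall
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, m] + D[m, j] < D[i, j]) D[i, j] <- D[i, m] + D[m, j]
      }
    }
  }
  D
}

oracle_path_length <- function(A) {
  D <- oracle_shortest_paths(A)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d) & d > 0])
}

oracle_global_efficiency <- function(A) {
  D <- oracle_shortest_paths(A)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (nrow(A) * (nrow(A) - 1))
}

# newman modularity of a partition on a binary graph
oracle_modularity <- function(A, membership) {
  m <- sum(A) / 2
  if (m == 0) return(0)
  deg <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + A[i, j] - deg[i] * deg[j] / (2 * m)
      }
    }
  }
  q / (2 * m)
}

adjacency_from_edges <- function(n, edges) {
  A <- matrix(0, n, n)
  for (e in edges) { A[e[1], e[2]] <- 1; A[e[2], e[1]] <- 1 }
  A
}

# ring lattice where each node connects to `k` nearest neighbours per side
ring_lattice <- function(n, k = 2) {
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (s in seq_len(k)) {
      j <- ((i - 1 + s) %% n) + 1
      A[i, j] <- 1; A[j, i] <- 1
    }
  }
  A
}
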