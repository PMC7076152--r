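#' Binarize a weighted network
#'
#' Converts an estimated network into an undirected binary graph. The
#' default rule keeps every edge whose absolute weight exceeds a small
#' tolerance (the estimator's own sparsity pattern); the `"density"` rule
#' keeps the strongest edges at a fixed edge density via
#' [threshold_network()]. Negative weights count by magnitude.
#'
#' @param W symmetric `N x N` weighted matrix.
#' @param rule `"nonzero"` or `"density"`.
#' @param density edge density for the `"density"` rule.
#' @param eps absolute-weight tolerance for the `"nonzero"` rule.
#' @return Symmetric 0/1 adjacency matrix with zero diagonal.
#' @export
binarize <- function(W, rule = c("nonzero", "density"), density = 0.2,
                     eps = 1e-6) {
  rule <- match.arg(rule)
  W <- finalize_network(W)
  if (rule == "density") W <- threshold_network(abs(W), density)
  A <- (abs(W) > eps) * 1
  diag(A) <- 0
  A
}

as_igraph <- function(A) {
  igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected", diag = FALSE)
}

#' Mean clustering coefficient
#'
#' Average over nodes of the local clustering coefficient
#' `2 * triangles / (k (k - 1))`; nodes with degree < 2 contribute 0.
#'
#' @param A binary adjacency matrix (or igraph object).
#' @return Scalar in [0, 1].
#' @export
clustering_coefficient <- function(A) {
  g <- if (inherits(A, "igraph")) A else as_igraph(A)
  lc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  if (!length(lc)) return(0)
  mean(lc)
}

#' Characteristic path length
#'
#' Mean shortest-path length over connected node pairs only; disconnected
#' pairs are excluded from the average.
#'
#' @param A binary adjacency matrix (or igraph object).
#' @return Scalar; `NaN` when no pair is connected.
#' @export
path_length <- function(A) {
  g <- if (inherits(A, "igraph")) A else as_igraph(A)
  D <- igraph::distances(g)
  d <- D[upper.tri(D)]
  d <- d[is.finite(d) & d > 0]
  if (!length(d)) return(NaN)
  mean(d)
}

#' Global efficiency
#'
#' Mean of `1 / d(u, v)` over all ordered node pairs, with disconnected
#' pairs contributing 0.
#'
#' @param A binary adjacency matrix (or igraph object).
#' @return Scalar in [0, 1].
#' @export
global_efficiency <- function(A) {
  g <- if (inherits(A, "igraph")) A else as_igraph(A)
  D <- igraph::distances(g)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  n <- nrow(D)
  if (n < 2) return(0)
  sum(inv) / (n * (n - 1))
}

#' Clustering and path length of degree-preserving null networks
#'
#' Randomizes the graph by double-edge swaps that preserve the degree
#' sequence (`10 * |E|` attempted swaps per null network) and averages the
#' clustering coefficient and characteristic path length over `n_null`
#' realizations.
#'
#' @param A binary adjacency matrix.
#' @param n_null number of null networks (default 100).
#' @param seed integer seed.
#' @return List with `Cp_rand`, `Lp_rand`, `n_null`.
#' @export
null_metrics <- function(A, n_null = 100, seed = 0L) {
  g <- as_igraph(A)
  ne <- igraph::ecount(g)
  if (ne == 0L) return(list(Cp_rand = 0, Lp_rand = NaN, n_null = n_null))
  with_seed(seed, {
    cps <- numeric(n_null); lps <- numeric(n_null)
    for (b in seq_len(n_null)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * ne))
      cps[b] <- clustering_coefficient(gr)
      lps[b] <- path_length(gr)
    }
    list(Cp_rand = mean(cps), Lp_rand = mean(lps, na.rm = TRUE),
         n_null = n_null)
  })
}

#' Small-world indices
#'
#' Normalized clustering `gamma = Cp / Cp_rand`, normalized path length
#' `lambda = Lp / Lp_rand`, and the small-world coefficient
#' `sigma = gamma / lambda`. Values above 1 for `gamma` and `sigma` with
#' `lambda` near 1 indicate small-world organization.
#'
#' @param Cp,Lp observed clustering coefficient and path length.
#' @param Cp_rand,Lp_rand null-model averages (e.g. from [null_metrics()]).
#' @return List with `gamma`, `lambda`, `sigma`.
#' @export
small_world <- function(Cp, Lp, Cp_rand, Lp_rand) {
  gamma <- Cp / Cp_rand
  lambda <- Lp / Lp_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

#' Greedy modularity maximization
#'
#' Agglomerative (CNM-style) greedy modularity optimization: starting from
#' singleton communities, repeatedly merge the pair with the largest
#' modularity gain until no merge improves Q.
#'
#' @param A binary adjacency matrix (or igraph object).
#' @return List with `Q` (best modularity) and `membership` (integer
#'   community labels).
#' @export
modularity_greedy <- function(A) {
  g <- if (inherits(A, "igraph")) A else as_igraph(A)
  if (igraph::ecount(g) == 0L) {
    return(list(Q = 0, membership = seq_len(igraph::vcount(g))))
  }
  cl <- igraph::cluster_fast_greedy(g)
  ## cut the merge dendrogram at the modularity-maximizing step and report
  ## the Q of that partition (the stored membership can disagree on ties)
  best_step <- which.max(cl$modularity)
  n_comm <- igraph::vcount(g) - (best_step - 1L)
  memb <- igraph::cut_at(cl, no = n_comm)
  list(Q = igraph::modularity(g, memb), membership = as.integer(memb))
}

#' Degree-based hub detection
#'
#' Default rule: a node is a hub when its degree exceeds the mean degree by
#' more than `sd_mult` standard deviations. Returns hubs sorted by degree
#' descending (ties by node index).
#'
#' @param A binary adjacency matrix.
#' @param sd_mult number of standard deviations above the mean (default 1).
#' @return Data frame with `node`, `degree` for the detected hubs.
#' @export
find_hubs <- function(A, sd_mult = 1) {
  g <- as_igraph(A)
  deg <- igraph::degree(g)
  cutoff <- mean(deg) + sd_mult * stats::sd(deg)
  hubs <- which(deg > cutoff)
  ord <- hubs[order(-deg[hubs], hubs)]
  data.frame(node = as.integer(ord), degree = deg[ord], row.names = NULL)
}

#' Full topology report for one network
#'
#' Computes the global graph-theory profile of a binarized network:
#' clustering coefficient Cp, characteristic path length Lp, normalized
#' gamma and lambda against degree-preserving nulls, small-world sigma,
#' global efficiency, and greedy modularity Q.
#'
#' @param W weighted network matrix (binarized internally) or a 0/1 matrix.
#' @param rule,density binarization rule, see [binarize()].
#' @param n_null,seed null-model controls, see [null_metrics()].
#' @return Object of class `fbn_topology`: list with `Cp`, `Lp`,
#'   `gamma_norm`, `lambda_norm`, `sigma`, `Eglobal`, `Q`, `n_null`.
#' @export
topology_report <- function(W, rule = "nonzero", density = 0.2,
                            n_null = 100, seed = 0L) {
  A <- binarize(W, rule = rule, density = density)
  Cp <- clustering_coefficient(A)
  Lp <- path_length(A)
  Eg <- global_efficiency(A)
  Q <- modularity_greedy(A)$Q
  nm <- null_metrics(A, n_null = n_null, seed = seed)
  sw <- small_world(Cp, Lp, nm$Cp_rand, nm$Lp_rand)
  structure(list(Cp = Cp, Lp = Lp, gamma_norm = sw$gamma,
                 lambda_norm = sw$lambda, sigma = sw$sigma,
                 Eglobal = Eg, Q = Q, n_null = n_null),
            class = "fbn_topology")
}

#' Per-group topology summary with group comparison
#'
#' Mean and standard deviation of every topology metric per class, with a
#' pooled two-sample t-test per metric and a significance flag at p < 0.01.
#'
#' @param reports list of `fbn_topology` objects (one per subject).
#' @param labels 0/1 class labels matching `reports`.
#' @return Data frame: metric, per-class mean and sd, t-test p-value,
#'   significance flag.
#' @export
group_topology <- function(reports, labels) {
  labels <- as.integer(labels)
  metrics <- c("Cp", "Lp", "gamma_norm", "lambda_norm", "sigma", "Eglobal", "Q")
  rows <- lapply(metrics, function(m) {
    v <- vapply(reports, function(r) as.numeric(r[[m]]), numeric(1))
    v0 <- v[labels == 0L]; v1 <- v[labels == 1L]
    p <- tryCatch(stats::t.test(v1, v0, var.equal = TRUE)$p.value,
                  error = function(e) NA_real_)
    data.frame(metric = m,
               mean_class0 = mean(v0), sd_class0 = stats::sd(v0),
               mean_class1 = mean(v1), sd_class1 = stats::sd(v1),
               p_value = p, significant = !is.na(p) & p < 0.01)
  })
  do.call(rbind, rows)
}
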