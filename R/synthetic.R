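#' Ground-truth networks for a two-class synthetic cohort
#'
#' Builds symmetric zero-diagonal ground-truth networks with a shared
#' within-class backbone, subject-level jitter on backbone edges, and a set
#' of class-differential edges present only in class 1. Edge magnitudes are
#' drawn with random signs so the implied precision matrices stay well
#' conditioned; if any subject's precision matrix (see [simulate_bold()])
#' would fall below the positive-definiteness margin, the whole cohort is
#' rescaled by one common factor so class contrasts are preserved.
#'
#' @param n_rois number of ROIs (nodes) `N`.
#' @param n_per_class integer vector `c(K0, K1)` of subjects per class.
#' @param backbone_density fraction of the `N(N-1)/2` possible edges in the
#'   shared backbone.
#' @param jitter standard deviation of the per-subject Gaussian perturbation
#'   added to each backbone edge weight.
#' @param n_diff_edges number of extra edges present only in class 1.
#' @param effect_size weight magnitude of the differential edges.
#' @param seed integer seed; every draw is reproducible from it.
#' @return List of class `fbn_cohort_truth`: `networks` (`N x N x K` array),
#'   `labels` (0/1), `backbone` (edge-index matrix of the shared backbone),
#'   `diff_edges` (edge-index matrix of differential edges), `support`
#'   (per-class logical edge vectors), and the generating parameters.
#' @export
make_group_networks <- function(n_rois = 20, n_per_class = c(20, 20),
                                backbone_density = 0.1, jitter = 0.1,
                                n_diff_edges = 8, effect_size = 0.35,
                                seed = 0L) {
  stopifnot(n_rois >= 2, length(n_per_class) == 2, all(n_per_class >= 1),
            backbone_density > 0, backbone_density <= 1,
            jitter >= 0, n_diff_edges >= 0, effect_size >= 0)
  pairs <- upper_pairs(n_rois)
  P <- nrow(pairs)
  n_backbone <- ceiling(backbone_density * P)
  if (n_backbone + n_diff_edges > P) {
    stop("backbone_density plus n_diff_edges exceeds the available edges")
  }
  K <- sum(n_per_class)
  labels <- rep(c(0L, 1L), times = n_per_class)

  with_seed(seed, {
    picked <- sample.int(P, n_backbone + n_diff_edges)
    backbone_idx <- picked[seq_len(n_backbone)]
    diff_idx <- if (n_diff_edges > 0) picked[n_backbone + seq_len(n_diff_edges)]
                else integer(0)
    base_w <- sample(c(-1, 1), n_backbone, replace = TRUE) *
      stats::runif(n_backbone, 0.25, 0.45)
    diff_w <- rep(effect_size, n_diff_edges) *
      sample(c(-1, 1), n_diff_edges, replace = TRUE)

    networks <- array(0, dim = c(n_rois, n_rois, K))
    for (k in seq_len(K)) {
      v <- numeric(P)
      v[backbone_idx] <- base_w + stats::rnorm(n_backbone, 0, jitter)
      if (labels[k] == 1L && n_diff_edges > 0) {
        v[diff_idx] <- diff_w + stats::rnorm(n_diff_edges, 0, jitter)
      }
      networks[, , k] <- upper_unvec(v, n_rois)
    }
    list(networks = networks, backbone_idx = backbone_idx, diff_idx = diff_idx)
  }) -> g

  ## common rescale so every subject's shifted precision matrix keeps a
  ## positive-definiteness margin (min eigenvalue > 0.05)
  margin <- function(W) {
    ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
    c_shift <- abs(min(ev)) + 0.5
    c_shift - max(ev)
  }
  scale_f <- 1
  margins <- apply(g$networks, 3, margin)
  if (min(margins) <= 0.05) {
    f_k <- vapply(seq_len(K), function(k) {
      W <- g$networks[, , k]
      ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
      spread <- max(ev) - abs(min(ev))      # margin(fW) = 0.5 - f * spread
      if (spread <= 0) Inf else 0.44 / spread
    }, numeric(1))
    scale_f <- min(1, min(f_k))
    g$networks <- g$networks * scale_f
  }

  structure(list(
    networks = g$networks,
    labels = labels,
    backbone = pairs[g$backbone_idx, , drop = FALSE],
    diff_edges = pairs[g$diff_idx, , drop = FALSE],
    support = list(
      class0 = seq_len(P) %in% g$backbone_idx,
      class1 = seq_len(P) %in% c(g$backbone_idx, g$diff_idx)),
    n_rois = n_rois, n_per_class = n_per_class,
    backbone_density = backbone_density, jitter = jitter,
    n_diff_edges = n_diff_edges, effect_size = effect_size,
    scale_factor = scale_f, seed = as.integer(seed)),
    class = "fbn_cohort_truth")
}

#' Simulate ROI time series from a ground-truth network
#'
#' Draws `T` i.i.d. samples from a zero-mean multivariate normal whose
#' precision matrix is `Omega = c I - W` with `c = |min eigenvalue of W| +
#' 0.5`. Off-diagonal precision entries are proportional to the network
#' weights, so regression-based (partial-correlation) estimators recover the
#' network support; the population partial correlation of an isolated
#' two-node edge with weight `w` is `w / c`. Samples are i.i.d. in time —
#' temporal autocorrelation is deliberately not modeled.
#'
#' @param W_true symmetric `N x N` network with zero diagonal.
#' @param n_time number of time points `T`.
#' @param seed integer seed.
#' @return `T x N` matrix of signals.
#' @export
simulate_bold <- function(W_true, n_time, seed = 0L) {
  stopifnot(is.matrix(W_true), nrow(W_true) == ncol(W_true), n_time >= 2)
  if (max(abs(W_true - t(W_true))) > 1e-10 || any(diag(W_true) != 0)) {
    stop("W_true must be symmetric with zero diagonal")
  }
  N <- nrow(W_true)
  ev <- eigen(W_true, symmetric = TRUE, only.values = TRUE)$values
  c_shift <- abs(min(ev)) + 0.5
  Omega <- diag(c_shift, N) - W_true
  if (min(c_shift - ev) <= 1e-8) {
    stop("precision matrix is not positive definite after the c-shift")
  }
  Sigma <- chol2inv(chol(Omega))
  R <- chol(Sigma)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_time * N), n_time, N)
    Z %*% R
  })
}

#' Generate a complete synthetic cohort
#'
#' Composes [make_group_networks()] and [simulate_bold()] into a cohort of
#' per-subject time series with known ground truth; optionally writes the
#' on-disk layout the estimation front ends consume (per-subject CSVs, a
#' `manifest.csv` with columns `subject_id,label,path`, and a
#' `ground_truth.json` edge-list sidecar).
#'
#' @param n_rois,n_per_class,backbone_density,jitter,n_diff_edges,effect_size
#'   forwarded to [make_group_networks()].
#' @param n_time time points per subject.
#' @param seed master seed (networks and signals derive sub-seeds from it).
#' @param dir optional output directory; created if missing.
#' @return Object of class `fbn_cohort`: the truth object plus `signals`
#'   (list of `T x N` matrices), `n_time`, and `dir` when written.
#' @export
make_cohort <- function(n_rois = 20, n_per_class = c(20, 20), n_time = 150,
                        backbone_density = 0.1, jitter = 0.1,
                        n_diff_edges = 8, effect_size = 0.35,
                        seed = 0L, dir = NULL) {
  truth <- make_group_networks(n_rois = n_rois, n_per_class = n_per_class,
                               backbone_density = backbone_density,
                               jitter = jitter, n_diff_edges = n_diff_edges,
                               effect_size = effect_size, seed = seed)
  K <- sum(n_per_class)
  signals <- lapply(seq_len(K), function(k) {
    simulate_bold(truth$networks[, , k], n_time,
                  seed = as.numeric(seed) * 1000 + k)
  })
  cohort <- structure(c(truth, list(signals = signals, n_time = n_time)),
                      class = c("fbn_cohort", "fbn_cohort_truth"))
  if (!is.null(dir)) {
    write_cohort(cohort, dir)
    cohort$dir <- dir
  }
  cohort
}
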