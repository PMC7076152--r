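#' Edge features from a stack of networks
#'
#' Each subject's finalized (symmetrized, zero-diagonal) network contributes
#' the `P = N(N-1)/2` strict upper-triangle weights, in fixed row-major
#' (i < j) order, as one feature row.
#'
#' @param W `N x N x K` array of estimated networks.
#' @param labels length-`K` class labels (0/1).
#' @return Object of class `fbn_features`: list with `X` (`K x P` matrix),
#'   `labels`, `edge_index` (`P x 2` matrix mapping feature to (i, j)), `n_rois`.
#' @export
extract_features <- function(W, labels) {
  stopifnot(length(dim(W)) == 3L, dim(W)[1] == dim(W)[2],
            length(labels) == dim(W)[3])
  N <- dim(W)[1]
  K <- dim(W)[3]
  pairs <- upper_pairs(N)
  X <- matrix(0, K, nrow(pairs))
  for (k in seq_len(K)) X[k, ] <- upper_vec(finalize_network(W[, , k]))
  structure(list(X = X, labels = as.integer(labels), edge_index = pairs,
                 n_rois = N),
            class = "fbn_features")
}

#' Two-sample t-test feature filter
#'
#' Classical pooled-variance two-sided t-test per feature between the two
#' classes; features with `p < p_threshold` are selected. No
#' multiple-testing correction is applied (the filter is deliberately the
#' simplest one). Features with zero pooled variance are excluded.
#'
#' @param X `S x P` feature matrix (training rows only).
#' @param labels length-`S` 0/1 labels; both classes must be present.
#' @param p_threshold selection threshold on the p-value (default 0.01).
#' @return Logical mask of length `P`; attribute `"p_values"` carries the
#'   per-feature p-values (NA where degenerate).
#' @export
ttest_select <- function(X, labels, p_threshold = 0.01) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in the training rows")
  }
  i0 <- labels == 0L; i1 <- labels == 1L
  n0 <- sum(i0); n1 <- sum(i1)
  m0 <- colMeans(X[i0, , drop = FALSE]); m1 <- colMeans(X[i1, , drop = FALSE])
  v0 <- apply(X[i0, , drop = FALSE], 2L, stats::var)
  v1 <- apply(X[i1, , drop = FALSE], 2L, stats::var)
  sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
  se <- sqrt(sp2 * (1 / n0 + 1 / n1))
  tstat <- (m1 - m0) / se
  p <- 2 * stats::pt(abs(tstat), df = n0 + n1 - 2, lower.tail = FALSE)
  p[!is.finite(se) | se < 1e-300] <- NA_real_
  mask <- !is.na(p) & p < p_threshold
  attr(mask, "p_values") <- p
  mask
}

#' Confusion-matrix metrics on the percent scale
#'
#' @param TP,FP,TN,FN nonnegative confusion counts.
#' @return List with `accuracy`, `sensitivity`, `specificity` (percent) and
#'   the counts.
#' @export
confusion_metrics <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0, TP + FP + TN + FN > 0)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       accuracy = 100 * (TP + TN) / (TP + FP + TN + FN),
       sensitivity = if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_,
       specificity = if (TN + FP > 0) 100 * TN / (TN + FP) else NA_real_)
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps a threshold over the scores (higher score = more likely class 1)
#' and accumulates the trapezoidal area under the (FPR, TPR) curve.
#'
#' @param scores numeric decision values.
#' @param labels 0/1 labels.
#' @return List with `roc` (data frame of threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("both classes required for ROC")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nn, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

## One outer fold: t-test selection, training-statistics z-scoring, linear
## SVM (C = cost), prediction on the held-out row. All statistics are
## computed from the training rows only. Returns prediction, decision score
## (oriented so larger = class 1), the selection mask and p-values.
fit_fold <- function(train_X, train_y, test_X, p_threshold = 0.01, cost = 1) {
  mask <- ttest_select(train_X, train_y, p_threshold)
  pvals <- attr(mask, "p_values")
  err <- NULL
  if (!any(mask)) {
    ## nothing passes the filter: train on all (non-degenerate) features
    ## instead. A majority vote would oppose the held-out label in balanced
    ## leave-one-out folds, and picking the single best sub-threshold feature
    ## maximizes selection overfit; skipping the filter keeps the fold close
    ## to chance when there is genuinely no signal.
    if (all(is.na(pvals))) {
      return(list(pred = 0L, score = 0, mask = mask, p_values = pvals,
                  error = "all features degenerate"))
    }
    mask <- !is.na(pvals)
    err <- "no features below threshold; filter skipped for this fold"
  }
  Xtr <- train_X[, mask, drop = FALSE]
  Xte <- matrix(test_X[mask], nrow = 1L)
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xtr <- sweep(sweep(Xtr, 2L, mu, "-"), 2L, sdv, "/")
  Xte <- sweep(sweep(Xte, 2L, mu, "-"), 2L, sdv, "/")
  fit <- e1071::svm(Xtr, factor(train_y, levels = c(0, 1)),
                    kernel = "linear", cost = cost, scale = FALSE)
  dv <- attr(stats::predict(fit, Xte, decision.values = TRUE),
             "decision.values")
  ## orient the decision value so positive means class 1 (e1071 reports the
  ## margin in favor of the first class named in the column label)
  score <- if (grepl("^0", colnames(dv)[1])) -dv[1, 1] else dv[1, 1]
  pred <- as.integer(as.character(stats::predict(fit, Xte)))
  list(pred = pred, score = score, mask = mask, p_values = pvals, error = err)
}

## Inner LOOCV accuracy of the selection + SVM pipeline on a feature matrix.
inner_loocv_accuracy <- function(X, y, p_threshold = 0.01, cost = 1) {
  S <- nrow(X)
  correct <- 0L
  for (s in seq_len(S)) {
    yt <- y[-s]
    if (length(unique(yt)) < 2L) next
    f <- fit_fold(X[-s, , drop = FALSE], yt, X[s, ], p_threshold, cost)
    correct <- correct + as.integer(f$pred == y[s])
  }
  correct / S
}

#' Nested leave-one-out cross-validated classification
#'
#' Outer LOOCV over subjects with an inner LOOCV grid search for
#' hyper-parameters, mirroring the standard connectome-classification
#' protocol: per-feature t-test filtering (`p < 0.01`), per-fold z-scoring
#' by training statistics, and a linear SVM with `C = 1`.
#'
#' Three input modes:
#' \describe{
#'   \item{feature matrix}{`x` is an [extract_features()] object (or plain
#'     matrix with `labels`); no hyper-parameter grid, each outer fold runs
#'     selection + SVM directly.}
#'   \item{per-subject estimators}{`method` in `pc`, `pc_thresh`, `sr`,
#'     `slr`: networks depend only on each subject's own signals, so each
#'     grid point's networks are estimated once; the inner LOOCV (training
#'     rows only) scores the grid.}
#'   \item{group estimators}{`method` in `gsr`, `tlr`, `stlr`: for every
#'     outer fold and grid point the joint estimation is re-run on the
#'     training subjects only; after the grid choice the held-out subject's
#'     network is estimated by appending its (label-free) signals to the
#'     training cohort and taking its slice of the joint solve, so the
#'     selection and classifier never see the test label.}
#' }
#'
#' Grid ties are broken toward weaker regularization (smallest
#' `lambda_sparse`, then smallest `gamma_lowrank`; largest `sparsity_keep`
#' for thresholded correlation).
#'
#' @param x feature object/matrix, or list of per-subject `T x N` signal
#'   matrices.
#' @param labels 0/1 labels (taken from `x` when it is an `fbn_features`).
#' @param method estimation method, or `"features"` for precomputed features.
#' @param lambda_grid,gamma_grid,keep_grid candidate hyper-parameter values
#'   (powers of two as numerics; `keep_grid` are edge-keep fractions).
#' @param cfg base [solver_config()] for the estimators.
#' @param p_threshold t-test selection threshold.
#' @param cost linear SVM cost parameter.
#' @return Object of class `fbn_classification`: confusion counts, percent
#'   metrics, `roc`/`auc`, per-fold chosen parameters, per-fold masks and
#'   p-values, per-fold errors.
#' @export
loocv_classify <- function(x, labels = NULL, method = "features",
                           lambda_grid = 2^(-5:5), gamma_grid = 2^(-5:5),
                           keep_grid = seq(0.05, 1, by = 0.05),
                           cfg = solver_config(), p_threshold = 0.01,
                           cost = 1) {
  method <- match.arg(method, c("features", "pc", "pc_thresh", "sr", "slr",
                                "gsr", "tlr", "stlr"))
  if (inherits(x, "fbn_features")) {
    labels <- x$labels
    feats <- x$X
  } else if (is.matrix(x) && method == "features") {
    feats <- x
  }
  if (is.null(labels)) stop("labels are required")
  labels <- as.integer(labels)
  S <- length(labels)
  if (S < 4L) stop("need at least 4 subjects for nested LOOCV")
  if (length(unique(labels)) < 2L) stop("both classes must be present")

  per_subject <- method %in% c("pc", "pc_thresh", "sr", "slr")
  group <- method %in% c("gsr", "tlr", "stlr")

  grid <- switch(method,
    features = data.frame(dummy = 0),
    pc = data.frame(dummy = 0),
    pc_thresh = data.frame(keep = keep_grid),
    sr = data.frame(lambda = lambda_grid),
    gsr = data.frame(lambda = lambda_grid),
    tlr = data.frame(gamma = gamma_grid),
    slr = expand.grid(lambda = lambda_grid, gamma = gamma_grid),
    stlr = expand.grid(lambda = lambda_grid, gamma = gamma_grid))

  cfg_for <- function(g) {
    cc <- cfg
    if (!is.null(g$lambda)) {
      if (method == "gsr") cc$lambda_group <- g$lambda
      else cc$lambda_sparse <- g$lambda
    }
    if (!is.null(g$gamma)) cc$gamma_lowrank <- g$gamma
    cc
  }

  ## features for every subject at each grid point (per-subject methods:
  ## estimation is label-free and subject-independent, so computed once)
  if (per_subject || method == "pc") {
    feat_by_grid <- lapply(seq_len(nrow(grid)), function(gi) {
      g <- as.list(grid[gi, , drop = FALSE])
      W <- estimate_cohort(x, method, cfg = cfg_for(g),
                           sparsity_keep = g$keep %||% 1.0)
      extract_features(W, labels)$X
    })
  }

  ## grid preference order for tie-breaking: weaker regularization first
  pref <- switch(method,
    pc_thresh = order(-grid$keep),
    sr = , gsr = order(grid$lambda),
    tlr = order(grid$gamma),
    slr = , stlr = order(grid$lambda, grid$gamma),
    seq_len(nrow(grid)))

  preds <- integer(S); scores <- numeric(S)
  fold_params <- vector("list", S)
  fold_masks <- vector("list", S)
  fold_pvals <- vector("list", S)
  fold_errors <- vector("list", S)

  for (s in seq_len(S)) {
    train_idx <- setdiff(seq_len(S), s)
    ytr <- labels[train_idx]
    res <- tryCatch({
      if (method == "features") {
        f <- fit_fold(feats[train_idx, , drop = FALSE], ytr, feats[s, ],
                      p_threshold, cost)
        list(fold = f, params = list())
      } else if (per_subject || method == "pc") {
        best_gi <- pref[1]
        if (nrow(grid) > 1L) {
          acc <- rep(NA_real_, nrow(grid))
          for (gi in seq_len(nrow(grid))) {
            Xg <- feat_by_grid[[gi]][train_idx, , drop = FALSE]
            acc[gi] <- inner_loocv_accuracy(Xg, ytr, p_threshold, cost)
          }
          best_gi <- pref[which.max(acc[pref])]
        }
        Xg <- feat_by_grid[[best_gi]]
        f <- fit_fold(Xg[train_idx, , drop = FALSE], ytr, Xg[s, ],
                      p_threshold, cost)
        list(fold = f, params = as.list(grid[best_gi, , drop = FALSE]))
      } else {
        ## group estimator: re-estimate per fold on training subjects
        train_sig <- x[train_idx]
        acc <- rep(NA_real_, nrow(grid))
        feats_tr <- vector("list", nrow(grid))
        for (gi in seq_len(nrow(grid))) {
          Wg <- estimate_cohort(train_sig, method,
                                cfg = cfg_for(as.list(grid[gi, , drop = FALSE])))
          feats_tr[[gi]] <- extract_features(Wg, ytr)$X
          acc[gi] <- if (nrow(grid) > 1L) {
            inner_loocv_accuracy(feats_tr[[gi]], ytr, p_threshold, cost)
          } else 1
        }
        best_gi <- pref[which.max(acc[pref])]
        ## joint re-estimation with the held-out subject appended (its
        ## signals only; no label enters selection or training)
        Wall <- estimate_cohort(c(train_sig, x[s]), method,
                                cfg = cfg_for(as.list(grid[best_gi, , drop = FALSE])))
        Xtr <- extract_features(Wall[, , seq_along(train_idx), drop = FALSE],
                                ytr)$X
        xte <- upper_vec(finalize_network(Wall[, , length(train_idx) + 1L]))
        f <- fit_fold(Xtr, ytr, xte, p_threshold, cost)
        list(fold = f, params = as.list(grid[best_gi, , drop = FALSE]))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fold_errors[[s]] <- conditionMessage(res)
      preds[s] <- as.integer(names(which.max(table(ytr))))
      scores[s] <- 0
      next
    }
    preds[s] <- res$fold$pred
    scores[s] <- res$fold$score
    fold_params[[s]] <- res$params
    fold_masks[[s]] <- res$fold$mask
    fold_pvals[[s]] <- res$fold$p_values
    fold_errors[[s]] <- res$fold$error
  }

  TP <- sum(preds == 1L & labels == 1L)
  TN <- sum(preds == 0L & labels == 0L)
  FP <- sum(preds == 1L & labels == 0L)
  FN <- sum(preds == 0L & labels == 1L)
  metrics <- confusion_metrics(TP, FP, TN, FN)
  roc <- roc_auc(scores, labels)
  structure(c(metrics,
              list(predictions = preds, scores = scores, labels = labels,
                   roc = roc$roc, auc = roc$auc, fold_params = fold_params,
                   fold_masks = fold_masks, fold_pvals = fold_pvals,
                   fold_errors = fold_errors, method = method)),
            class = "fbn_classification")
}

#' Consensus discriminative connections across folds
#'
#' Edges selected by the t-test filter in every outer fold (set
#' intersection), ranked by their mean p-value across folds. Also reports
#' the mean and variance of the per-fold selected-feature counts.
#'
#' @param masks list of per-fold logical selection masks (equal length).
#' @param pvals list of per-fold p-value vectors.
#' @param edge_index optional `P x 2` matrix mapping features to (i, j).
#' @return Data frame with columns `feature`, `i`, `j`, `mean_p`, sorted by
#'   `mean_p`; attributes `"n_selected_mean"` and `"n_selected_var"`.
#' @export
consensus_connections <- function(masks, pvals, edge_index = NULL) {
  masks <- masks[!vapply(masks, is.null, logical(1))]
  if (!length(masks)) stop("no fold masks supplied")
  M <- do.call(rbind, lapply(masks, as.logical))
  counts <- rowSums(M)
  consensus <- which(colSums(M) == nrow(M))
  Pm <- do.call(rbind, pvals[!vapply(pvals, is.null, logical(1))])
  mean_p <- if (length(consensus)) colMeans(Pm[, consensus, drop = FALSE])
            else numeric(0)
  ord <- order(mean_p)
  out <- data.frame(feature = consensus[ord],
                    i = if (is.null(edge_index)) NA_integer_
                        else edge_index[consensus[ord], 1],
                    j = if (is.null(edge_index)) NA_integer_
                        else edge_index[consensus[ord], 2],
                    mean_p = mean_p[ord])
  attr(out, "n_selected_mean") <- mean(counts)
  attr(out, "n_selected_var") <- stats::var(counts)
  out
}

#' Rank nodes by their number of consensus connections
#'
#' @param consensus data frame from [consensus_connections()] with `i`, `j`.
#' @param n_rois total number of nodes.
#' @param top number of top nodes to return (default all with >= 1 edge).
#' @return Data frame `node`, `degree`, ranked by degree descending, ties by
#'   node index.
#' @export
region_degree_ranking <- function(consensus, n_rois, top = Inf) {
  if (nrow(consensus) == 0L) {
    return(data.frame(node = integer(0), degree = integer(0)))
  }
  deg <- tabulate(c(consensus$i, consensus$j), nbins = n_rois)
  keep <- which(deg > 0)
  ord <- keep[order(-deg[keep], keep)]
  if (is.finite(top)) ord <- utils::head(ord, top)
  data.frame(node = ord, degree = deg[ord])
}
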