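test_that("edge features enumerate the strict upper triangle in fixed order", {
  W <- array(0, c(3, 3, 2))
  W[1, 2, 1] <- 1; W[2, 1, 1] <- 1
  W[1, 3, 1] <- 2; W[3, 1, 1] <- 2
  W[2, 3, 1] <- 3; W[3, 2, 1] <- 3
  fe <- extract_features(W, c(0, 1))
  expect_equal(fe$X[1, ], c(1, 2, 3))
  expect_equal(fe$edge_index,
               cbind(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L)))
  # bijection: features reconstruct the symmetric slice
  rec <- stlrnet:::upper_unvec(fe$X[1, ], 3)
  expect_equal(rec, W[, , 1])
  # feature count formula at atlas scale
  expect_equal(nrow(stlrnet:::upper_pairs(116)), 6670)
})

test_that("t-test selection matches the classical pooled test", {
  set.seed(71)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- rep(c(0, 1), each = 10)
  X[y == 1, 3] <- X[y == 1, 3] + 3
  mask <- ttest_select(X, y, 0.01)
  p <- attr(mask, "p_values")
  for (j in 1:8) {
    ref <- stats::t.test(X[y == 1, j], X[y == 0, j], var.equal = TRUE)$p.value
    expect_equal(p[j], ref, tolerance = 1e-12)
  }
  expect_true(mask[3])
  # constant feature is excluded, not an error
  X[, 5] <- 1
  mask2 <- ttest_select(X, y, 0.01)
  expect_false(mask2[5])
  expect_true(is.na(attr(mask2, "p_values")[5]))
  # near-deterministic label feature is selected
  X[, 1] <- y + rnorm(20, sd = 1e-3)
  expect_true(ttest_select(X, y)[1])
  expect_error(ttest_select(X, rep(0, 20)), "both classes")
})

test_that("confusion metrics follow their percent-scale definitions", {
  m <- confusion_metrics(1, 0, 1, 0)
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity), c(100, 100, 100))
  m <- confusion_metrics(TP = 63, FP = 6, TN = 63, FN = 5)
  expect_equal(m$accuracy, 100 * 126 / 137, tolerance = 1e-12)
  expect_equal(round(m$sensitivity, 2), 92.65)
  expect_equal(round(m$specificity, 2), 91.30)
  m <- confusion_metrics(TP = 60, FP = 15, TN = 54, FN = 8)
  expect_equal(round(m$accuracy, 2), 83.21)
})

test_that("ROC and AUC behave on perfect, reversed and random rankings", {
  y <- rep(c(0, 1), each = 5)
  expect_equal(roc_auc(c(1:5, 6:10), y)$auc, 1.0)
  expect_equal(roc_auc(c(6:10, 1:5), y)$auc, 0.0)
  set.seed(73)
  y <- rbinom(200, 1, 0.5)
  r <- roc_auc(rnorm(200), y)
  expect_lt(abs(r$auc - 0.5), 0.1)
  expect_true(all(diff(r$roc$tpr) >= 0))
  expect_true(all(diff(r$roc$fpr) >= 0))
  # independent oracle
  skip_if_not_installed("pROC")
  sc <- rnorm(200)
  expect_equal(roc_auc(sc, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("LOOCV is perfect on separable features and chance on permuted nulls", {
  set.seed(79)
  S <- 20; P <- 30
  X <- matrix(rnorm(S * P), S, P)
  y <- rep(c(0L, 1L), each = S / 2)
  X[, 1] <- y * 4 + rnorm(S, sd = 0.1)
  rep1 <- loocv_classify(X, y, method = "features")
  expect_equal(rep1$accuracy, 100)
  expect_equal(rep1$TP + rep1$TN + rep1$FP + rep1$FN, S)
  expect_equal(rep1$accuracy,
               confusion_metrics(rep1$TP, rep1$FP, rep1$TN, rep1$FN)$accuracy)

  # permuted labels on pure-noise features: accuracy within the chance band
  accs <- vapply(1:3, function(s) {
    set.seed(400 + s)
    Xn <- matrix(rnorm(S * P), S, P)
    yn <- sample(y)
    loocv_classify(Xn, yn, method = "features")$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 15)
})

test_that("per-fold pipeline never touches the held-out row", {
  # leakage canary: a feature that is noise on the training rows but encodes
  # the label on the held-out row must not lift accuracy above chance
  set.seed(83)
  S <- 20; P <- 40
  X <- matrix(rnorm(S * P), S, P)
  y <- rep(c(0L, 1L), S / 2)
  correct <- 0L
  for (s in seq_len(S)) {
    canary_train <- rnorm(S - 1)
    Xtr <- cbind(X[-s, ], canary_train)
    xte <- c(X[s, ], y[s] * 10 - 5)
    f <- stlrnet:::fit_fold(Xtr, y[-s], xte, p_threshold = 0.05, cost = 1)
    correct <- correct + as.integer(f$pred == y[s])
  }
  expect_lt(abs(100 * correct / S - 50), 30)  # binomial band at S = 20
})

test_that("nested LOOCV with per-subject estimation picks grid points honestly", {
  set.seed(89)
  co <- make_cohort(n_rois = 8, n_per_class = c(5, 5), n_time = 100,
                    jitter = 0.05, n_diff_edges = 4, effect_size = 0.6,
                    seed = 21)
  rep <- loocv_classify(co$signals, co$labels, method = "sr",
                        lambda_grid = c(2^-4, 2^-3))
  expect_gte(rep$accuracy, 70)
  expect_true(all(vapply(rep$fold_params, function(p)
    p$lambda %in% c(2^-4, 2^-3), logical(1))))
  expect_equal(length(rep$predictions), 10)
})

test_that("consensus connections are the across-fold intersection", {
  m1 <- c(TRUE, TRUE, FALSE, TRUE)
  m2 <- c(TRUE, FALSE, FALSE, TRUE)
  p1 <- c(0.001, 0.5, 0.9, 0.004)
  p2 <- c(0.003, 0.6, 0.8, 0.002)
  idx <- stlrnet:::upper_pairs(4)[1:4, ]
  cons <- consensus_connections(list(m1, m2), list(p1, p2), idx)
  expect_equal(cons$feature, c(1L, 4L))   # ranked by mean p ascending
  expect_equal(attr(cons, "n_selected_mean"), 2.5)
  expect_equal(attr(cons, "n_selected_var"), 0.5)
  # identical masks: intersection is the mask
  cons2 <- consensus_connections(list(m1, m1), list(p1, p1), idx)
  expect_equal(cons2$feature, c(1L, 4L, 2L))
  # one empty mask empties the consensus
  cons3 <- consensus_connections(list(m1, rep(FALSE, 4)), list(p1, p2), idx)
  expect_equal(nrow(cons3), 0)
})

test_that("planted differential edges surface in the consensus", {
  set.seed(97)
  S <- 24; P <- 45
  X <- matrix(rnorm(S * P), S, P)
  y <- rep(c(0L, 1L), each = S / 2)
  planted <- c(3, 17, 30)
  for (f in planted) X[y == 1, f] <- X[y == 1, f] + 3
  rep <- loocv_classify(X, y, method = "features")
  cons <- consensus_connections(rep$fold_masks, rep$fold_pvals,
                                stlrnet:::upper_pairs(10))
  expect_true(all(planted %in% cons$feature))
})

test_that("region ranking counts incident consensus edges", {
  cons <- data.frame(feature = 1:3, i = c(1L, 1L, 1L), j = c(2L, 3L, 4L),
                     mean_p = c(0.001, 0.002, 0.003))
  r <- region_degree_ranking(cons, n_rois = 5)
  expect_equal(r$node[1], 1L)      # star hub first
  expect_equal(r$degree[1], 3L)
  expect_equal(nrow(region_degree_ranking(cons[0, ], 5)), 0)
  # edges concentrated on three nodes put them on top
  cons2 <- data.frame(feature = 1:4, i = c(1L, 1L, 2L, 2L),
                      j = c(2L, 3L, 3L, 4L), mean_p = rep(0.001, 4))
  r2 <- region_degree_ranking(cons2, n_rois = 6)
  expect_equal(sort(r2$node[1:3]), c(1L, 2L, 3L))
})
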