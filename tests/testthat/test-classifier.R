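# Scaling, splits, the two classifiers, cross-validation, ROC and the
# operating threshold.

test_that("scaler standardizes with training statistics only", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  sc <- fit_scaler(x)
  xs <- apply_scaler(sc, x)
  expect_equal(xs[, "a"], c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(xs[, "b"], c(0, 0, 0))       # constant column rule
  expect_true(sc$constant[["b"]])

  # held-out rows transformed with TRAIN parameters, not their own stats
  held <- cbind(a = c(10, 20), b = c(7, 9))
  hs <- apply_scaler(sc, held)
  expect_equal(hs[, "a"], (c(10, 20) - 2) / sc$sd[["a"]])
  expect_error(apply_scaler(sc, cbind(b = 1, a = 2)), "match")
})

test_that("train/test split is stratified, exhaustive and deterministic", {
  y <- rep(c(0L, 1L), c(6, 3))
  sp <- split_train_test(y, seed = 4)
  expect_length(sp$train, 6L)
  expect_length(sp$test, 3L)
  expect_setequal(c(sp$train, sp$test), 1:9)
  expect_identical(sp, split_train_test(y, seed = 4))

  # proportions preserved within one sample across random label mixes
  set.seed(9)
  for (i in 1:10) {
    n <- sample(30:200, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    sp <- split_train_test(y, seed = i)
    expect_length(sp$train, round(2 * n / 3))
    frac_all <- mean(y)
    expect_lte(abs(sum(y[sp$train]) - frac_all * length(sp$train)), 1)
  }
  expect_error(split_train_test(rep(1L, 10), seed = 1), "both classes")
})

test_that("k-fold assignment partitions, balances and stratifies", {
  y <- rep(c(0L, 1L), each = 50)
  f <- kfold_indices(y, k = 10, seed = 2)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(tabulate(f) == 10))
  # stratified: each fold has both classes
  expect_true(all(vapply(1:10, function(k) length(unique(y[f == k])), 1L)
                  == 2L))
  # n = 23, k = 10: sizes in {2, 3} (pigeonhole)
  f23 <- kfold_indices(rep(c(0L, 1L), c(11, 12)), k = 10, seed = 5)
  expect_true(all(tabulate(f23, 10) %in% c(2L, 3L)))
  expect_warning(kfold_indices(rep(c(0L, 1L), c(3, 47)), k = 10, seed = 1),
                 "fewer members")
})

test_that("lasso recovers the informative features and kills noise", {
  set.seed(21)
  n <- 500
  X <- matrix(rnorm(n * 22), n)
  colnames(X) <- c("inf1", "inf2", paste0("noise", 1:20))
  eta <- 1.5 * X[, 1] - 1.5 * X[, 2]
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  m <- train_lasso_logistic(X, y, seed = 22)
  td <- tidy(m)
  expect_true(all(td$coefficient[td$feature %in% c("inf1", "inf2")] != 0))
  noise_beta <- td$coefficient[grepl("^noise", td$feature)]
  expect_gte(mean(noise_beta == 0), 0.8)
  # |coefficient| ranking puts the two informative features on top
  expect_setequal(td$feature[td$rank <= 2], c("inf1", "inf2"))
  expect_error(train_lasso_logistic(X, rep(1L, n)), "both classes")
})

test_that("the penalty-infinity limit zeroes every coefficient", {
  set.seed(5)
  X <- matrix(rnorm(200), 100)
  colnames(X) <- c("a", "b")
  y <- rbinom(100, 1, 0.5)
  m <- train_lasso_logistic(X, y, seed = 6)
  big <- glmnet::glmnet(X, y, family = "binomial", lambda = 1e6)
  expect_true(all(as.numeric(big$beta) == 0))
  expect_true(is.numeric(m$coefficients))
})

test_that("the RBF-SVM separates blobs, calibrates monotonically, nulls out", {
  bl <- make_blobs(n = 200, sep = 3, seed = 31)
  m <- train_svm_rbf(bl$X, bl$y, seed = 32)
  expect_equal(mean(predict(m, bl$X, type = "class") == bl$y), 1.0)
  # probability is monotone in the decision value
  f <- predict(m, bl$X, type = "decision")
  p <- predict(m, bl$X, type = "prob")
  expect_true(all(diff(p[order(f)]) >= 0))
  expect_true(all(p >= 0 & p <= 1))

  # label-permuted data: 10-fold CV AUC near chance
  set.seed(33)
  yperm <- sample(bl$y)
  s <- cv_out_of_fold_scores(bl$X, yperm, "svm_rbf", k = 10, seed = 34)
  auc <- attr(roc_and_auc(s, yperm), "auc")
  expect_gt(auc, 0.4); expect_lt(auc, 0.6)

  expect_error(train_svm_rbf(cbind(a = c(1, NA), b = c(1, 2)), c(0L, 1L)),
               "non-finite")
})

test_that("the SVM pipeline is invariant to affine rescaling of a feature", {
  bl <- make_blobs(n = 120, sep = 2, seed = 41)
  m1 <- train_svm_rbf(bl$X, bl$y, calibration_folds = 0, seed = 42)
  X2 <- bl$X
  X2[, 1] <- X2[, 1] * 37 - 5    # affine map of one input feature
  m2 <- train_svm_rbf(X2, bl$y, calibration_folds = 0, seed = 42)
  p1 <- predict(m1, bl$X, type = "decision")
  p2 <- predict(m2, X2, type = "decision")
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("out-of-fold scoring covers each sample once without leakage", {
  bl <- make_blobs(n = 100, sep = 3, seed = 51)
  s <- cv_out_of_fold_scores(bl$X, bl$y, "svm_rbf", k = 5, seed = 52)
  expect_length(s, 100L)
  expect_true(all(is.finite(s)))
  expect_gte(attr(roc_and_auc(s, bl$y), "auc"), 0.95)
  # no-leakage check: the fold-1 scores are exactly what a model trained
  # on the other folds (never seeing fold 1) produces
  fold <- attr(s, "folds")
  k1 <- fold == 1
  m_ext <- train_svm_rbf(bl$X[!k1, , drop = FALSE], bl$y[!k1],
                         seed = 52 + 1)
  expect_equal(s[k1], predict(m_ext, bl$X[k1, , drop = FALSE], "prob"),
               tolerance = 1e-10)
})

test_that("ROC/AUC matches the concordance oracle and handles ties", {
  r <- roc_and_auc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
  expect_equal(attr(r, "auc"), 0.75)
  expect_equal(attr(roc_and_auc(c(1, 1, 0, 0), c(1, 1, 0, 0)), "auc"), 1.0)
  expect_equal(attr(roc_and_auc(rep(0.5, 10), rep(c(0, 1), 5)), "auc"), 0.5)
  expect_error(roc_and_auc(c(.1, .2), c(1, 1)), "both classes")
  # curve endpoints and monotonicity
  expect_equal(r$tpr[1], 0); expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[nrow(r)], 1); expect_equal(r$fpr[nrow(r)], 1)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
})

test_that("operating threshold is the highest reaching the target TPR", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.5, 0.4, 0.3, 0.1)
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0)
  op <- select_operating_threshold(roc_and_auc(scores, labels), 0.8)
  expect_equal(op$threshold, 0.6)
  expect_equal(op$tpr, 0.8)
  expect_equal(op$fpr, 0.0)
  # exhaustive scan: no higher threshold reaches the target
  for (t in sort(unique(scores), decreasing = TRUE)) {
    tpr_t <- mean(scores[labels == 1] >= t)
    if (t > op$threshold) expect_lt(tpr_t, 0.8)
  }
  # target 1 forces the minimum positive score
  op1 <- select_operating_threshold(roc_and_auc(scores, labels), 1)
  expect_equal(op1$threshold, 0.2)
  expect_equal(op1$tpr, 1)
})

test_that("the hyperparameter grid ranks a sane region on separable data", {
  bl <- make_blobs(n = 100, sep = 3, seed = 65)
  g <- tune_svm_rbf(bl$X, bl$y, k = 3, seed = 66)
  expect_equal(nrow(g), 9L)
  expect_true(all(g$auc >= 0.5 & g$auc <= 1))
  expect_gte(g$auc[1], 0.95)               # best cell separates the blobs
  best <- attr(g, "best")
  expect_true(best[["cost"]] %in% c(0.5, 1, 4))
})

test_that("model artifacts survive a JSON round trip", {
  bl <- make_blobs(n = 80, sep = 3, seed = 61)
  for (algo in c("svm_rbf", "lasso_logistic")) {
    m <- if (algo == "svm_rbf") train_svm_rbf(bl$X, bl$y, seed = 62) else
      train_lasso_logistic(bl$X, bl$y, seed = 62)
    tmp <- withr::local_tempfile(fileext = ".json")
    write_model(m, tmp)
    m2 <- read_model(tmp)
    expect_equal(predict(m2, bl$X, type = "prob"),
                 predict(m, bl$X, type = "prob"), tolerance = 1e-10)
  }
})
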