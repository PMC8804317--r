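# Classification layer: standardization, stratified splits, Lasso-logistic
# (glmnet) and RBF-kernel SVM (own SMO solver + Platt calibration), k-fold
# cross-validation, ROC/AUC, and operating-threshold selection at a target
# true-positive rate.

.as_feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  num <- vapply(x, is.numeric, TRUE)
  drop_cols <- intersect(names(x), c("pos", "label"))
  num[names(num) %in% drop_cols] <- FALSE
  as.matrix(x[num])
}

.check_binary_labels <- function(y) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) rlang::abort("labels must be 0/1")
  if (length(unique(y)) < 2L) {
    rlang::abort("both classes must be present in the labels")
  }
  y
}

#' Fit / apply column standardization
#'
#' Columns are centered and scaled to unit variance using the *training*
#' statistics (population standard deviation, the sklearn `scale`
#' convention); constant columns are flagged and map to 0. Held-out data
#' must be transformed with the training parameters, never its own.
#'
#' @param x Numeric matrix (or feature tibble) of training data, complete
#'   (post-imputation).
#' @return `fit_scaler()`: a `scaler_params` object; `apply_scaler()`: the
#'   transformed matrix.
#' @export
fit_scaler <- function(x) {
  X <- .as_feature_matrix(x)
  m <- colMeans(X)
  s <- sqrt(colMeans(sweep(X, 2L, m)^2))
  structure(list(mean = m, sd = s, constant = s == 0,
                 columns = colnames(X)),
            class = "scaler_params")
}

#' @rdname fit_scaler
#' @param params A `scaler_params` from [fit_scaler()].
#' @export
apply_scaler <- function(params, x) {
  X <- .as_feature_matrix(x)
  if (!identical(colnames(X), params$columns)) {
    rlang::abort("column set/order does not match the fitted scaler")
  }
  s <- ifelse(params$constant, 1, params$sd)
  sweep(sweep(X, 2L, params$mean), 2L, s, "/")
}

#' Stratified train/test split
#'
#' Splits `length(labels)` samples into disjoint, exhaustive train and test
#' sets, stratified by class; the train size is `round(n * train_fraction)`
#' and class proportions are preserved within one sample (largest-remainder
#' apportionment). Errors if either side would lose a class.
#'
#' @param labels 0/1 label vector.
#' @param train_fraction Fraction assigned to training (default 2/3).
#' @param seed Integer seed (mandatory - splits are deterministic given it).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, train_fraction = 2 / 3, seed) {
  y <- .check_binary_labels(labels)
  n <- length(y)
  stopifnot(n >= 3, train_fraction > 0, train_fraction < 1)
  n_train <- round(n * train_fraction)
  classes <- sort(unique(y))
  quota <- n_train * (tabulate(factor(y, classes)) / n)
  take <- floor(quota)
  rem <- order(quota - take, decreasing = TRUE)
  short <- n_train - sum(take)
  if (short > 0) take[rem[seq_len(short)]] <- take[rem[seq_len(short)]] + 1L
  set.seed(seed)
  train <- integer(0)
  for (ci in seq_along(classes)) {
    idx <- which(y == classes[ci])
    train <- c(train, sample(idx, take[ci]))
  }
  train <- sort(train)
  test <- setdiff(seq_len(n), train)
  if (length(unique(y[train])) < 2L || length(unique(y[test])) < 2L) {
    rlang::abort("a class is absent from the train or test side")
  }
  list(train = train, test = test)
}

#' Stratified k-fold assignment
#'
#' Partitions samples into `k` folds with sizes differing by at most one,
#' stratified by class (within each class, shuffled samples are dealt
#' round-robin, continuing the deal across classes so overall fold sizes
#' stay balanced). If some class has fewer than `k` members the assignment
#' falls back to unstratified with a warning.
#'
#' @param labels 0/1 label vector (used for stratification).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
kfold_indices <- function(labels, k = 10L, seed) {
  y <- as.integer(labels)
  n <- length(y)
  stopifnot(n >= k, k >= 2)
  set.seed(seed)
  fold <- integer(n)
  strata <- if (min(tabulate(factor(y))) < k) {
    rlang::warn("a class has fewer members than folds; unstratified folds")
    list(seq_len(n))
  } else {
    split(seq_len(n), y)
  }
  cursor <- sample.int(k, 1L) - 1L
  for (idx in strata) {
    idx <- sample(idx)
    fold[idx] <- ((cursor + seq_along(idx) - 1L) %% k) + 1L
    cursor <- (cursor + length(idx)) %% k
  }
  fold
}

.schema_fingerprint <- function(columns) rlang::hash(columns)

#' Train a Lasso-penalized logistic classifier
#'
#' L1-penalized logistic regression (glmnet path) with the penalty chosen
#' by k-fold cross-validated deviance. The L1 penalty performs feature
#' selection: non-discriminative features get a coefficient of exactly
#' zero and are reported as discarded. Features are standardized with
#' [fit_scaler()] before fitting (training statistics stored in the
#' artifact), so |coefficient| ranks feature contribution on a common
#' scale.
#'
#' @param x Complete numeric feature matrix (or feature tibble).
#' @param y 0/1 labels (1 = pathogenic).
#' @param penalty_rule `"1se"` (default; sparsest model within one standard
#'   error of the minimum CV deviance - the usual parsimony rule for
#'   feature selection) or `"min"`.
#' @param nfolds CV folds for the penalty search (default 10).
#' @param seed Integer seed (controls the CV folds).
#' @return An `snv_model` object (algorithm `"lasso_logistic"`).
#' @export
train_lasso_logistic <- function(x, y, penalty_rule = c("1se", "min"),
                                 nfolds = 10L, seed = 1L) {
  penalty_rule <- match.arg(penalty_rule)
  y <- .check_binary_labels(y)
  X <- .as_feature_matrix(x)
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  foldid <- kfold_indices(y, k = nfolds, seed = seed)
  cv <- glmnet::cv.glmnet(Xs, y, family = "binomial",
                          type.measure = "deviance", foldid = foldid,
                          standardize = FALSE)
  lambda <- if (penalty_rule == "1se") cv$lambda.1se else cv$lambda.min
  beta <- as.numeric(stats::coef(cv, s = lambda))
  names(beta) <- c("(Intercept)", colnames(Xs))
  structure(list(
    algorithm = "lasso_logistic",
    scaler = scaler,
    fit = cv$glmnet.fit,
    lambda = lambda,
    coefficients = beta,
    discarded = colnames(Xs)[beta[-1L] == 0],
    schema_fingerprint = .schema_fingerprint(colnames(Xs)),
    seed = seed
  ), class = "snv_model")
}

# --- RBF-SVM ----------------------------------------------------------------

.rbf_kernel <- function(X, Z, gamma) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(Z))) +
    outer(rep(1, nrow(X)), rowSums(Z^2)) - 2 * tcrossprod(X, Z)
  exp(-gamma * pmax(d2, 0))
}

# Platt's sigmoid calibration P(y=1|f) = 1/(1+exp(A f + B)), Newton descent
# with backtracking (Lin, Lin & Weng's numerically stable variant).
.platt_fit <- function(f, y, max_iter = 100L) {
  prior1 <- sum(y == 1); prior0 <- sum(y == 0)
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  t <- ifelse(y == 1, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  Fv <- fval(A, B)
  for (it in seq_len(max_iter)) {
    z <- A * f + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      newA <- A + step * dA; newB <- B + step * dB
      newF <- fval(newA, newB)
      if (newF < Fv + 1e-4 * step * gd) {
        A <- newA; B <- newB; Fv <- newF
        break
      }
      step <- step / 2
      if (step < 1e-10) return(c(A = A, B = B))
    }
  }
  c(A = A, B = B)
}

.platt_prob <- function(ab, f) {
  z <- ab[["A"]] * f + ab[["B"]]
  ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
}

#' Train an RBF-kernel support vector machine
#'
#' Soft-margin SVM with a radial-basis-function kernel, solved in the dual
#' by sequential minimal optimization (second-order working-set selection
#' on a precomputed kernel matrix). Decision values are mapped to
#' probabilities by a monotone Platt sigmoid fitted on out-of-fold decision
#' values from an internal cross-validation of the training data, so the
#' calibration never sees its own training scores. Features are
#' standardized internally with training statistics.
#'
#' @param x Complete numeric feature matrix (or feature tibble).
#' @param y 0/1 labels (1 = pathogenic).
#' @param cost Soft-margin cost C (default 1).
#' @param gamma RBF kernel width; `NULL` (default) uses `1/n_features` on
#'   the standardized inputs (the "scale" convention).
#' @param calibration_folds Internal folds for the Platt fit (default 3;
#'   0 calibrates on resubstitution decision values).
#' @param eps SMO stopping tolerance on the KKT violation (default 1e-3).
#' @param seed Integer seed (controls calibration folds).
#' @return An `snv_model` object (algorithm `"svm_rbf"`).
#' @export
train_svm_rbf <- function(x, y, cost = 1, gamma = NULL,
                          calibration_folds = 3L, eps = 1e-3, seed = 1L) {
  y <- .check_binary_labels(y)
  X <- .as_feature_matrix(x)
  if (any(!is.finite(X))) rlang::abort("feature matrix has non-finite values")
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  if (is.null(gamma)) gamma <- 1 / ncol(Xs)
  ysvm <- ifelse(y == 1L, 1L, -1L)

  train_dual <- function(Xtr, ytr) {
    K <- .rbf_kernel(Xtr, Xtr, gamma)
    smo_solve(K, as.integer(ytr), C = cost, eps = eps)
  }
  decision <- function(sol, Xtr, ytr, Xnew) {
    sv <- sol$alpha > 1e-12
    if (!any(sv)) return(rep(-sol$rho, nrow(Xnew)))
    Kx <- .rbf_kernel(Xnew, Xtr[sv, , drop = FALSE], gamma)
    drop(Kx %*% (sol$alpha[sv] * ytr[sv])) - sol$rho
  }

  # out-of-fold decision values for the sigmoid
  if (calibration_folds >= 2) {
    fold <- kfold_indices(y, k = calibration_folds, seed = seed)
    f_oof <- numeric(length(y))
    for (kk in seq_len(calibration_folds)) {
      tr <- fold != kk
      sol_k <- train_dual(Xs[tr, , drop = FALSE], ysvm[tr])
      f_oof[!tr] <- decision(sol_k, Xs[tr, , drop = FALSE], ysvm[tr],
                             Xs[!tr, , drop = FALSE])
    }
  }
  sol <- train_dual(Xs, ysvm)
  if (calibration_folds < 2) f_oof <- decision(sol, Xs, ysvm, Xs)
  platt <- .platt_fit(f_oof, y)

  sv <- sol$alpha > 1e-12
  structure(list(
    algorithm = "svm_rbf",
    scaler = scaler,
    support_vectors = Xs[sv, , drop = FALSE],
    dual_coef = sol$alpha[sv] * ysvm[sv],
    rho = sol$rho,
    gamma = gamma, cost = cost,
    platt = platt,
    iterations = sol$iterations,
    schema_fingerprint = .schema_fingerprint(colnames(Xs)),
    seed = seed
  ), class = "snv_model")
}

#' Predict pathogenicity probabilities from a trained model
#'
#' @param object An `snv_model`.
#' @param newdata Feature matrix or tibble with the training columns.
#' @param type `"prob"` (default), `"decision"` (SVM decision value /
#'   logistic linear predictor) or `"class"` (0/1 at probability 0.5).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.snv_model <- function(object, newdata,
                              type = c("prob", "decision", "class"), ...) {
  type <- match.arg(type)
  X <- .as_feature_matrix(newdata)
  if (!identical(colnames(X), object$scaler$columns)) {
    rlang::abort("feature columns do not match the model's schema fingerprint")
  }
  Xs <- apply_scaler(object$scaler, X)
  if (object$algorithm == "lasso_logistic") {
    eta <- drop(cbind(1, Xs) %*% object$coefficients)
    p <- 1 / (1 + exp(-eta))
    f <- eta
  } else {
    Kx <- .rbf_kernel(Xs, object$support_vectors, object$gamma)
    f <- drop(Kx %*% object$dual_coef) - object$rho
    p <- .platt_prob(object$platt, f)
  }
  switch(type, prob = p, decision = f, class = as.integer(p >= 0.5))
}

#' @export
print.snv_model <- function(x, ...) {
  cat(sprintf("<snv_model> %s, %d features (fingerprint %s)\n",
              x$algorithm, length(x$scaler$columns),
              substr(x$schema_fingerprint, 1, 8)))
  if (x$algorithm == "lasso_logistic") {
    cat(sprintf("  lambda=%.4g, %d features discarded (zero coefficient)\n",
                x$lambda, length(x$discarded)))
  } else {
    cat(sprintf("  C=%g gamma=%.4g, %d support vectors\n",
                x$cost, x$gamma, nrow(x$support_vectors)))
  }
  invisible(x)
}

#' Tidy a trained model
#'
#' For the Lasso, one row per feature with its coefficient on the
#' standardized scale, the |coefficient| rank (the model's feature-ranking
#' device) and whether the feature was discarded (coefficient exactly 0).
#' For the SVM, per-feature support-vector summaries are not meaningful, so
#' a one-row-per-support-vector tibble of dual coefficients is returned.
#'
#' @param x An `snv_model`.
#' @param ... Unused.
#' @export
tidy.snv_model <- function(x, ...) {
  if (x$algorithm == "lasso_logistic") {
    beta <- x$coefficients[-1L]
    tibble::tibble(
      feature = names(beta),
      coefficient = unname(beta),
      discarded = beta == 0,
      rank = rank(-abs(beta), ties.method = "min")
    ) |> dplyr::arrange(.data$rank)
  } else {
    tibble::tibble(support_vector = seq_along(x$dual_coef),
                   dual_coef = x$dual_coef)
  }
}

#' @rdname tidy.snv_model
#' @export
glance.snv_model <- function(x, ...) {
  if (x$algorithm == "lasso_logistic") {
    tibble::tibble(algorithm = x$algorithm,
                   n_features = length(x$scaler$columns),
                   lambda = x$lambda,
                   n_discarded = length(x$discarded))
  } else {
    tibble::tibble(algorithm = x$algorithm,
                   n_features = length(x$scaler$columns),
                   cost = x$cost, gamma = x$gamma,
                   n_support_vectors = length(x$dual_coef))
  }
}

#' Out-of-fold cross-validated probabilities
#'
#' Stratified k-fold cross-validation in which every sample is scored
#' exactly once by a model that never saw it; standardization and (for the
#' SVM) probability calibration are refit inside each training fold, so no
#' statistic leaks from the held-out fold.
#'
#' @param x Complete feature matrix or tibble.
#' @param y 0/1 labels.
#' @param algorithm `"svm_rbf"` or `"lasso_logistic"`.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @param ... Passed to the trainer.
#' @return Numeric vector of out-of-fold probabilities, one per sample,
#'   with the fold assignment in attribute `folds`.
#' @export
cv_out_of_fold_scores <- function(x, y, algorithm = c("svm_rbf",
                                                      "lasso_logistic"),
                                  k = 10L, seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  y <- .check_binary_labels(y)
  X <- .as_feature_matrix(x)
  fold <- kfold_indices(y, k = k, seed = seed)
  scores <- numeric(length(y))
  trainer <- if (algorithm == "svm_rbf") train_svm_rbf else
    train_lasso_logistic
  for (kk in seq_len(k)) {
    tr <- fold != kk
    model <- trainer(X[tr, , drop = FALSE], y[tr], seed = seed + kk, ...)
    scores[!tr] <- predict(model, X[!tr, , drop = FALSE], type = "prob")
  }
  attr(scores, "folds") <- fold
  scores
}

#' Tune SVM hyperparameters over a small cross-validated grid
#'
#' Grid-searches cost and kernel width by k-fold cross-validated AUC,
#' using the fast resubstitution-calibrated trainer inside folds (the
#' probability calibration does not affect AUC ranking, which is
#' threshold-free).
#'
#' @inheritParams train_svm_rbf
#' @param cost_grid Candidate soft-margin costs.
#' @param gamma_grid Candidate kernel widths; `NULL` uses
#'   `c(0.5, 1, 2) / n_features`.
#' @param k Cross-validation folds (default 5).
#' @return Tibble `cost gamma auc`, best first, with the winning pair in
#'   attribute `best`.
#' @export
tune_svm_rbf <- function(x, y, cost_grid = c(0.5, 1, 4),
                         gamma_grid = NULL, k = 5L, seed = 1L) {
  y <- .check_binary_labels(y)
  X <- .as_feature_matrix(x)
  if (is.null(gamma_grid)) gamma_grid <- c(0.5, 1, 2) / ncol(X)
  grid <- tidyr::expand_grid(cost = cost_grid, gamma = gamma_grid)
  grid$auc <- vapply(seq_len(nrow(grid)), function(i) {
    s <- cv_out_of_fold_scores(X, y, "svm_rbf", k = k, seed = seed,
                               cost = grid$cost[i], gamma = grid$gamma[i],
                               calibration_folds = 0L)
    attr(roc_and_auc(s, y), "auc")
  }, 1)
  grid <- dplyr::arrange(grid, dplyr::desc(.data$auc))
  structure(grid, best = c(cost = grid$cost[1L], gamma = grid$gamma[1L]))
}

# --- ROC --------------------------------------------------------------------

#' ROC curve and AUC
#'
#' Sweeps the call rule "probability >= threshold" over every distinct
#' score (ties grouped), yielding (FPR, TPR) points from (0,0) to (1,1);
#' the AUC is the trapezoidal area, which equals the Mann-Whitney
#' concordance probability with ties counted one half.
#'
#' @param scores Numeric classifier scores (higher = more pathogenic).
#' @param labels 0/1 truth labels; both classes must be present.
#' @return A `roc_curve`: tibble `threshold tpr fpr` (threshold `Inf` is the
#'   (0,0) anchor) with attribute `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  y <- .check_binary_labels(labels)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  np <- sum(y == 1L); nn <- sum(y == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp <- !duplicated(s)
  tp <- cumsum(yy == 1L); fp <- cumsum(yy == 0L)
  last <- which(c(grp[-1L], TRUE)) # last index of each tie group
  curve <- tibble::tibble(
    threshold = c(Inf, s[last]),
    tpr = c(0, tp[last] / np),
    fpr = c(0, fp[last] / nn)
  )
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  structure(curve, auc = auc, class = c("roc_curve", class(curve)))
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f over %d thresholds\n",
              attr(x, "auc"), nrow(x) - 1L))
  NextMethod()
}

#' @rdname roc_and_auc
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @export
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = attr(x, "auc"), n_thresholds = nrow(x) - 1L)
}

#' @rdname roc_and_auc
#' @param object A `roc_curve`.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))
    )
}

#' Select the operating threshold at a target TPR
#'
#' Classifier probabilities need a cutoff to become binary pathogenicity
#' calls. This picks the *highest* threshold whose true-positive rate
#' reaches the target (default 0.80): among all thresholds achieving the
#' target sensitivity, the highest one minimizes the false-positive rate.
#' Calls at the threshold use `probability >= threshold`.
#'
#' @param curve A `roc_curve` from [roc_and_auc()].
#' @param target_tpr Required sensitivity (default 0.80).
#' @return One-row tibble `threshold tpr fpr`.
#' @export
select_operating_threshold <- function(curve, target_tpr = 0.80) {
  stopifnot(target_tpr > 0, target_tpr <= 1)
  ok <- which(curve$tpr >= target_tpr)
  hit <- ok[1L] # thresholds are in decreasing order; first hit is highest
  tibble::tibble(threshold = curve$threshold[hit],
                 tpr = curve$tpr[hit], fpr = curve$fpr[hit])
}

#' Fit a pathogenicity classifier from a labeled feature matrix
#'
#' Data-frame-first wrapper around the trainers: takes an imputed feature
#' matrix carrying a `label` column (`"positive"`/`"negative"` or 0/1),
#' drops the variant-key columns, and trains the requested algorithm.
#'
#' @param data Labeled, complete feature tibble.
#' @param algorithm `"svm_rbf"` or `"lasso_logistic"`.
#' @param label_col Name of the label column (default `"label"`).
#' @param ... Passed to the trainer.
#' @return An `snv_model`.
#' @export
fit_pathogenicity_model <- function(data,
                                    algorithm = c("svm_rbf",
                                                  "lasso_logistic"),
                                    label_col = "label", ...) {
  algorithm <- match.arg(algorithm)
  lab <- data[[label_col]]
  if (is.character(lab) || is.factor(lab)) {
    lab <- as.integer(as.character(lab) == "positive")
  }
  X <- .as_feature_matrix(data[setdiff(names(data),
                                       c(label_col, .key_cols, "region"))])
  trainer <- if (algorithm == "svm_rbf") train_svm_rbf else
    train_lasso_logistic
  trainer(X, lab, ...)
}

#' Serialize / restore a model artifact as JSON
#'
#' @param model An `snv_model`.
#' @param path JSON file path.
#' @return `write_model()`: `path`, invisibly; `read_model()`: the model.
#' @export
write_model <- function(model, path) {
  obj <- unclass(model)
  obj$scaler <- unclass(obj$scaler)
  # jsonlite drops names on atomic vectors; keep them via lists
  obj$scaler$mean <- as.list(obj$scaler$mean)
  obj$scaler$sd <- as.list(obj$scaler$sd)
  if (!is.null(obj$platt)) obj$platt <- as.list(obj$platt)
  if (!is.null(obj$coefficients)) {
    obj$coefficients <- as.list(obj$coefficients)
  }
  if (!is.null(obj$fit)) obj$fit <- NULL # glmnet path not needed to predict
  if (!is.null(obj$support_vectors)) {
    obj$support_vectors <- list(values = as.vector(obj$support_vectors),
                                dim = dim(obj$support_vectors),
                                colnames = colnames(obj$support_vectors))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$scaler <- structure(list(
    mean = unlist(obj$scaler$mean),
    sd = unlist(obj$scaler$sd),
    constant = as.logical(obj$scaler$constant),
    columns = as.character(obj$scaler$columns)
  ), class = "scaler_params")
  names(obj$scaler$constant) <- obj$scaler$columns
  if (!is.null(obj$support_vectors)) {
    sv <- matrix(as.numeric(obj$support_vectors$values),
                 nrow = obj$support_vectors$dim[1L])
    colnames(sv) <- obj$support_vectors$colnames
    obj$support_vectors <- sv
    obj$platt <- unlist(obj$platt)
    obj$dual_coef <- as.numeric(obj$dual_coef)
  }
  if (!is.null(obj$coefficients)) obj$coefficients <- unlist(obj$coefficients)
  structure(obj, class = "snv_model")
}
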