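# Chained-equation imputation (MICE-style) for mixed continuous/binary
# feature matrices. Hand-rolled on lm.fit/glm.fit: single imputation, each
# incomplete column regressed on all other columns, iterated.

#' Build an imputation plan
#'
#' @param iterations Number of chained-equation sweeps (default 10).
#' @param seed Seed for the stochastic draws (mandatory when
#'   `mode = "stochastic"`).
#' @param mode `"stochastic"` (default; adds seeded residual noise for
#'   continuous columns and Bernoulli draws for binary columns, avoiding
#'   variance shrinkage) or `"deterministic"` (pure regression predictions:
#'   reproducible point estimates, used by recovery tests).
#' @param tol Convergence tolerance on the mean absolute change of imputed
#'   values between sweeps; sweeps stop early below it (deterministic mode
#'   only; stochastic chains always run all iterations).
#' @return An `imputation_plan` list.
#' @export
imputation_plan <- function(iterations = 10L, seed = 1L,
                            mode = c("stochastic", "deterministic"),
                            tol = 1e-4) {
  mode <- match.arg(mode)
  stopifnot(iterations >= 1)
  structure(list(iterations = as.integer(iterations), seed = as.integer(seed),
                 mode = mode, tol = tol),
            class = "imputation_plan")
}

.is_binary_col <- function(x) {
  obs <- x[!is.na(x)]
  length(obs) > 0 && all(obs %in% c(0, 1))
}

# least-squares fit tolerant of rank deficiency (NA pivots -> 0)
.lin_fit <- function(X, y) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(beta = beta, sigma = stats::sd(fit$residuals))
}

.lin_predict <- function(beta, X) {
  drop(cbind(1, X) %*% beta)
}

.logit_fit <- function(X, y) {
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(Xd, y, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$coefficients))) return(NULL)
  beta <- fit$coefficients
  beta[is.na(beta) | !is.finite(beta)] <- 0
  beta
}

#' Impute missing feature values by chained equations
#'
#' Missing cells are first filled with the column mean (continuous) or mode
#' (binary); then, for `plan$iterations` sweeps, every originally
#' incomplete column is regressed on all other columns over its observed
#' rows (linear model for continuous, logistic for binary) and its missing
#' entries are replaced by model predictions - plus a seeded residual draw
#' in stochastic mode. Observed cells are never modified; binary columns
#' come back in \{0, 1\}; the same seed reproduces the output bit for bit.
#'
#' @param data Feature-matrix tibble; non-numeric columns and `id_cols` are
#'   passed through untouched.
#' @param plan An [imputation_plan()].
#' @param id_cols Columns excluded from the model (default: the variant-key
#'   columns plus `region` and `label` when present).
#' @return The completed tibble with attribute `impute_report` (per-column
#'   missing counts and iterations run).
#' @export
mice_impute <- function(data, plan = imputation_plan(),
                        id_cols = c("chrom", "pos", "ref", "alt", "region",
                                    "label")) {
  stopifnot(inherits(plan, "imputation_plan"))
  id_cols <- intersect(id_cols, names(data))
  keep <- data[id_cols]
  num_cols <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], id_cols)
  X <- as.matrix(data[num_cols])
  if (ncol(X) < 2) rlang::abort("imputation needs at least 2 feature columns")

  miss <- is.na(X)
  all_missing <- colSums(!miss) == 0
  if (any(all_missing)) {
    rlang::abort(sprintf("column(s) with no observed values: %s",
                         paste(num_cols[all_missing], collapse = ", ")))
  }
  n_missing <- colSums(miss)
  report <- tibble::tibble(column = num_cols, n_missing = as.integer(n_missing))
  if (!any(miss)) {
    out <- dplyr::bind_cols(keep, tibble::as_tibble(X))
    attr(out, "impute_report") <- list(columns = report, iterations = 0L)
    return(out)
  }

  binary <- apply(X, 2L, .is_binary_col)
  # initial fill: mean / mode
  for (j in seq_len(ncol(X))) {
    if (!any(miss[, j])) next
    obs <- X[!miss[, j], j]
    fill <- if (binary[j]) as.numeric(mean(obs) >= 0.5) else mean(obs)
    X[miss[, j], j] <- fill
  }

  incomplete <- which(n_missing > 0)
  set.seed(plan$seed)
  iters_run <- 0L
  for (it in seq_len(plan$iterations)) {
    prev <- X[miss]
    for (j in incomplete) {
      obs_rows <- !miss[, j]
      pred <- X[, -j, drop = FALSE]
      # drop predictors constant over observed rows (no information, and
      # they break the logistic fit)
      keep_p <- apply(pred[obs_rows, , drop = FALSE], 2L,
                      function(v) stats::sd(v) > 0)
      predj <- pred[, keep_p, drop = FALSE]
      mis_rows <- miss[, j]
      if (ncol(predj) == 0) next # nothing to regress on; keep initial fill
      if (binary[j]) {
        beta <- .logit_fit(predj[obs_rows, , drop = FALSE], X[obs_rows, j])
        if (is.null(beta)) { # separation etc.: fall back to linear + round
          lf <- .lin_fit(predj[obs_rows, , drop = FALSE], X[obs_rows, j])
          p <- .lin_predict(lf$beta, predj[mis_rows, , drop = FALSE])
          p <- pmin(pmax(p, 0), 1)
        } else {
          eta <- .lin_predict(beta, predj[mis_rows, , drop = FALSE])
          p <- 1 / (1 + exp(-pmin(pmax(eta, -30), 30)))
        }
        X[mis_rows, j] <- if (plan$mode == "stochastic") {
          stats::rbinom(sum(mis_rows), 1L, p)
        } else as.numeric(p >= 0.5)
      } else {
        lf <- .lin_fit(predj[obs_rows, , drop = FALSE], X[obs_rows, j])
        mu <- .lin_predict(lf$beta, predj[mis_rows, , drop = FALSE])
        X[mis_rows, j] <- if (plan$mode == "stochastic" &&
                              is.finite(lf$sigma) && lf$sigma > 0) {
          mu + stats::rnorm(sum(mis_rows), 0, lf$sigma)
        } else mu
      }
    }
    iters_run <- it
    if (plan$mode == "deterministic") {
      delta <- mean(abs(X[miss] - prev))
      if (is.finite(delta) && delta < plan$tol) break
    }
  }

  out <- dplyr::bind_cols(keep, tibble::as_tibble(X))
  attr(out, "impute_report") <- list(columns = report, iterations = iters_run,
                                     mode = plan$mode, seed = plan$seed)
  out
}
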