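#' Pearson product-moment correlation
#'
#' Standard coefficient, clamped to `[-1, 1]` against floating-point
#' rounding; constant inputs are an error (the coefficient is undefined).
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input")
  max(-1, min(1, cor(x, y)))
}

#' Two-tailed p-value of a correlation coefficient
#'
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` referred to the t-distribution with
#' `n - 2` degrees of freedom, two-tailed.  `|r| = 1` returns exactly 0.
#'
#' @param r correlation coefficient.
#' @param n sample size (>= 3).
#' @return list with `t` and `p`.
#' @export
p_from_r <- function(r, n) {
  stopifnot(abs(r) <= 1, n >= 3)
  if (abs(r) == 1) return(list(t = Inf * sign(r), p = 0))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(t = t, p = 2 * pt(-abs(t), df = n - 2))
}

#' Correlation screen of features against outcome scores
#'
#' Per feature: Pearson r, t statistic, two-tailed p, and a significance
#' flag at `p <= alpha` (inclusive).  Constant features receive `NA` and are
#' never significant.  Results are sorted by p.
#'
#' @param features subjects x features matrix (or data.frame) with column
#'   names.
#' @param scores numeric outcome vector, one per subject.
#' @param alpha significance level (default 0.05).
#' @return data.frame `feature`, `r`, `t`, `p`, `n`, `significant`.
#' @export
screen_features <- function(features, scores, alpha = 0.05) {
  features <- as.matrix(features)
  if (nrow(features) != length(scores))
    stop("feature rows (", nrow(features), ") != scores (", length(scores), ")")
  n <- length(scores)
  out <- do.call(rbind, lapply(colnames(features), function(f) {
    x <- features[, f]
    if (sd(x) == 0 || sd(scores) == 0)
      return(data.frame(feature = f, r = NA_real_, t = NA_real_,
                        p = NA_real_, n = n, significant = FALSE))
    r <- pearson_r(x, scores)
    tp <- p_from_r(r, n)
    data.frame(feature = f, r = r, t = tp$t, p = tp$p, n = n,
               significant = tp$p <= alpha)
  }))
  out[order(out$p), , drop = FALSE]
}

#' Tree-ensemble model specification
#'
#' Mirrors the common regression-learner defaults: 30 learners, boosting
#' learning rate 0.1, minimum leaf size 8.
#'
#' @param kind `"bagged"` (bootstrap-aggregated trees) or `"boosted"`
#'   (least-squares gradient boosting of shallow trees).
#' @param n_learners number of trees.
#' @param learning_rate shrinkage in (0, 1], boosted only.
#' @param min_leaf minimum observations per terminal leaf.
#' @param max_depth tree depth cap, or `NULL` for unlimited.
#' @param seed seed controlling the bootstrap resamples.
#' @export
model_spec <- function(kind = c("bagged", "boosted"), n_learners = 30,
                       learning_rate = 0.1, min_leaf = 8, max_depth = NULL,
                       seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_learners >= 1, learning_rate > 0, learning_rate <= 1,
            min_leaf >= 1)
  structure(list(kind = kind, n_learners = as.integer(n_learners),
                 learning_rate = learning_rate,
                 min_leaf = as.integer(min_leaf), max_depth = max_depth,
                 seed = as.integer(seed)), class = "model_spec")
}

rpart_control_for <- function(spec) {
  rpart::rpart.control(minsplit = max(2L, 2L * spec$min_leaf),
                       minbucket = spec$min_leaf, cp = 0, xval = 0,
                       maxdepth = if (is.null(spec$max_depth)) 30
                                  else spec$max_depth,
                       maxsurrogate = 0, maxcompete = 0)
}

#' Fit a bagged or boosted regression-tree ensemble
#'
#' Bagged: regression trees on bootstrap resamples, prediction = mean over
#' learners.  Boosted: least-squares gradient boosting — each tree fits the
#' current residuals and contributes `learning_rate` times its prediction on
#' top of the training-mean initialisation.  Deterministic given the spec's
#' seed.
#'
#' @param features subjects x features matrix or data.frame.
#' @param scores numeric outcome vector.
#' @param spec a [model_spec()].
#' @return an object of class `tree_ensemble` with a [predict][predict.tree_ensemble] method.
#' @export
fit_ensemble <- function(features, scores, spec = model_spec()) {
  x <- as.data.frame(features)
  names(x) <- make.names(names(x))
  if (!all(vapply(x, function(col) all(is.finite(col)), TRUE)))
    stop("non-finite feature value")
  stopifnot(nrow(x) >= 2, ncol(x) >= 1)
  df <- cbind(.y = scores, x)
  ctrl <- rpart_control_for(spec)
  set.seed(spec$seed)
  trees <- vector("list", spec$n_learners)
  init <- NULL
  if (spec$kind == "bagged") {
    for (b in seq_len(spec$n_learners)) {
      idx <- sample(nrow(df), replace = TRUE)
      trees[[b]] <- rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                                 method = "anova", control = ctrl)
    }
  } else {
    init <- mean(scores)
    fhat <- rep(init, nrow(df))
    for (b in seq_len(spec$n_learners)) {
      df$.y <- scores - fhat
      trees[[b]] <- rpart::rpart(.y ~ ., data = df, method = "anova",
                                 control = ctrl)
      fhat <- fhat + spec$learning_rate * predict(trees[[b]], newdata = x)
    }
  }
  structure(list(spec = spec, trees = trees, init = init,
                 feature_names = names(x)), class = "tree_ensemble")
}

#' Predict from a fitted tree ensemble
#'
#' @param object a `tree_ensemble`.
#' @param newdata matrix or data.frame of features.
#' @param ... unused.
#' @export
predict.tree_ensemble <- function(object, newdata, ...) {
  x <- as.data.frame(newdata)
  names(x) <- make.names(names(x))
  per_tree <- vapply(object$trees, function(tr) predict(tr, newdata = x),
                     numeric(nrow(x)))
  per_tree <- matrix(per_tree, nrow = nrow(x))
  if (object$spec$kind == "bagged") unname(rowMeans(per_tree))
  else unname(object$init + object$spec$learning_rate * rowSums(per_tree))
}

#' Regression error metrics
#'
#' RMSE, MAE and R-squared, the latter against the constant baseline at the
#' mean of the actual values.
#'
#' @param actual,predicted equal-length numeric vectors.
#' @return list `rmse`, `mae`, `r_squared`.
#' @export
regression_metrics <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 1)
  if (var(actual) == 0) stop("r_squared undefined for zero-variance actuals")
  err <- actual - predicted
  list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
       r_squared = 1 - sum(err^2) / sum((actual - mean(actual))^2))
}

#' Leave-one-subject-out cross-validated prediction
#'
#' Each subject is predicted by an ensemble trained on the remaining
#' subjects; metrics are pooled over all held-out predictions (RMSE, MAE,
#' and R-squared about the grand mean of the actual scores).  Per-fold
#' absolute errors are kept in the fold log, and the fold-averaged RMSE/MAE
#' are reported alongside the pooled values.
#'
#' @param features subjects x features matrix or data.frame.
#' @param scores numeric outcome vector (length >= 3).
#' @param spec a [model_spec()]; each fold derives its own seed from it.
#' @return an object of class `prediction_report`.
#' @export
losocv <- function(features, scores, spec = model_spec()) {
  x <- as.data.frame(features)
  n <- length(scores)
  if (n < 3) stop("LOSOCV needs at least 3 subjects")
  stopifnot(nrow(x) == n)
  predicted <- numeric(n)
  if (var(scores) == 0) {
    predicted[] <- scores[1]
    metrics <- list(rmse = 0, mae = 0, r_squared = NA_real_)
  } else {
    for (i in seq_len(n)) {
      fold_spec <- spec
      fold_spec$seed <- derive_seed(spec$seed, i, salt = 4L)
      fit <- fit_ensemble(x[-i, , drop = FALSE], scores[-i], fold_spec)
      predicted[i] <- predict(fit, x[i, , drop = FALSE])
    }
    metrics <- regression_metrics(scores, predicted)
  }
  fold_log <- data.frame(subject = seq_len(n), actual = scores,
                         predicted = predicted,
                         abs_error = abs(scores - predicted))
  structure(list(model_id = spec$kind, spec = spec,
                 predictions = fold_log,
                 rmse = metrics$rmse, mae = metrics$mae,
                 r_squared = metrics$r_squared,
                 fold_rmse_mean = mean(abs(scores - predicted)),
                 fold_log = fold_log), class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %s trees, LOSOCV over %d subjects\n",
              x$model_id, nrow(x$predictions)))
  cat(sprintf("  RMSE = %.3f  MAE = %.3f  R-squared = %.3f\n",
              x$rmse, x$mae, x$r_squared))
  invisible(x)
}
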