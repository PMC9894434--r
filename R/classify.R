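# Cross-validated truth/lie classification on the feature battery.
#
# The native baseline is an L2-regularized logistic regression fitted by
# full-batch gradient descent (deterministic, dependency-free); SVM-RBF and
# gradient-boosting adapters plug in the same interface when e1071/xgboost
# are available. Folding is group-aware by default: all four statements of a
# subject share a fold, so author style cannot leak across the split.

#' Assemble the classification matrix
#'
#' Selects a modality subset, converts count features to per-token rates,
#' and drops rows with any missing value in the selected columns (dropped
#' ids are recorded in the `dropped` attribute). Standardization is NOT
#' applied here: [kfold_cv()] z-scores each fold using training-fold
#' statistics only.
#'
#' @param feature_table data.frame from [extract_feature_table()].
#' @param subset `"all"`, `"transcribed"`, or `"written"`.
#' @param variables feature columns; defaults to all battery columns
#'   present.
#' @return list(x = numeric matrix, y = labels (`truth`/`lie`),
#'   groups = subject ids, statement_id).
#' @export
assemble_matrix <- function(feature_table,
                            subset = c("all", "transcribed", "written"),
                            variables = NULL) {
  subset <- match.arg(subset)
  tab <- feature_table
  if (subset != "all") tab <- tab[tab$modality == subset, , drop = FALSE]
  if (nrow(tab) == 0L) stop("subset '", subset, "' selects no statements")
  meta_cols <- c("statement_id", "subject_id", "topic", "veracity",
                 "modality")
  if (is.null(variables)) variables <- setdiff(names(tab), meta_cols)
  x <- as.matrix(tab[, variables, drop = FALSE])
  storage.mode(x) <- "double"
  rate_cols <- is_count_feature(variables)
  if (any(rate_cols))
    x[, rate_cols] <- x[, rate_cols, drop = FALSE] / tab$n_tokens
  complete <- stats::complete.cases(x)
  dropped <- tab$statement_id[!complete]
  x <- x[complete, , drop = FALSE]
  structure(list(x = x, y = tab$veracity[complete],
                 groups = as.character(tab$subject_id[complete]),
                 statement_id = tab$statement_id[complete]),
            dropped = dropped)
}

#' Train the native baseline classifier
#'
#' L2-regularized logistic regression (intercept unpenalized) fitted by
#' full-batch gradient descent with a Lipschitz step size, run to gradient
#' tolerance `tol`. Deterministic given its inputs.
#'
#' @param x numeric training matrix.
#' @param y labels; the second of `sort(unique(y))` is the positive class.
#' @param lambda L2 penalty per observation.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with `predict_prob(newx)` and `predict_label(newx)`.
#' @export
train_baseline_classifier <- function(x, y, lambda = 1e-2, tol = 1e-6,
                                      max_iter = 5000L) {
  if (!all(is.finite(x))) stop("non-finite features in training matrix")
  classes <- sort(unique(y))
  if (length(classes) != 2L)
    stop("need exactly 2 classes in training data, got ",
         length(classes))
  t01 <- as.numeric(y == classes[2])
  n <- nrow(x)
  X1 <- cbind(1, x)
  p <- ncol(X1)
  # gradient Lipschitz constant of the mean logistic loss + ridge
  L <- 0.25 * max(eigen(crossprod(X1) / n, symmetric = TRUE,
                        only.values = TRUE)$values) + lambda
  w <- numeric(p)
  pen <- c(0, rep(lambda, p - 1L))  # intercept unpenalized
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% w)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X1, mu - t01)) / n + pen * w
    if (sqrt(sum(grad^2)) < tol) break
    w <- w - grad / L
  }
  predict_prob <- function(newx) {
    pr <- stats::plogis(drop(cbind(1, newx) %*% w))
    stats::setNames(data.frame(1 - pr, pr), classes)
  }
  list(weights = w, classes = classes,
       predict_prob = predict_prob,
       predict_label = function(newx)
         classes[1L + (stats::plogis(drop(cbind(1, newx) %*% w)) >= 0.5)])
}

train_svm_classifier <- function(x, y, cost = 1, gamma = 1 / ncol(x)) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("model 'svm' requires the e1071 package")
  fit <- e1071::svm(x, factor(y), kernel = "radial", cost = cost,
                    gamma = gamma, scale = FALSE)
  list(predict_label = function(newx) as.character(stats::predict(fit, newx)))
}

train_gboost_classifier <- function(x, y, nrounds = 100, max_depth = 3,
                                    eta = 0.3) {
  if (!requireNamespace("xgboost", quietly = TRUE))
    stop("model 'gboost' requires the xgboost package")
  fit <- xgboost::xgboost(x, factor(y), nrounds = nrounds,
                          max_depth = max_depth, learning_rate = eta,
                          nthreads = 1, verbosity = 0)
  list(predict_label = function(newx)
    as.character(stats::predict(fit, newx, type = "class")))
}

classifier_trainers <- function(model) {
  switch(model,
         baseline = train_baseline_classifier,
         svm = train_svm_classifier,
         gboost = train_gboost_classifier,
         stop("unknown model '", model,
              "'; use 'baseline', 'svm' or 'gboost'"))
}

#' k-fold cross-validated accuracy
#'
#' Partitions statements into `k` folds — by subject when
#' `group_aware = TRUE` (default), so repeated statements by one person
#' never straddle the train/test split — trains the chosen model on each
#' training set, and scores accuracy on the held-out fold. Columns are
#' z-scored with training-fold means/sds only (zero-sd columns pass through
#' unscaled); the same transform is applied to the test fold. The summary is
#' the mean fold accuracy with standard error `sd(folds)/sqrt(k)`.
#' Deterministic given `seed`.
#'
#' @param x,y,groups from [assemble_matrix()].
#' @param k number of folds.
#' @param model `"baseline"`, `"svm"`, or `"gboost"`.
#' @param seed integer seed for fold assignment.
#' @param group_aware fold by subject (default) or by statement.
#' @param subset label stored in the result.
#' @param ... passed to the model trainer.
#' @return A `cv_result`: list(subset, model_name, k, fold_accuracies,
#'   mean_acc, se_acc, seed, n).
#' @export
kfold_cv <- function(x, y, groups, k = 20L, model = "baseline",
                     seed = 1L, group_aware = TRUE, subset = "all", ...) {
  trainer <- classifier_trainers(model)
  n <- nrow(x)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)
  if (group_aware) {
    units <- sort(unique(groups))
    if (k > length(units))
      stop("k = ", k, " exceeds the ", length(units), " subjects")
    fold_of_unit <- stats::setNames(
      rep_len(seq_len(k), length(units))[sample(length(units))], units)
    fold <- unname(fold_of_unit[groups])
  } else {
    if (k > n) stop("k = ", k, " exceeds the ", n, " statements")
    fold <- rep_len(seq_len(k), n)[sample(n)]
  }
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sd_ <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sd_[sd_ == 0 | is.na(sd_)] <- 1
    scale_fold <- function(m) sweep(sweep(m, 2, mu), 2, sd_, "/")
    if (length(unique(y[tr])) < 2L)
      stop("training fold ", f, " contains a single class")
    if (length(unique(y[!tr])) < 2L)
      warning("test fold ", f, " contains a single class")
    fitted <- trainer(scale_fold(x[tr, , drop = FALSE]), y[tr], ...)
    pred <- fitted$predict_label(scale_fold(x[!tr, , drop = FALSE]))
    acc[f] <- mean(pred == y[!tr])
  }
  structure(list(subset = subset, model_name = model, k = k,
                 fold_accuracies = acc, mean_acc = mean(acc),
                 se_acc = stats::sd(acc) / sqrt(k), seed = seed, n = n),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%s / %s: %d-fold CV accuracy %.3f ± %.3f (n = %d)\n",
              x$subset, x$model_name, x$k, x$mean_acc, x$se_acc, x$n))
  invisible(x)
}

#' Run the full classification protocol on a feature table
#'
#' Convenience wrapper: [assemble_matrix()] for the requested subset, then
#' [kfold_cv()].
#'
#' @param feature_table data.frame from [extract_feature_table()].
#' @param subset `"all"`, `"transcribed"`, or `"written"`.
#' @param k folds.
#' @param model classifier name.
#' @param seed fold-assignment seed.
#' @param ... passed to [kfold_cv()].
#' @return A `cv_result`.
#' @export
classify_statements <- function(feature_table, subset = "all", k = 20L,
                                model = "baseline", seed = 1L, ...) {
  mat <- assemble_matrix(feature_table, subset)
  kfold_cv(mat$x, mat$y, mat$groups, k = k, model = model, seed = seed,
           subset = subset, ...)
}
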