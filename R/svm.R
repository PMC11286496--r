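#' Gaussian (RBF) kernel
#'
#' \eqn{\kappa(x_i, x_j) = \exp(-\|x_i - x_j\|^2 / 2\sigma^2)}: symmetric,
#' equal to 1 at zero distance and decreasing with distance.
#'
#' @param xi,xj numeric feature vectors of equal length.
#' @param sigma kernel width, > 0.
#' @return Similarity in `(0, 1]`.
#' @export
gaussian_kernel <- function(xi, xj, sigma) {
  if (length(xi) != length(xj)) stop("feature vectors must have equal length")
  if (sigma <= 0) stop("sigma must be positive")
  exp(-sum((xi - xj)^2) / (2 * sigma^2))
}

# full kernel matrix between the rows of two matrices
gaussian_kernel_matrix <- function(x, y = x, sigma) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' Stratified train/test split of a feature table
#'
#' Splits by status with a fixed training fraction per class (default 70/30),
#' deterministically for a given seed.
#'
#' @param table feature table with a `status` column.
#' @param train_frac training fraction in `(0, 1)`.
#' @param seed integer seed.
#' @return List with data frames `train` and `test`.
#' @export
split_train_test <- function(table, train_frac = 0.7, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must lie in (0, 1)")
  counts <- table(table$status)
  if (any(counts < 2)) stop("every class needs at least 2 rows to split")
  set.seed(seed)
  train_idx <- unlist(lapply(split(seq_len(nrow(table)), table$status),
                             function(idx) {
                               sample(idx, round(train_frac * length(idx)))
                             }), use.names = FALSE)
  list(train = table[sort(train_idx), , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), train_idx), , drop = FALSE])
}

#' Train the soft-margin Gaussian-kernel SVM tissue classifier
#'
#' Solves the kernelized soft-margin problem (penalty `C` on slack
#' variables) with the Gaussian kernel of width `sigma` on z-scored
#' features; multi-class problems use one-vs-one voting.  The decision
#' function of each binary subproblem is
#' \eqn{f(x) = \sum_i \alpha_i y_i \kappa(x_i, x) + b}.  Feature means and
#' standard deviations are fitted on the training data only and stored with
#' the model.
#'
#' @param train training feature table (must contain `status` and the
#'   requested feature columns).
#' @param features character vector of feature column names.
#' @param C soft-margin penalty, > 0.
#' @param sigma Gaussian kernel width on the z-scored scale, > 0.
#' @return An object of class `tissue_svm`.
#' @export
train_classifier <- function(train, features = MARKER_NAMES, C = 10,
                             sigma = 2) {
  if (length(features) == 0) stop("at least one feature is required")
  if (!all(features %in% names(train))) stop("unknown feature column(s)")
  y <- factor(train$status)
  if (nlevels(y) < 2) stop("training data must contain at least 2 classes")
  x <- as.matrix(train[, features, drop = FALSE])
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  if (any(scale_ == 0)) {
    warning("zero-variance feature(s): ",
            paste(features[scale_ == 0], collapse = ", "),
            "; standard deviation set to 1")
    scale_[scale_ == 0] <- 1
  }
  z <- sweep(sweep(x, 2, center), 2, scale_, "/")
  model <- e1071::svm(x = z, y = y, scale = FALSE, kernel = "radial",
                      gamma = 1 / (2 * sigma^2), cost = C)
  structure(list(model = model, features = features, center = center,
                 scale = scale_, C = C, sigma = sigma,
                 classes = as.integer(levels(y))),
            class = "tissue_svm")
}

#' @export
print.tissue_svm <- function(x, ...) {
  cat(sprintf(
    "<tissue_svm: classes {%s}, %d features, C = %g, sigma = %g, %d SVs>\n",
    paste(x$classes, collapse = ", "), length(x$features), x$C, x$sigma,
    x$model$tot.nSV))
  invisible(x)
}

# z-score new data with the training standardizer
standardize_features <- function(clf, table) {
  x <- as.matrix(table[, clf$features, drop = FALSE])
  sweep(sweep(x, 2, clf$center), 2, clf$scale, "/")
}

#' @export
predict.tissue_svm <- function(object, newdata, ...) {
  z <- standardize_features(object, newdata)
  as.integer(as.character(stats::predict(object$model, z)))
}

#' Continuous decision scores of a trained classifier
#'
#' For binary classifiers, the signed decision value oriented so that larger
#' scores favour the larger status code.  For multi-class classifiers, a
#' matrix of per-class scores (each the sum of the signed one-vs-one
#' decision values in that class's favour), used for one-vs-rest ROC curves.
#'
#' @param clf a [train_classifier()] model.
#' @param table feature table.
#' @return Numeric vector (binary) or matrix with one column per class.
#' @export
decision_scores <- function(clf, table) {
  z <- standardize_features(clf, table)
  dv <- attr(stats::predict(clf$model, z, decision.values = TRUE),
             "decision.values")
  classes <- clf$classes
  if (length(classes) == 2) {
    # column name "a/b": positive values favour class a
    pair <- as.integer(strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]])
    sgn <- if (pair[1] > pair[2]) 1 else -1
    return(sgn * dv[, 1])
  }
  scores <- matrix(0, nrow(z), length(classes),
                   dimnames = list(NULL, as.character(classes)))
  for (j in seq_len(ncol(dv))) {
    pair <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1]]
    scores[, pair[1]] <- scores[, pair[1]] + dv[, j]
    scores[, pair[2]] <- scores[, pair[2]] - dv[, j]
  }
  scores
}

# ROC by threshold sweep over continuous scores; AUC by trapezoid
roc_sweep <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  tpr <- c(0, cumsum(pos) / max(sum(pos), 1))
  fpr <- c(0, cumsum(!pos) / max(sum(!pos), 1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a classifier on a test table
#'
#' Computes test accuracy, the per-class confusion matrix, and ROC/AUC from
#' the continuous decision scores (binary: single score sweep; multi-class:
#' macro-averaged one-vs-rest).
#'
#' @param clf a [train_classifier()] model.
#' @param test feature table containing the same features and `status`.
#' @return An object of class `eval_metrics`: `accuracy`, `confusion`,
#'   `roc` (data frame of ROC points, or per-class list), `auc` (binary
#'   AUC or macro-average).
#' @export
evaluate_classifier <- function(clf, test) {
  if (!all(test$status %in% clf$classes)) {
    stop("test data contains class codes the classifier was not trained on")
  }
  pred <- predict(clf, test)
  truth <- as.integer(test$status)
  confusion <- table(truth = factor(truth, levels = clf$classes),
                     predicted = factor(pred, levels = clf$classes))
  scores <- decision_scores(clf, test)
  if (length(clf$classes) == 2) {
    roc <- roc_sweep(scores, truth == max(clf$classes))
    out <- list(accuracy = mean(pred == truth), confusion = confusion,
                roc = roc$points, auc = roc$auc)
  } else {
    per_class <- lapply(seq_along(clf$classes), function(j) {
      roc_sweep(scores[, j], truth == clf$classes[j])
    })
    names(per_class) <- as.character(clf$classes)
    out <- list(accuracy = mean(pred == truth), confusion = confusion,
                roc = lapply(per_class, `[[`, "points"),
                auc = mean(vapply(per_class, `[[`, numeric(1), "auc")))
  }
  structure(out, class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics: accuracy %.4f, AUC %.4f>\n", x$accuracy, x$auc))
  print(x$confusion)
  invisible(x)
}

#' Default hyperparameter grid
#'
#' `C` in \{0.1, 1, 10, 100\} by `sigma` in \{0.5, 1, 2, 5\} on z-scored
#' features, ordered so that cross-validation ties resolve toward smaller
#' `C`, then smaller `sigma`.
#' @return Data frame with columns `C` and `sigma`.
#' @export
default_grid <- function() {
  expand.grid(sigma = c(0.5, 1, 2, 5), C = c(0.1, 1, 10, 100))[, c("C", "sigma")]
}

#' Stratified k-fold cross-validation over a hyperparameter grid
#'
#' Splits the table into `k` stratified folds; each grid point is scored by
#' the mean held-out-fold accuracy over all `k` folds; ties break toward
#' smaller `C`, then smaller `sigma`.
#'
#' @param table feature table.
#' @param features feature columns to use.
#' @param k number of folds (default 10); every class must have at least
#'   `k` rows.
#' @param grid data frame of `C`, `sigma` candidates.
#' @param seed seed fixing the fold assignment.
#' @return List `best_C`, `best_sigma`, `mean_accuracy`, `results` (the
#'   grid with its mean accuracies).
#' @export
cross_validate <- function(table, features = MARKER_NAMES, k = 10,
                           grid = default_grid(), seed = 1L) {
  if (k < 2) stop("k must be at least 2")
  if (nrow(grid) == 0) stop("hyperparameter grid is empty")
  if (any(table(table$status) < k)) {
    stop("every class needs at least k rows for k-fold cross-validation")
  }
  set.seed(seed)
  fold <- integer(nrow(table))
  for (idx in split(seq_len(nrow(table)), table$status)) {
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  acc <- matrix(NA_real_, nrow(grid), k)
  for (f in seq_len(k)) {
    tr <- table[fold != f, , drop = FALSE]
    te <- table[fold == f, , drop = FALSE]
    for (g in seq_len(nrow(grid))) {
      clf <- train_classifier(tr, features, C = grid$C[g],
                              sigma = grid$sigma[g])
      acc[g, f] <- mean(predict(clf, te) == te$status)
    }
  }
  mean_acc <- rowMeans(acc)
  best <- which.max(mean_acc)   # first max: grid ordered small C, small sigma
  list(best_C = grid$C[best], best_sigma = grid$sigma[best],
       mean_accuracy = mean_acc[best],
       results = cbind(grid, mean_accuracy = mean_acc))
}

#' Pearson correlation matrix of the markers (optionally with status)
#'
#' Plain Pearson product-moment correlations,
#' \eqn{r = \sum(x-\bar x)(y-\bar y) / \sqrt{\sum(x-\bar x)^2 \sum(y-\bar y)^2}},
#' between all marker columns and (optionally) the ordinal status code.
#' Constant columns yield `NA` entries (undefined, not zero).
#'
#' @param table feature table.
#' @param include_status include the `status` column as a variable.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(table, include_status = TRUE) {
  cols <- intersect(c(MARKER_NAMES, if (include_status) "status"),
                    names(table))
  x <- as.matrix(table[, cols, drop = FALSE])
  if (nrow(x) < 3) stop("need at least 3 rows for correlations")
  sds <- apply(x, 2, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  r
}
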