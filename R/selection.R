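# train the one-vs-one binary subproblems explicitly on z-scored data;
# needed to evaluate the kernel-space margin criterion per subproblem
pairwise_svms <- function(z, y, C, sigma) {
  lev <- levels(y)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  lapply(pairs, function(pr) {
    sel <- y %in% pr
    e1071::svm(x = z[sel, , drop = FALSE], y = droplevels(y[sel]),
               scale = FALSE, kernel = "radial",
               gamma = 1 / (2 * sigma^2), cost = C)
  })
}

# W^2 = sum_ij alpha_i alpha_j y_i y_j K(x_i, x_j) over one binary model's
# support vectors; `zero` optionally zeroes a feature column in z-space
margin_criterion <- function(model, sigma, zero = NULL) {
  sv <- model$SV
  if (!is.null(zero)) sv[, zero] <- 0
  k <- gaussian_kernel_matrix(sv, sv, sigma)
  a <- as.numeric(model$coefs)   # alpha_i * y_i
  as.numeric(a %*% k %*% a)
}

#' Rank markers by SVM recursive feature elimination
#'
#' Nonlinear SVM-RFE with the kernel-space margin criterion
#' \eqn{W^2 = \sum_{ij} \alpha_i \alpha_j y_i y_j \kappa(x_i, x_j)} (summed
#' over the one-vs-one subproblems for multi-class tables).  At each round
#' the feature whose removal (zeroing its z-scored column in the kernel)
#' changes \eqn{W^2} least is eliminated; the reversed elimination order is
#' the ranking, and each feature's importance is its \eqn{|\Delta W^2|} at
#' elimination, normalised by the maximum.
#'
#' @param table feature table used for ranking (typically the training
#'   split).
#' @param features candidate feature columns.
#' @param C,sigma SVM hyperparameters used throughout the elimination.
#' @return List with `ranking` (most important first), and
#'   `normalized_importance` (named, in `[0, 1]`, max exactly 1).
#' @export
rfe_rank <- function(table, features = MARKER_NAMES, C = 10, sigma = 2) {
  if (length(features) == 1) {
    return(list(ranking = features,
                normalized_importance = stats::setNames(1, features)))
  }
  y <- factor(table$status)
  x <- as.matrix(table[, features, drop = FALSE])
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  remaining <- features
  eliminated <- character(0)
  delta_at_elim <- numeric(0)
  while (length(remaining) > 1) {
    zi <- z[, remaining, drop = FALSE]
    models <- pairwise_svms(zi, y, C, sigma)
    w2_full <- sum(vapply(models, margin_criterion, numeric(1), sigma = sigma))
    delta <- vapply(remaining, function(f) {
      w2_zero <- sum(vapply(models, margin_criterion, numeric(1),
                            sigma = sigma, zero = f))
      abs(w2_full - w2_zero)
    }, numeric(1))
    drop_f <- names(which.min(delta))
    eliminated <- c(eliminated, drop_f)
    delta_at_elim <- c(delta_at_elim, delta[[drop_f]])
    remaining <- setdiff(remaining, drop_f)
  }
  # the survivor is credited with its Delta-W^2 in the final 2-feature round
  zi <- z[, c(eliminated[length(eliminated)], remaining), drop = FALSE]
  models <- pairwise_svms(zi, y, C, sigma)
  w2_full <- sum(vapply(models, margin_criterion, numeric(1), sigma = sigma))
  w2_zero <- sum(vapply(models, margin_criterion, numeric(1),
                        sigma = sigma, zero = remaining))
  eliminated <- c(eliminated, remaining)
  delta_at_elim <- c(delta_at_elim, abs(w2_full - w2_zero))

  ranking <- rev(eliminated)
  importance <- rev(delta_at_elim)
  importance <- importance / max(importance)
  names(importance) <- ranking
  list(ranking = ranking, normalized_importance = importance)
}

#' Cross-validated accuracy versus number of top-ranked markers
#'
#' Evaluates k-fold cross-validation accuracy of the top-`m` ranked markers
#' for `m = 1..length(ranking)` at fixed hyperparameters, and reports the
#' smallest marker count whose accuracy is within half a percentage point of
#' the maximum.
#'
#' @param table feature table.
#' @param ranking marker names, most important first (from [rfe_rank()]).
#' @param k_folds number of folds (default 10).
#' @param C,sigma SVM hyperparameters.
#' @param seed fold-assignment seed.
#' @return List `optimal_k`, `accuracy_vs_k` (numeric vector, one entry per
#'   marker count).
#' @export
optimal_marker_count <- function(table, ranking, k_folds = 10, C = 10,
                                 sigma = 2, seed = 1L) {
  if (k_folds < 2) stop("k_folds must be at least 2")
  acc <- vapply(seq_along(ranking), function(m) {
    cross_validate(table, ranking[seq_len(m)], k = k_folds,
                   grid = data.frame(C = C, sigma = sigma),
                   seed = seed)$mean_accuracy
  }, numeric(1))
  list(optimal_k = which(acc >= max(acc) - 0.005)[1], accuracy_vs_k = acc)
}

#' Cumulative Gaussian-noise feature ablation
#'
#' Starting from a 70/30 split, markers are cumulatively replaced — in the
#' given importance order — by Gaussian noise (standard normal in z-scored
#' units, mapped back to the feature scale), in both the training and test
#' splits; the classifier is retrained after every replacement.  The first
#' curve entry is the unablated baseline accuracy.
#'
#' @param table feature table.
#' @param ranking marker names, most important first.
#' @param order `"high_to_low"` (ablate most important first) or
#'   `"low_to_high"` (least important first).
#' @param seed seed for the split and the noise draws.
#' @param C,sigma SVM hyperparameters (fixed across steps).
#' @param train_frac training fraction.
#' @return Numeric accuracy curve of length `length(ranking) + 1`.
#' @export
ablate_features <- function(table, ranking,
                            order = c("high_to_low", "low_to_high"),
                            seed = 1L, C = 10, sigma = 2, train_frac = 0.7) {
  order <- match.arg(order)
  if (!all(ranking %in% names(table))) stop("ranking must cover table features")
  seq_markers <- if (order == "high_to_low") ranking else rev(ranking)
  sp <- split_train_test(table, train_frac, seed)
  clf <- train_classifier(sp$train, ranking, C = C, sigma = sigma)
  curve <- numeric(length(ranking) + 1)
  curve[1] <- evaluate_classifier(clf, sp$test)$accuracy
  set.seed(seed + 1L)
  tr <- sp$train
  te <- sp$test
  for (j in seq_along(seq_markers)) {
    f <- seq_markers[j]
    # fresh standard-normal draws in z-scored units, expressed on the raw
    # feature scale with the training-split statistics
    mu <- mean(sp$train[[f]])
    sdv <- stats::sd(sp$train[[f]])
    tr[[f]] <- mu + sdv * stats::rnorm(nrow(tr))
    te[[f]] <- mu + sdv * stats::rnorm(nrow(te))
    clf_j <- train_classifier(tr, ranking, C = C, sigma = sigma)
    curve[j + 1] <- evaluate_classifier(clf_j, te)$accuracy
  }
  curve
}

#' Full marker-importance and ablation report
#'
#' Bundles [rfe_rank()], [optimal_marker_count()] and both
#' [ablate_features()] orders into one report object.
#'
#' @param table feature table.
#' @param features candidate markers.
#' @param C,sigma SVM hyperparameters.
#' @param seed seed for splits/noise.
#' @param k_folds folds for the marker-count curve.
#' @return An object of class `ablation_report`.
#' @export
ablation_report <- function(table, features = MARKER_NAMES, C = 10,
                            sigma = 2, seed = 1L, k_folds = 10) {
  rk <- rfe_rank(table, features, C = C, sigma = sigma)
  omc <- optimal_marker_count(table, rk$ranking, k_folds = k_folds,
                              C = C, sigma = sigma, seed = seed)
  structure(list(
    ranking = rk$ranking,
    normalized_importance = rk$normalized_importance,
    optimal_k = omc$optimal_k,
    accuracy_vs_k = omc$accuracy_vs_k,
    curve_high_to_low = ablate_features(table, rk$ranking, "high_to_low",
                                        seed = seed, C = C, sigma = sigma),
    curve_low_to_high = ablate_features(table, rk$ranking, "low_to_high",
                                        seed = seed, C = C, sigma = sigma)),
    class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("<ablation_report>\n  ranking:", paste(x$ranking, collapse = " > "),
      sprintf("\n  optimal marker count: %d\n", x$optimal_k))
  invisible(x)
}
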