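# Plain-JSON persistence of a trained classifier.  The stored state is the
# complete dual solution (support vectors in z-scored space, dual
# coefficients, biases), the standardizer and the kernel configuration, so
# predictions can be reproduced without libsvm from the decision-function
# contract f(x) = sum_i alpha_i y_i kappa(x_i, x) + b per binary subproblem.

#' Save / load a trained classifier as JSON
#'
#' `save_classifier()` writes every component needed to reproduce the
#' decision function: support vectors, dual coefficients, per-subproblem
#' biases, class labels and support-vector counts, the feature list, the
#' training standardizer, and `(C, sigma)`.  `load_classifier()` returns a
#' `tissue_svm_frozen` object whose `predict()` and [decision_scores()]
#' recompute the one-vs-one decision functions directly from the stored
#' state with the package's own Gaussian-kernel arithmetic.
#'
#' @param clf a [train_classifier()] model.
#' @param path JSON file path.
#' @return `save_classifier()` returns `path` invisibly;
#'   `load_classifier()` returns a `tissue_svm_frozen` object.
#' @export
save_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "tissue_svm"))
  m <- clf$model
  state <- list(
    features = clf$features,
    center = as.list(clf$center),
    scale = as.list(clf$scale),
    C = clf$C, sigma = clf$sigma,
    classes = clf$classes,
    labels = as.integer(as.character(levels(m$fitted)))[m$labels],
    n_sv = m$nSV,
    sv = apply(m$SV, 1, as.numeric, simplify = FALSE),
    coefs = apply(m$coefs, 1, as.numeric, simplify = FALSE),
    rho = m$rho)
  jsonlite::write_json(state, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) {
    if (is.list(x)) x <- do.call(rbind, x)
    if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    unname(x)
  }
  structure(list(
    features = s$features,
    center = unlist(s$center), scale = unlist(s$scale),
    C = s$C, sigma = s$sigma,
    classes = as.integer(s$classes),
    labels = as.integer(s$labels),
    n_sv = as.integer(s$n_sv),
    sv = as_mat(s$sv),
    coefs = as_mat(s$coefs),
    rho = as.numeric(s$rho)),
    class = "tissue_svm_frozen")
}

# one-vs-one decision values from the stored dual state; columns follow
# libsvm pair order (1,2), (1,3), ..., (2,3), ...
frozen_decision_matrix <- function(state, z) {
  k <- gaussian_kernel_matrix(z, state$sv, state$sigma)
  n_cls <- length(state$labels)
  starts <- cumsum(c(0, state$n_sv))
  idx <- lapply(seq_len(n_cls), function(c) {
    seq.int(starts[c] + 1, starts[c + 1])
  })
  pairs <- utils::combn(n_cls, 2, simplify = FALSE)
  dv <- matrix(0, nrow(z), length(pairs))
  cn <- character(length(pairs))
  for (p in seq_along(pairs)) {
    i <- pairs[[p]][1]; j <- pairs[[p]][2]
    ii <- idx[[i]]; jj <- idx[[j]]
    dv[, p] <- k[, ii, drop = FALSE] %*% state$coefs[ii, j - 1] +
      k[, jj, drop = FALSE] %*% state$coefs[jj, i] - state$rho[p]
    cn[p] <- paste(state$labels[i], state$labels[j], sep = "/")
  }
  colnames(dv) <- cn
  dv
}

#' @export
predict.tissue_svm_frozen <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  dv <- frozen_decision_matrix(object, z)
  n_cls <- length(object$labels)
  votes <- matrix(0L, nrow(z), n_cls)
  p <- 0L
  for (i in seq_len(n_cls - 1)) {
    for (j in seq.int(i + 1, n_cls)) {
      p <- p + 1L
      win <- dv[, p] > 0
      votes[, i] <- votes[, i] + win
      votes[, j] <- votes[, j] + !win
    }
  }
  object$labels[max.col(votes, ties.method = "first")]
}

#' @export
print.tissue_svm_frozen <- function(x, ...) {
  cat(sprintf(
    "<tissue_svm_frozen: classes {%s}, %d features, C = %g, sigma = %g>\n",
    paste(x$classes, collapse = ", "), length(x$features), x$C, x$sigma))
  invisible(x)
}
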