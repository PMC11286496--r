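#' Drug-efficacy recovery report from pairwise classification accuracies
#'
#' Quantifies how far a treated group has moved away from the diseased state
#' toward the healthy state: a classifier that can no longer distinguish
#' treated from healthy tissue (accuracy near chance) while cleanly
#' separating treated from diseased tissue indicates recovery.  Two binary
#' Gaussian-kernel SVMs are trained with the standard stratified 70/30
#' protocol on all nine markers: treated-vs-healthy (accuracy `acc_TH`) and
#' treated-vs-diseased (`acc_TD`).  The recovery index is `acc_TD - acc_TH`;
#' the verdict is `full_recovery` when `acc_TH <= 0.60` and
#' `acc_TD >= 0.80`, `no_recovery` when `acc_TD <= 0.60` and
#' `acc_TH >= 0.80`, otherwise `partial_recovery`.
#'
#' @param table feature table containing all three statuses \{0, 1, 2\}.
#' @param features marker columns used by both classifiers.
#' @param C,sigma optional fixed hyperparameters; if `NULL`, each task is
#'   tuned by 10-fold cross-validated grid search on its training split.
#' @param grid hyperparameter grid for tuning.
#' @param seed seed for splits and fold assignment.
#' @param train_frac training fraction.
#' @return An object of class `recovery_report` with fields
#'   `acc_treated_vs_healthy`, `acc_treated_vs_diseased`, `recovery_index`
#'   and `verdict`.
#' @export
recovery_report <- function(table, features = MARKER_NAMES, C = NULL,
                            sigma = NULL, grid = default_grid(), seed = 1L,
                            train_frac = 0.7) {
  if (!all(0:2 %in% table$status)) {
    stop("recovery assessment needs all three statuses (0, 1, 2)")
  }
  pair_acc <- function(statuses) {
    sub <- table[table$status %in% statuses, , drop = FALSE]
    sp <- split_train_test(sub, train_frac, seed)
    if (is.null(C) || is.null(sigma)) {
      cv <- cross_validate(sp$train, features, k = 10, grid = grid,
                           seed = seed)
      cc <- cv$best_C; ss <- cv$best_sigma
    } else {
      cc <- C; ss <- sigma
    }
    clf <- train_classifier(sp$train, features, C = cc, sigma = ss)
    evaluate_classifier(clf, sp$test)$accuracy
  }
  acc_th <- pair_acc(c(1, 0))
  acc_td <- pair_acc(c(1, 2))
  verdict <- if (acc_th <= 0.60 && acc_td >= 0.80) {
    "full_recovery"
  } else if (acc_td <= 0.60 && acc_th >= 0.80) {
    "no_recovery"
  } else {
    "partial_recovery"
  }
  structure(list(acc_treated_vs_healthy = acc_th,
                 acc_treated_vs_diseased = acc_td,
                 recovery_index = acc_td - acc_th,
                 verdict = verdict),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<recovery_report>\n",
    "  treated vs healthy accuracy:  %.3f\n",
    "  treated vs diseased accuracy: %.3f\n",
    "  recovery index: %+.3f  ->  %s\n"),
    x$acc_treated_vs_healthy, x$acc_treated_vs_diseased,
    x$recovery_index, x$verdict))
  invisible(x)
}
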