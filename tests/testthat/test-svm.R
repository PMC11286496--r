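test_that("gaussian kernel: unit self-similarity, closed form, symmetry", {
  expect_identical(gaussian_kernel(c(1, 2), c(1, 2), 1), 1)
  # squared distance of 2 sigma^2 gives exp(-1)
  expect_equal(gaussian_kernel(c(0, 0), c(2, 0), sigma = sqrt(2)), exp(-1))
  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(5); s <- runif(1, 0.5, 3)
    expect_equal(gaussian_kernel(a, b, s), gaussian_kernel(b, a, s))
  }
  expect_error(gaussian_kernel(1:3, 1:4, 1), "equal length")
  expect_error(gaussian_kernel(1:3, 1:3, 0), "positive")
})

test_that("kernel matrices are positive semi-definite", {
  set.seed(12)
  for (i in 1:5) {
    x <- matrix(rnorm(40 * 4), 40)
    k <- viscomarker:::gaussian_kernel_matrix(x, sigma = runif(1, 0.5, 3))
    expect_gt(min(eigen(k, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("stratified split: sizes, determinism, partition", {
  tab <- data.frame(status = rep(c(0L, 2L), each = 800), x = rnorm(1600))
  sp <- split_train_test(tab, 0.7, seed = 4)
  expect_identical(as.integer(table(sp$train$status)), c(560L, 560L))
  expect_identical(as.integer(table(sp$test$status)), c(240L, 240L))
  sp2 <- split_train_test(tab, 0.7, seed = 4)
  expect_identical(sp$train, sp2$train)
  expect_identical(sort(c(rownames(sp$train), rownames(sp$test))),
                   sort(rownames(tab)))
  expect_error(split_train_test(data.frame(status = c(0, 1), x = 1:2), 1.2),
               "0, 1")
})

test_that("RBF-SVM solves separable and XOR toys; chance on pure noise", {
  # far-separated clouds: perfect training accuracy
  tab <- blob_table(n = 120, gap = 10, seed = 3)
  clf <- train_classifier(tab, c("x1", "x2"), C = 10, sigma = 1)
  expect_identical(mean(predict(clf, tab) == tab$status), 1)

  # XOR pattern is linearly inseparable but RBF-separable
  set.seed(5)
  n <- 400
  cx <- sample(c(0, 4), n, TRUE); cy <- sample(c(0, 4), n, TRUE)
  xor_tab <- data.frame(status = as.integer(xor(cx > 1, cy > 1)) * 2L,
                        x1 = rnorm(n, cx, 0.5), x2 = rnorm(n, cy, 0.5))
  sp <- split_train_test(xor_tab, 0.7, seed = 6)
  cv <- cross_validate(sp$train, c("x1", "x2"), k = 5, seed = 6)
  clf <- train_classifier(sp$train, c("x1", "x2"), cv$best_C, cv$best_sigma)
  expect_gte(evaluate_classifier(clf, sp$test)$accuracy, 0.95)

  # pure-noise features: test accuracy near chance
  set.seed(9)
  noise_tab <- data.frame(status = rep(c(0L, 2L), 200),
                          x1 = rnorm(400), x2 = rnorm(400))
  sp <- split_train_test(noise_tab, 0.7, seed = 9)
  clf <- train_classifier(sp$train, c("x1", "x2"), C = 1, sigma = 1)
  acc <- evaluate_classifier(clf, sp$test)$accuracy
  expect_gt(acc, 0.5 - 0.08); expect_lt(acc, 0.5 + 0.08)
})

test_that("zero-variance features are tolerated with a warning", {
  tab <- blob_table(n = 80, gap = 6, seed = 2)
  tab$flat <- 1
  expect_warning(clf <- train_classifier(tab, c("x1", "flat"), 10, 1),
                 "zero-variance")
  expect_gt(mean(predict(clf, tab) == tab$status), 0.95)
})

test_that("evaluation metrics: accuracy, confusion, ROC symmetry", {
  tab <- blob_table(n = 200, gap = 8, seed = 7)
  sp <- split_train_test(tab, 0.7, seed = 7)
  clf <- train_classifier(sp$train, c("x1", "x2"), 10, 1)
  ev <- evaluate_classifier(clf, sp$test)
  expect_identical(ev$accuracy, 1)
  expect_equal(ev$auc, 1)
  expect_identical(as.integer(rowSums(ev$confusion)),
                   as.integer(table(sp$test$status)))

  # inverting the scores mirrors the ROC: AUC' = 1 - AUC
  sc <- decision_scores(clf, sp$test)
  pos <- sp$test$status == 2
  auc <- viscomarker:::roc_sweep(sc, pos)$auc
  auc_inv <- viscomarker:::roc_sweep(-sc, pos)$auc
  expect_equal(auc_inv, 1 - auc)

  bad <- sp$test; bad$status[1] <- 7L
  expect_error(evaluate_classifier(clf, bad), "not trained")
})

test_that("binary AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  tab <- blob_table(n = 160, gap = 1.5, seed = 13)
  sp <- split_train_test(tab, 0.7, seed = 13)
  clf <- train_classifier(sp$train, c("x1", "x2"), 1, 1)
  sc <- decision_scores(clf, sp$test)
  mine <- viscomarker:::roc_sweep(sc, sp$test$status == 2)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(sp$test$status, sc, quiet = TRUE,
                                        direction = "<", levels = c(0, 2))))
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("the decision function is reproducible from the stored model state", {
  # f(x) = sum_i alpha_i y_i kappa(x_i, x) + b, rebuilt from the stored
  # support vectors and dual coefficients with the package's own kernel
  tab <- blob_table(n = 120, gap = 2, seed = 15)
  clf <- train_classifier(tab, c("x1", "x2"), C = 5, sigma = 1.5)
  z <- viscomarker:::standardize_features(clf, tab)
  m <- clf$model
  k <- viscomarker:::gaussian_kernel_matrix(z, m$SV, sigma = 1.5)
  f_mine <- as.numeric(k %*% as.numeric(m$coefs)) - m$rho
  f_libsvm <- attr(stats::predict(m, z, decision.values = TRUE),
                   "decision.values")[, 1]
  expect_equal(f_mine, unname(f_libsvm), tolerance = 1e-8)
})

test_that("cross-validation: folds, determinism, tie-breaking, degenerate grid", {
  tab <- blob_table(n = 1600, gap = 2, seed = 10)
  set.seed(10)
  fold_sizes <- table(unlist(lapply(split(1:1600, tab$status),
                                    function(i) rep_len(1:10, length(i)))))
  expect_true(all(abs(fold_sizes - 160) <= 1))

  sub <- tab[c(1:150, 801:950), ]
  single <- cross_validate(sub, c("x1", "x2"), k = 5,
                           grid = data.frame(C = 7, sigma = 3), seed = 2)
  expect_identical(single$best_C, 7)
  expect_identical(single$best_sigma, 3)

  a <- cross_validate(sub, c("x1", "x2"), k = 5, seed = 3)
  b <- cross_validate(sub, c("x1", "x2"), k = 5, seed = 3)
  expect_identical(a$results, b$results)

  # a fully separable toy ties many grid points at accuracy 1; the winner
  # must be the smallest C, then the smallest sigma among them
  sep <- blob_table(n = 200, gap = 12, seed = 11)
  cv <- cross_validate(sep, c("x1", "x2"), k = 5, seed = 4)
  res <- cv$results
  top <- res[res$mean_accuracy == max(res$mean_accuracy), ]
  expect_identical(cv$best_C, min(top$C))
  expect_identical(cv$best_sigma, min(top$sigma[top$C == cv$best_C]))

  expect_error(cross_validate(tab, c("x1", "x2"), k = 5,
                              grid = data.frame()[0, ]), "empty")
})

test_that("pearson matrix matches hand-evaluated correlations", {
  tab <- data.frame(status = c(0L, 1L, 2L),
                    Esum = c(1, 2, 3), eta = c(2, 4, 5))
  r <- pearson_matrix(tab)
  expect_equal(r["Esum", "eta"], 3 / sqrt(2 * 4.666667), tolerance = 1e-6)
  expect_true(isSymmetric(r))
  expect_true(all(diag(r) == 1))

  x <- rnorm(20)
  tab2 <- data.frame(status = rep(0:1, 10), Esum = x, eta = 2 * x + 3,
                     fT = -x)
  r2 <- pearson_matrix(tab2, include_status = FALSE)
  expect_equal(r2["Esum", "eta"], 1)
  expect_equal(r2["Esum", "fT"], -1)

  tab2$tau <- 5  # constant column: undefined, reported as missing
  r3 <- pearson_matrix(tab2, include_status = FALSE)
  expect_true(all(is.na(r3["tau", ])))
})

test_that("label permutation yields chance-level accuracy", {
  tab <- blob_table(n = 300, gap = 5, seed = 17)
  set.seed(18)
  tab$status <- sample(tab$status)
  sp <- split_train_test(tab, 0.7, seed = 18)
  clf <- train_classifier(sp$train, c("x1", "x2"), C = 1, sigma = 1)
  acc <- evaluate_classifier(clf, sp$test)$accuracy
  expect_lt(abs(acc - 0.5), 0.1)
})
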