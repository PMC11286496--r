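test_that("noiseless fits recover every model parameter within 5%", {
  t <- default_times()
  set.seed(21)
  specs <- default_group_specs()
  draws <- do.call(rbind, lapply(specs, sample_group_params, n = 4))
  for (i in seq_len(nrow(draws))) {
    truth <- visco_params(draws$E1[i], draws$E2[i], draws$E3[i],
                          draws$eta[i], draws$alphaL[i], draws$alphaR[i])
    fit <- fit_hierarchical_model(creep_compliance(truth, t))
    expect_true(fit$converged)
    expect_gte(fit$r_squared, 0.999)
    for (nm in c("E1", "E2", "E3", "eta", "alphaL", "alphaR")) {
      expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 0.05,
                   label = sprintf("%s (draw %d)", nm, i))
    }
    expect_equal(fit$derived$Esum, draws$Esum[i], tolerance = 0.05)
    expect_equal(fit$derived$tau, draws$tau[i], tolerance = 0.05)
  }
})

test_that("noiseless fits reach R^2 = 1 to within 1e-6", {
  t <- default_times()
  fit <- fit_hierarchical_model(creep_compliance(healthy_params(), t))
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
})

test_that("double power-law windows recover exact and two-branch exponents", {
  t <- default_times()
  # exact single power law gives the same slope in both windows
  mono <- creep_curve(t, 0.01 * t^0.9, "compliance")
  pl <- fit_double_power_law(mono)
  expect_equal(pl$alphaL_hat, 0.9, tolerance = 1e-10)
  expect_equal(pl$alphaR_hat, 0.9, tolerance = 1e-10)

  # healthy two-branch curve: short-time exponent in (0.5, 1), long-time
  # exponent near 0.2
  pl <- fit_double_power_law(creep_compliance(healthy_params(), t))
  expect_gt(pl$alphaL_hat, 0.5); expect_lt(pl$alphaL_hat, 1.0)
  expect_equal(pl$alphaR_hat, 0.20, tolerance = 0.25)
  expect_lt(abs(pl$alphaR_hat - 0.20), 0.05)

  expect_error(fit_double_power_law(mono, short_window = c(0.02, 4)),
               "disjoint")
  expect_error(fit_double_power_law(mono, long_window = c(3, 50)), "grid")
})

test_that("window exponents agree with the local-slope medians", {
  t <- default_times()
  set.seed(4)
  for (nm in c("healthy", "diseased")) {
    spec <- default_group_specs()[[nm]]
    d <- sample_group_params(spec, n = 1)
    p <- visco_params(d$E1, d$E2, d$E3, d$eta, d$alphaL, d$alphaR)
    curve <- creep_compliance(p, t)
    pl <- fit_double_power_law(curve)
    sl <- local_loglog_slope(curve, 7)
    expect_equal(pl$alphaL_hat, median(sl[t <= 0.1]), tolerance = 0.03)
    expect_equal(pl$alphaR_hat, median(sl[t >= 3]), tolerance = 0.03)
  }
})

test_that("fit-quality filtering keeps rows with good fits and drops bad ones", {
  co <- small_cohort(n = 8, seed = 31)
  ft <- extract_features(co)
  expect_identical(nrow(ft), 24L)
  expect_identical(names(ft),
                   c("measurement_id", "status", "E1", "E2", "E3", "Esum",
                     "eta", "tau", "fT", "alphaL", "alphaR"))
  expect_false(anyNA(ft))

  # forcing one fit below the threshold drops exactly one row
  t <- default_times()
  curves <- lapply(1:6, function(i) creep_compliance(healthy_params(), t))
  fits <- lapply(curves, fit_hierarchical_model)
  fits[[3]]$r_squared <- 0.5
  pl <- data.frame(alphaL_hat = rep(0.8, 6), alphaR_hat = rep(0.2, 6))
  tab <- build_feature_table(fits, pl, status = rep(0L, 6))
  expect_identical(nrow(tab), 5L)
  expect_identical(attr(tab, "fit_report")$n_low_r2, 1L)

  # filtering is idempotent: refiltering an already-clean table changes
  # nothing
  keep2 <- build_feature_table(fits[-3], pl[-3, ], status = rep(0L, 5))
  expect_identical(tab[, -1], keep2[, -1])

  # mass failure warns loudly instead of erroring
  for (i in 1:4) fits[[i]]$r_squared <- 0.1
  expect_warning(build_feature_table(fits, pl, status = rep(0L, 6)),
                 "dropped")
})

test_that("extraction tracks ground truth at the default noise level", {
  co <- small_cohort(n = 25, seed = 41)
  ft <- extract_features(co)
  expect_gte(nrow(ft) / 75, 0.95)
  gt <- co$ground_truth
  gt <- gt[gt$measurement_id %in% ft$measurement_id, ]
  # within-group rank agreement of extracted vs true Esum
  for (s in 0:2) {
    rho <- cor(ft$Esum[ft$status == s], gt$Esum[gt$status == s],
               method = "spearman")
    expect_gte(rho, 0.9)
  }
  expect_gte(attr(ft, "fit_report")$median_r2, 0.9)
})
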