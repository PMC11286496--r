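test_that("Laplace-domain modulus matches hand-evaluated closed forms", {
  # elastic limit: only the network spring survives
  spring <- visco_params(0, 0, 456.1, 0, 0.9, 0.2, strict = FALSE)
  expect_equal(laplace_modulus(spring, c(0.01, 1, 50)), rep(456.1, 3))

  # single spring-pot: E * s^alpha
  sp <- visco_params(100, 0, 0, 0, 0.5, 0.2, strict = FALSE)
  expect_equal(laplace_modulus(sp, 4), 100 * 2)

  # sum of all branches at the reference rate s = 1
  full <- visco_params(100, 200, 156.1, 50, 0.85, 0.20)
  expect_equal(laplace_modulus(full, 1), 506.1)

  expect_error(laplace_modulus(full, -1), "positive")
  expect_error(laplace_modulus(full, 0), "positive")
})

test_that("laplace modulus is increasing in s with plateau E3 at low rates", {
  set.seed(42)
  for (i in 1:20) {
    p <- visco_params(runif(1, 10, 1000), runif(1, 10, 1000),
                      runif(1, 10, 1000), runif(1, 1, 100),
                      runif(1, 0.55, 0.95), runif(1, 0.12, 0.33))
    s <- sort(10^runif(8, -3, 3))
    g <- laplace_modulus(p, s)
    expect_true(all(diff(g) > 0))
    # excess over the E3 plateau vanishes as s -> 0 (slow power-law tail)
    excess_low <- laplace_modulus(p, 1e-12) - p$E3
    expect_gt(excess_low, 0)
    expect_lt(excess_low, 0.1 * (laplace_modulus(p, 1) - p$E3))
  }
})

test_that("Stehfest creep compliance matches the three closed-form limits", {
  t <- default_times()
  # Hookean spring: J = 1/E3
  spring <- visco_params(0, 0, 456.1, 0, 0.9, 0.2, strict = FALSE)
  j <- creep_compliance(spring, t)$values
  expect_lt(max(abs(j * 456.1 - 1)), 5e-3)

  # Newtonian dashpot: J = t / eta
  dash <- visco_params(0, 0, 0, 50, 0.9, 0.2, strict = FALSE)
  j <- creep_compliance(dash, t)$values
  expect_lt(max(abs(j - t / 50) / (t / 50)), 5e-3)

  # single spring-pot: J = t^alpha / (E * gamma(1 + alpha))
  pot <- visco_params(100, 0, 0, 0, 0.6, 0.2, strict = FALSE)
  j <- creep_compliance(pot, t)$values
  ref <- t^0.6 / (100 * gamma(1.6))
  expect_lt(max(abs(j - ref) / ref), 5e-3)
})

test_that("creep compliance is positive, non-decreasing, with the expected slopes", {
  t <- default_times()
  set.seed(7)
  for (i in 1:15) {
    p <- visco_params(10^runif(1, 1, 3), 10^runif(1, 1, 3),
                      10^runif(1, 1, 3), 10^runif(1, 0, 2),
                      runif(1, 0.55, 0.95), runif(1, 0.12, 0.33))
    j <- creep_compliance(p, t)$values
    expect_true(all(j > 0))
    expect_true(all(diff(j) > -1e-15))
  }

  # the default healthy curve shows the two-stage scaling law
  sl <- local_loglog_slope(creep_compliance(healthy_params(), t))
  expect_true(all(sl[t <= 0.1] > 0.5 & sl[t <= 0.1] < 1.0))
  expect_true(all(abs(sl[t >= 3] - 0.2) < 0.05 + 1e-9))

  expect_error(creep_compliance(healthy_params(), c(1e-4, 1)), "within")
})

test_that("Hertz conversion matches Eq-level hand evaluation and is involutive", {
  proto <- indentation_protocol(force = 1e-8, probe_radius = 1e-5,
                                poisson = 0.5)
  t <- default_times(10)
  delta <- creep_curve(t, rep(1e-7, 10), "indentation")
  j <- hertz_compliance(delta, proto)
  # 4 sqrt(1e-5) (1e-7)^1.5 / (3e-8 * 0.75)
  expect_equal(j$values, rep(1.77777e-5, 10), tolerance = 1e-4)

  # doubling the force halves the compliance
  proto2 <- indentation_protocol(force = 2e-8, probe_radius = 1e-5)
  expect_equal(hertz_compliance(delta, proto2)$values, j$values / 2)

  # round trip is the identity to machine precision
  back <- hertz_indentation(j, proto)
  expect_equal(back$values, delta$values, tolerance = 1e-12)

  # Poisson's ratio enters as (1 - nu^2)^{2/3} in the indentation
  proto0 <- indentation_protocol(force = 1e-8, probe_radius = 1e-5,
                                 poisson = 0)
  d0 <- hertz_indentation(j, proto0)
  d5 <- hertz_indentation(j, proto)
  expect_equal(d5$values / d0$values, rep(0.75^(2 / 3), 10))

  expect_error(indentation_protocol(force = 0), "positive")
  expect_error(hertz_compliance(j, proto), "indentation")
})

test_that("derived markers: Esum, tau and the branch-crossing frequency", {
  p <- visco_params(100, 200, 156.1, 50, 0.85, 0.20)
  d <- derived_markers(p)
  expect_equal(d$Esum, 456.1)
  expect_equal(d$tau, 0.5)
  expect_equal(d$fT, 2^(1 / 0.65) / (2 * pi), tolerance = 1e-12)

  # fT is where the two power-law branches are equal (bisection oracle)
  set.seed(3)
  for (i in 1:10) {
    p <- visco_params(10^runif(1, 1, 3), 10^runif(1, 1, 3), 50, 10,
                      runif(1, 0.6, 0.95), runif(1, 0.12, 0.3))
    root <- uniroot(function(w) p$E1 * w^p$alphaL - p$E2 * w^p$alphaR,
                    c(1e-8, 1e8), tol = 1e-12)$root
    expect_equal(derived_markers(p)$fT, root / (2 * pi), tolerance = 1e-6)
  }

  expect_error(derived_markers(visco_params(1, 1, 1, 1, 0.5, 0.5,
                                            strict = FALSE)),
               "degenerate")
})

test_that("local log-log slope recovers exact power laws, edges included", {
  t <- default_times(40)
  pow <- creep_curve(t, 3 * t^0.5, "compliance")
  expect_equal(local_loglog_slope(pow, 7), rep(0.5, 40), tolerance = 1e-10)

  const <- creep_curve(t, rep(2, 40), "compliance")
  expect_equal(local_loglog_slope(const, 7), rep(0, 40), tolerance = 1e-12)

  expect_error(local_loglog_slope(pow, 4), "odd")
  expect_error(local_loglog_slope(pow, 1), "odd")
})

test_that("creep records enforce their invariants and survive a CSV round trip", {
  t <- default_times(12)
  expect_error(creep_curve(t[1:7], rep(1, 7)), "at least 8")
  expect_error(creep_curve(rev(t), rep(1, 12)), "increasing")
  expect_error(creep_curve(t, c(rep(1, 11), -1)), "positive")

  curve <- creep_curve(t, t^0.3, "indentation")
  path <- withr::local_tempfile(fileext = ".csv")
  write_creep_csv(curve, path, metadata = list(group = 2))
  back <- read_creep_csv(path)
  expect_equal(back$times, curve$times)
  expect_equal(back$values, curve$values)
  expect_identical(back$kind, "indentation")
  expect_identical(attr(back, "metadata")$group, "2")
})
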