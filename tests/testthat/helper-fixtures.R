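# shared fixtures built in code: small cohorts and reference parameter sets

default_times <- function(n = 60) exp(seq(log(0.02), log(10), length.out = n))

healthy_params <- function() {
  visco_params(E1 = 100, E2 = 300, E3 = 56.1, eta = 12,
               alphaL = 0.85, alphaR = 0.20)
}

# small three-group cohort (same group means as the defaults, fewer rows)
small_cohort <- function(n = 60, seed = 101, curves = TRUE, noise_sd = 0.03) {
  generate_cohort(cohort_config(group_specs = default_group_specs(n = n),
                                noise_sd = noise_sd, seed = seed),
                  include_curves = curves)
}

# two-cluster binary toy table with optional pure-noise feature columns
blob_table <- function(n = 100, gap = 6, n_noise = 0, seed = 1) {
  set.seed(seed)
  half <- n %/% 2
  tab <- data.frame(status = rep(c(0L, 2L), each = half),
                    x1 = c(stats::rnorm(half), stats::rnorm(half, gap)),
                    x2 = c(stats::rnorm(half), stats::rnorm(half, gap)))
  for (k in seq_len(n_noise)) tab[[paste0("noise", k)]] <- stats::rnorm(n)
  tab
}
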