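# Conversion between the cohort's nominal stress unit U (numbers as printed
# in group statistics) and SI pascals used for the Hertz indentation
# round-trip: 1 U = 1 kPa, a physiologically plausible scale for liver
# tissue.  Classification is invariant to this choice after z-scoring.
COHORT_UNIT_PA <- 1e3

#' Distributional specification of one tissue group
#'
#' Describes how the viscoelastic parameters of one group (healthy = 0,
#' drug-treated = 1, diseased/fibrotic = 2) are distributed across
#' measurements.  Moduli and viscosity are lognormal (parameterised by mean
#' and coefficient of variation); `E2` and `E3` are tied to `E1` through
#' lognormal ratios so the three moduli are strongly positively correlated
#' within a group, as observed in tissue; exponents are truncated normal with
#' `alphaL` in (0.5, 1.0), `alphaR` in (0.10, 0.35) and `alphaL > alphaR`
#' per draw.
#'
#' @param status integer group code: 0 healthy, 1 treated, 2 diseased.
#' @param mean_E1 mean cytoplasm modulus, U.
#' @param mean_E2_ratio,mean_E3_ratio mean ratios `E2/E1` and `E3/E1`.
#' @param cov_E1,cov_ratios,cov_eta coefficients of variation.
#' @param mean_eta mean viscosity, U*s.
#' @param mean_alphaL,sd_alphaL,mean_alphaR,sd_alphaR exponent distribution.
#' @param n number of measurements in the group.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(status, mean_E1, mean_E2_ratio, mean_E3_ratio,
                       cov_E1, cov_ratios, mean_eta, cov_eta,
                       mean_alphaL, sd_alphaL, mean_alphaR, sd_alphaR,
                       n = 800L) {
  if (!status %in% 0:2) stop("status must be 0 (healthy), 1 (treated) or 2 (diseased)")
  if (mean_alphaL <= 0.5 || mean_alphaL >= 1.0) {
    stop("mean_alphaL must lie inside the truncation bounds (0.5, 1.0)")
  }
  if (mean_alphaR <= 0.10 || mean_alphaR >= 0.35) {
    stop("mean_alphaR must lie inside the truncation bounds (0.10, 0.35)")
  }
  if (any(c(mean_E1, mean_E2_ratio, mean_E3_ratio, mean_eta) <= 0)) {
    stop("means of moduli, ratios and viscosity must be positive")
  }
  if (n < 0) stop("n must be non-negative")
  structure(list(status = as.integer(status), mean_E1 = mean_E1,
                 mean_E2_ratio = mean_E2_ratio, mean_E3_ratio = mean_E3_ratio,
                 cov_E1 = cov_E1, cov_ratios = cov_ratios,
                 mean_eta = mean_eta, cov_eta = cov_eta,
                 mean_alphaL = mean_alphaL, sd_alphaL = sd_alphaL,
                 mean_alphaR = mean_alphaR, sd_alphaR = sd_alphaR,
                 n = as.integer(n)),
            class = "group_spec")
}

#' Default group calibration for the three liver states
#'
#' The calibration targets the published group statistics: mean total modulus
#' `Esum` of 456.1 U (healthy), 681.4 U (treated) and 2280.5 U (diseased,
#' i.e. five times healthy); short-time exponents in (0.5, 1.0) falling with
#' disease severity; long-time exponents near 0.2 throughout.  The spreads
#' (modulus CoV 0.39, ratio CoV 0.10, viscosity CoV 0.40) make healthy and
#' diseased tissue nearly separable on `Esum` alone while leaving healthy and
#' treated heavily overlapped in `Esum`, so the treated-state signal is
#' carried mostly by `alphaL`, `fT` and `eta`.  Mean viscosities (12 / 14 /
#' 25 U s, rising with disease severity) are set so the dashpot stays a
#' subdominant (roughly 25 percent) contribution at the window's shortest
#' times: large enough to be measurable, small enough that the short-time
#' power-law branch — the exponent `alphaL` — remains observable in every
#' group.
#'
#' @param n measurements per group (default 800).
#' @return List of three [group_spec()] objects named `healthy`, `treated`,
#'   `diseased`.
#' @export
default_group_specs <- function(n = 800L) {
  base <- function(status, scale, eta, aL, aR, n) {
    group_spec(status = status, mean_E1 = 100 * scale,
               mean_E2_ratio = 3.0, mean_E3_ratio = 0.561,
               cov_E1 = 0.39, cov_ratios = 0.10,
               mean_eta = eta, cov_eta = 0.40,
               mean_alphaL = aL, sd_alphaL = 0.05,
               mean_alphaR = aR, sd_alphaR = 0.025, n = n)
  }
  list(healthy  = base(0L, 1.000, eta = 12, aL = 0.85, aR = 0.20, n = n),
       treated  = base(1L, 1.494, eta = 14, aL = 0.72, aR = 0.21, n = n),
       diseased = base(2L, 5.000, eta = 25, aL = 0.55, aR = 0.22, n = n))
}

#' Cohort simulation configuration
#'
#' @param group_specs list of three [group_spec()]s with distinct status
#'   codes.
#' @param protocol an [indentation_protocol()].
#' @param noise_sd relative multiplicative measurement noise on indentation
#'   (lognormal; in `[0, 0.2]`).
#' @param seed integer seed controlling all randomness of the cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(group_specs = default_group_specs(),
                          protocol = indentation_protocol(),
                          noise_sd = 0.03, seed = 1L) {
  statuses <- vapply(group_specs, function(g) g$status, integer(1))
  if (anyDuplicated(statuses)) stop("group status codes must be distinct")
  if (noise_sd < 0 || noise_sd > 0.2) stop("noise_sd must lie in [0, 0.2]")
  structure(list(group_specs = group_specs, protocol = protocol,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

# lognormal draws parameterised by arithmetic mean and coefficient of
# variation
rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  todo <- seq_len(n)
  guard <- 0L
  while (length(todo)) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw > lower & draw < upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
    guard <- guard + 1L
    if (guard > 1000L) {
      stop("truncation bounds incompatible with the requested mean/sd")
    }
  }
  out
}

#' Draw ground-truth viscoelastic parameters for one group
#'
#' Samples `n` parameter sets from a [group_spec()] using the current RNG
#' state (set the seed beforehand for reproducibility).  Exponent pairs are
#' redrawn until `alphaL > alphaR + 0.1`.
#'
#' @param spec a [group_spec()].
#' @param n number of draws (defaults to `spec$n`).
#' @return Data frame with columns `status`, `E1`, `E2`, `E3`, `Esum`,
#'   `eta`, `tau`, `fT`, `alphaL`, `alphaR` (ground truth, cohort stress units U).
#' @export
sample_group_params <- function(spec, n = spec$n) {
  if (n == 0L) {
    return(data.frame(status = integer(0), E1 = numeric(0), E2 = numeric(0),
                      E3 = numeric(0), Esum = numeric(0), eta = numeric(0),
                      tau = numeric(0), fT = numeric(0), alphaL = numeric(0),
                      alphaR = numeric(0)))
  }
  E1 <- rlnorm_mean_cv(n, spec$mean_E1, spec$cov_E1)
  r12 <- rlnorm_mean_cv(n, spec$mean_E2_ratio, spec$cov_ratios)
  r13 <- rlnorm_mean_cv(n, spec$mean_E3_ratio, spec$cov_ratios)
  eta <- rlnorm_mean_cv(n, spec$mean_eta, spec$cov_eta)
  aL <- rtrunc_norm(n, spec$mean_alphaL, spec$sd_alphaL, 0.5, 1.0)
  aR <- rtrunc_norm(n, spec$mean_alphaR, spec$sd_alphaR, 0.10, 0.35)
  # redraw pairs violating the exponent gap (cannot occur under the default
  # truncation bounds, but enforced for user-supplied specs)
  bad <- which(aL <= aR + 0.1)
  guard <- 0L
  while (length(bad)) {
    aL[bad] <- rtrunc_norm(length(bad), spec$mean_alphaL, spec$sd_alphaL, 0.5, 1.0)
    aR[bad] <- rtrunc_norm(length(bad), spec$mean_alphaR, spec$sd_alphaR, 0.10, 0.35)
    bad <- bad[aL[bad] <= aR[bad] + 0.1]
    guard <- guard + 1L
    if (guard > 1000L) stop("cannot satisfy alphaL > alphaR + 0.1")
  }
  E2 <- E1 * r12
  E3 <- E1 * r13
  data.frame(status = rep(spec$status, n), E1 = E1, E2 = E2, E3 = E3,
             Esum = E1 + E2 + E3, eta = eta, tau = eta / E1,
             fT = (1 / (2 * pi)) * (E2 / E1)^(1 / (aL - aR)),
             alphaL = aL, alphaR = aR)
}

#' Simulate one AFM creep measurement
#'
#' Runs the forward model for one parameter set: creep compliance of the
#' hierarchical model, converted to indentation depth through the inverse
#' Hertz map (with 1 U = 1 kPa), then corrupted by pointwise multiplicative
#' lognormal noise `exp(eps)`, `eps ~ N(0, noise_sd)`.  No monotonicity
#' enforcement is applied: noise may create local dips, which downstream
#' fitting must tolerate.
#'
#' @param params a [visco_params()] object (cohort stress units U).
#' @param protocol an [indentation_protocol()].
#' @param noise_sd relative noise level in `[0, 0.2]`.
#' @return An indentation [creep_curve()] (metres).
#' @export
simulate_measurement <- function(params, protocol, noise_sd = 0.03) {
  if (noise_sd < 0 || noise_sd > 0.2) stop("noise_sd must lie in [0, 0.2]")
  times <- protocol_times(protocol)
  j_u <- creep_compliance(params, times)
  j_si <- creep_curve(times, j_u$values / COHORT_UNIT_PA, kind = "compliance")
  delta <- hertz_indentation(j_si, protocol)
  if (noise_sd > 0) {
    delta$values <- delta$values *
      exp(stats::rnorm(length(delta$values), 0, noise_sd))
  }
  delta
}

#' Generate a labelled synthetic cohort
#'
#' Draws ground-truth parameters for every group of a [cohort_config()] and
#' (optionally) simulates the corresponding noisy indentation records.  The
#' whole cohort is reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param include_curves simulate the indentation records (set `FALSE` when
#'   only the ground-truth marker table is needed).
#' @return An object of class `cohort_dataset`: a list with `ground_truth`
#'   (data frame: `measurement_id`, `status` and the nine markers),
#'   `curves` (list of indentation [creep_curve()]s or `NULL`), `protocol`
#'   and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), include_curves = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ord <- order(vapply(config$group_specs, function(g) g$status, integer(1)))
  specs <- config$group_specs[ord]
  gt <- do.call(rbind, lapply(specs, sample_group_params))
  rownames(gt) <- NULL
  gt <- cbind(measurement_id = sprintf("m%04d", seq_len(nrow(gt))), gt,
              stringsAsFactors = FALSE)
  curves <- NULL
  if (include_curves) {
    curves <- lapply(seq_len(nrow(gt)), function(i) {
      p <- visco_params(gt$E1[i], gt$E2[i], gt$E3[i], gt$eta[i],
                        gt$alphaL[i], gt$alphaR[i])
      simulate_measurement(p, config$protocol, config$noise_sd)
    })
    names(curves) <- gt$measurement_id
  }
  structure(list(ground_truth = gt, curves = curves,
                 protocol = config$protocol, config = config),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  tab <- table(x$ground_truth$status)
  cat(sprintf("<cohort_dataset: %d measurements (%s)%s>\n",
              nrow(x$ground_truth),
              paste(sprintf("status %s: %d", names(tab), tab), collapse = ", "),
              if (is.null(x$curves)) ", ground truth only" else ""))
  invisible(x)
}

#' Write a cohort to disk as plain-text artifacts
#'
#' Writes `ground_truth.csv`, `cohort_manifest.json` and (if curves are
#' present) one CSV per measurement under `measurements/`.
#'
#' @param cohort a [cohort_dataset()][generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  manifest <- list(seed = cohort$config$seed,
                   noise_sd = cohort$config$noise_sd,
                   n_measurements = nrow(cohort$ground_truth),
                   protocol = unclass(cohort$protocol))
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(cohort$curves)) {
    mdir <- file.path(dir, "measurements")
    dir.create(mdir, showWarnings = FALSE)
    for (i in seq_along(cohort$curves)) {
      id <- names(cohort$curves)[i]
      write_creep_csv(cohort$curves[[i]], file.path(mdir, paste0(id, ".csv")),
                      metadata = list(measurement_id = id,
                                      group = cohort$ground_truth$status[i],
                                      force_N = cohort$protocol$force,
                                      probe_radius_m = cohort$protocol$probe_radius,
                                      poisson = cohort$protocol$poisson))
    }
  }
  invisible(dir)
}
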