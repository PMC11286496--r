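#' Viscoelastic parameter set of the hierarchical tissue model
#'
#' Bundles the six parameters of the double power-law viscoelastic model used
#' throughout the package: the cytoplasm modulus `E1`, the cytoskeleton-fiber
#' modulus `E2`, the whole-network modulus `E3` (all in the cohort's stress
#' unit `U`), the cytoplasm viscosity `eta` (`U*s`), and the two power-law
#' exponents `alphaL` (short times) and `alphaR` (long times).  The relaxation
#' modulus in the Laplace domain is
#' \deqn{\hat G(s) = E_3 + E_2 (s/\omega_0)^{\alpha_R} +
#'                   E_1 (s/\omega_0)^{\alpha_L} + \eta s,}
#' with the reference rate fixed at \eqn{\omega_0 = 1} rad/s so that moduli
#' and exponents are jointly identifiable.
#'
#' @param E1,E2,E3 elastic moduli, `U` (> 0; zero allowed when `strict = FALSE`
#'   to express degenerate single-element limits).
#' @param eta viscosity, `U*s`.
#' @param alphaL,alphaR short- and long-time power-law exponents; must satisfy
#'   `0 < alphaR < alphaL < 1` when `strict = TRUE`.
#' @param strict enforce full-model invariants.  `strict = FALSE` admits
#'   degenerate limits (single spring, dashpot, spring-pot) used for
#'   closed-form validation.
#'
#' @return An object of class `visco_params`.
#' @examples
#' p <- visco_params(E1 = 100, E2 = 200, E3 = 156.1, eta = 50,
#'                   alphaL = 0.85, alphaR = 0.20)
#' derived_markers(p)
#' @export
visco_params <- function(E1, E2, E3, eta, alphaL, alphaR, strict = TRUE) {
  vals <- c(E1 = as.numeric(E1)[1], E2 = as.numeric(E2)[1],
            E3 = as.numeric(E3)[1], eta = as.numeric(eta)[1],
            alphaL = as.numeric(alphaL)[1], alphaR = as.numeric(alphaR)[1])
  E1 <- vals[["E1"]]; E2 <- vals[["E2"]]; E3 <- vals[["E3"]]
  eta <- vals[["eta"]]; alphaL <- vals[["alphaL"]]; alphaR <- vals[["alphaR"]]
  if (any(!is.finite(vals))) {
    stop("all viscoelastic parameters must be finite numbers")
  }
  if (strict) {
    if (any(vals[c("E1", "E2", "E3", "eta")] <= 0)) {
      stop("E1, E2, E3 and eta must be strictly positive")
    }
    if (!(alphaR > 0 && alphaR < alphaL && alphaL < 1)) {
      stop("exponents must satisfy 0 < alphaR < alphaL < 1")
    }
  } else {
    if (any(vals[c("E1", "E2", "E3", "eta")] < 0)) {
      stop("moduli and viscosity cannot be negative")
    }
    if (alphaL < 0 || alphaL > 1 || alphaR < 0 || alphaR > 1) {
      stop("exponents must lie in [0, 1]")
    }
  }
  structure(as.list(vals), strict = strict, class = "visco_params")
}

#' @export
print.visco_params <- function(x, ...) {
  cat("<visco_params>\n")
  cat(sprintf("  E1 = %.4g  E2 = %.4g  E3 = %.4g  (Esum = %.4g)\n",
              x$E1, x$E2, x$E3, x$E1 + x$E2 + x$E3))
  cat(sprintf("  eta = %.4g  alphaL = %.3f  alphaR = %.3f\n",
              x$eta, x$alphaL, x$alphaR))
  invisible(x)
}

#' Relaxation modulus in the Laplace domain
#'
#' Evaluates \eqn{\hat G(s) = E_3 + E_2 s^{\alpha_R} + E_1 s^{\alpha_L} +
#' \eta s} (rates measured against \eqn{\omega_0 = 1} rad/s).  \eqn{\hat G}
#' is strictly increasing in `s` and tends to the network plateau `E3` as
#' `s -> 0`.
#'
#' @param params a [visco_params()] object.
#' @param s positive Laplace rate(s), 1/s.  Vectorised.
#' @return Modulus value(s) in the unit of the moduli.
#' @export
laplace_modulus <- function(params, s) {
  if (any(!is.finite(s)) || any(s <= 0)) {
    stop("Laplace rate s must be strictly positive")
  }
  params$E3 + params$E2 * s^params$alphaR +
    params$E1 * s^params$alphaL + params$eta * s
}

#' Derived viscoelastic markers: Esum, tau and fT
#'
#' Computes the three markers derived from the model parameters: the total
#' modulus `Esum = E1 + E2 + E3`, the relaxation time `tau = eta / E1`
#' (seconds), and the transition frequency `fT` (Hz) at which the two
#' power-law branches of the relaxation modulus are equal,
#' \deqn{f_T = \frac{\omega_0}{2\pi}\left(\frac{E_2}{E_1}\right)^{1/(\alpha_L-\alpha_R)}.}
#' `fT` marks the crossover between fiber-dominated slow dynamics and
#' cytoplasm-dominated fast dynamics.
#'
#' @param params a [visco_params()] object.
#' @return Named list with elements `Esum`, `tau`, `fT`, all positive.
#' @export
derived_markers <- function(params) {
  if (params$alphaL == params$alphaR) {
    stop("degenerate exponents: alphaL must differ from alphaR for fT")
  }
  if (params$E1 <= 0 || params$E2 <= 0) {
    stop("E1 and E2 must be positive to define tau and fT")
  }
  list(
    Esum = params$E1 + params$E2 + params$E3,
    tau  = params$eta / params$E1,
    fT   = (1 / (2 * pi)) *
      (params$E2 / params$E1)^(1 / (params$alphaL - params$alphaR))
  )
}
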