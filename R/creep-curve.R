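#' A single creep record
#'
#' Container for one time series from a creep test: either creep compliance
#' `J(t)` (1/U, or 1/Pa in SI) or indentation depth `delta(t)` (m).
#'
#' @param times sampling times, seconds; strictly increasing, all positive,
#'   at least 8 points.
#' @param values strictly positive compliance or indentation values.
#' @param kind `"compliance"` or `"indentation"`.
#' @return An object of class `creep_curve`.
#' @export
creep_curve <- function(times, values, kind = c("compliance", "indentation")) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have equal length")
  }
  if (length(times) < 8) stop("a creep record needs at least 8 points")
  if (any(!is.finite(times)) || any(times <= 0) || any(diff(times) <= 0)) {
    stop("times must be finite, positive and strictly increasing")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("creep values must be finite and strictly positive")
  }
  structure(list(times = times, values = values, kind = kind),
            class = "creep_curve")
}

#' @export
print.creep_curve <- function(x, ...) {
  cat(sprintf("<creep_curve: %s, %d points, t in [%.3g, %.3g] s>\n",
              x$kind, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Spherical-probe step-stress indentation protocol
#'
#' Describes the AFM creep protocol: a step force applied through a spherical
#' probe and held for `hold_time` seconds while indentation is recorded.
#' Defaults follow a 20 um diameter bead held for 10 s on incompressible
#' tissue, sampled on a logarithmic time grid.
#'
#' @param force step force, N.
#' @param probe_radius probe radius, m (default 10e-6, i.e. 20 um diameter).
#' @param poisson Poisson's ratio (0.5 = incompressible).
#' @param hold_time hold duration, s.
#' @param n_points number of log-spaced samples.
#' @param t_min first sampling time, s.
#' @return An object of class `indentation_protocol`.
#' @export
indentation_protocol <- function(force = 1e-8, probe_radius = 10e-6,
                                 poisson = 0.5, hold_time = 10,
                                 n_points = 60, t_min = 0.02) {
  if (force <= 0) stop("step force must be positive")
  if (probe_radius <= 0) stop("probe radius must be positive")
  if (poisson < 0 || poisson >= 1) stop("Poisson's ratio must lie in [0, 1)")
  if (t_min <= 0 || hold_time <= t_min) {
    stop("need 0 < t_min < hold_time")
  }
  if (n_points < 8) stop("n_points must be at least 8")
  structure(list(force = force, probe_radius = probe_radius,
                 poisson = poisson, hold_time = hold_time,
                 n_points = n_points, t_min = t_min),
            class = "indentation_protocol")
}

#' Log-spaced sampling times of a protocol
#' @param protocol an [indentation_protocol()].
#' @return Numeric vector of times, s.
#' @export
protocol_times <- function(protocol) {
  exp(seq(log(protocol$t_min), log(protocol$hold_time),
          length.out = protocol$n_points))
}

# Gaver-Stehfest weights for an even number of terms.  Exact rational
# arithmetic is unnecessary: factorials up to 14! are exactly representable
# in double precision.
stehfest_weights <- function(n = 14L) {
  if (n %% 2L != 0L) stop("Stehfest term count must be even")
  half <- n %/% 2L
  v <- numeric(n)
  for (k in seq_len(n)) {
    acc <- 0
    for (j in seq(floor((k + 1) / 2), min(k, half))) {
      acc <- acc + j^half * factorial(2 * j) /
        (factorial(half - j) * factorial(j) * factorial(j - 1) *
           factorial(k - j) * factorial(2 * j - k))
    }
    v[k] <- (-1)^(k + half) * acc
  }
  v
}

.stehfest_env <- new.env(parent = emptyenv())

stehfest_weights_cached <- function(n = 14L) {
  key <- as.character(n)
  if (is.null(.stehfest_env[[key]])) {
    .stehfest_env[[key]] <- stehfest_weights(n)
  }
  .stehfest_env[[key]]
}

#' Creep compliance of the hierarchical model
#'
#' Computes `J(t)` by Gaver-Stehfest numerical inversion of the Laplace-domain
#' compliance \eqn{\tilde J(s) = 1 / (s \hat G(s))}, where \eqn{\hat G} is the
#' relaxation modulus of [laplace_modulus()].  The result is positive and
#' non-decreasing, with local log-log slope moving from about `alphaL` (or 1
#' where the dashpot dominates) at short times to about `alphaR` at long
#' times.
#'
#' @param params a [visco_params()] object.
#' @param times evaluation times in seconds, within `[1e-3, 1e3]`.
#' @param n_terms number of Stehfest terms (even; default 14).
#' @return A compliance [creep_curve()].
#' @export
creep_compliance <- function(params, times, n_terms = 14L) {
  if (any(times < 1e-3) || any(times > 1e3)) {
    stop("times must lie within [1e-3, 1e3] s")
  }
  v <- stehfest_weights_cached(n_terms)
  ln2 <- log(2)
  # s[k, i] = k * ln2 / t_i; plain vector arithmetic keeps the evaluation
  # bitwise reproducible
  s <- matrix(seq_len(n_terms) * ln2, n_terms, length(times)) *
    rep(1 / times, each = n_terms)
  g <- params$E3 + params$E2 * s^params$alphaR +
    params$E1 * s^params$alphaL + params$eta * s
  jt <- colSums(v * (1 / (s * g))) * ln2 / times
  if (any(!is.finite(jt)) || any(jt <= 0)) {
    stop("Stehfest inversion produced non-finite or non-positive compliance; ",
         "check parameter magnitudes")
  }
  creep_curve(times, jt, kind = "compliance")
}

#' Convert an indentation record to creep compliance (Hertz contact)
#'
#' For a step force `F` applied through a rigid sphere of radius `R` on an
#' incompressible half-space, the Hertz model gives
#' \deqn{J(t) = \frac{4 \sqrt{R}\, \delta(t)^{3/2}}{3 F (1 - \nu^2)}.}
#' With SI inputs the result is in 1/Pa.
#'
#' @param indentation an indentation [creep_curve()], values in m.
#' @param protocol an [indentation_protocol()] supplying `F`, `R`, `nu`.
#' @return A compliance [creep_curve()].
#' @export
hertz_compliance <- function(indentation, protocol) {
  stopifnot(inherits(indentation, "creep_curve"))
  if (indentation$kind != "indentation") {
    stop("input curve must hold indentation values")
  }
  j <- 4 * sqrt(protocol$probe_radius) * indentation$values^1.5 /
    (3 * protocol$force * (1 - protocol$poisson^2))
  creep_curve(indentation$times, j, kind = "compliance")
}

#' Indentation depth implied by a compliance record (inverse Hertz map)
#'
#' Inverse of [hertz_compliance()]:
#' \eqn{\delta(t) = [3 F (1-\nu^2) J(t) / (4\sqrt{R})]^{2/3}}.  Used by the
#' measurement simulator to turn model compliances into AFM-like indentation
#' records.
#'
#' @inheritParams hertz_compliance
#' @param compliance a compliance [creep_curve()].
#' @return An indentation [creep_curve()], values in m for SI inputs.
#' @export
hertz_indentation <- function(compliance, protocol) {
  stopifnot(inherits(compliance, "creep_curve"))
  if (compliance$kind != "compliance") {
    stop("input curve must hold compliance values")
  }
  d <- (3 * protocol$force * (1 - protocol$poisson^2) * compliance$values /
          (4 * sqrt(protocol$probe_radius)))^(2 / 3)
  creep_curve(compliance$times, d, kind = "indentation")
}

#' Local log-log slope of a creep record
#'
#' Centered sliding linear regression of `log(value)` on `log(time)`; the
#' output has the same length as the input, with truncated windows at the
#' edges so the short-time exponent can be read near `t_min`.
#'
#' @param curve a [creep_curve()].
#' @param window odd window size, at least 3 points.
#' @return Numeric vector of local slopes (dimensionless).
#' @export
local_loglog_slope <- function(curve, window = 7L) {
  stopifnot(inherits(curve, "creep_curve"))
  if (window < 3L || window %% 2L == 0L) {
    stop("window must be an odd count of at least 3 points")
  }
  lt <- log(curve$times)
  lv <- log(curve$values)
  n <- length(lt)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - h):min(n, i + h)
    x <- lt[idx] - mean(lt[idx])
    y <- lv[idx] - mean(lv[idx])
    sum(x * y) / sum(x * x)
  }, numeric(1))
}

#' Write / read a creep record as CSV
#'
#' Plain-text interchange format: a header comment block of `#`-prefixed
#' `key=value` metadata lines, then `time_s,value` rows.
#'
#' @param curve a [creep_curve()].
#' @param path file path.
#' @param metadata named list written as `# key=value` header lines.
#' @return `write_creep_csv()` returns `path` invisibly; `read_creep_csv()`
#'   returns the [creep_curve()] with a `metadata` attribute.
#' @export
write_creep_csv <- function(curve, path, metadata = list()) {
  meta <- c(list(value_kind = curve$kind), metadata)
  hdr <- sprintf("# %s=%s", names(meta), vapply(meta, format, character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "time_s,value"), con)
  utils::write.table(data.frame(curve$times, curve$values), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_creep_csv
#' @export
read_creep_csv <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  body <- utils::read.csv(text = lines[!is_meta])
  kind <- if (identical(meta$value_kind, "indentation")) "indentation" else "compliance"
  curve <- creep_curve(body$time_s, body$value, kind = kind)
  attr(curve, "metadata") <- meta
  curve
}
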