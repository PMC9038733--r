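#' Wrap an angular difference onto the 180-degree orientation circle
#'
#' Orientations are 180-degree periodic (a bar at 10 degrees is the same bar
#' at 190 degrees), so a report error is only defined up to multiples of 180.
#' `wrap180()` maps any real difference onto its unique representative in
#' `(-90, 90]`.
#'
#' @param delta Numeric vector of angular differences in degrees.
#' @return Numeric vector with each element in `(-90, 90]`, congruent to
#'   `delta` modulo 180.
#' @examples
#' wrap180(178)   # -2
#' wrap180(-90)   # 90 (half-open boundary convention)
#' @export
wrap180 <- function(delta) {
  if (!is.numeric(delta)) stop("`delta` must be numeric.", call. = FALSE)
  if (any(!is.finite(delta))) stop("`delta` must be finite.", call. = FALSE)
  90 - ((90 - delta) %% 180)
}

#' Signed report error on the orientation circle
#'
#' The error of a single trial is the reported orientation minus the true
#' target orientation, wrapped to `(-90, 90]` so that zero means a perfect
#' report.
#'
#' @param response,target Numeric vectors of orientations in degrees.
#' @return Numeric vector of signed errors in degrees, in `(-90, 90]`.
#' @examples
#' signed_error(10, 170)  # 20: wraps across the 180-degree boundary
#' @export
signed_error <- function(response, target) {
  wrap180(response - target)
}

#' Convert between orientation-space SD and von Mises concentration
#'
#' The orientation circle (period 180 degrees) is mapped to the standard
#' circle by angle doubling, `x -> 2x`.  A von Mises distribution with
#' concentration `kappa` on the doubled circle has circular standard
#' deviation `sqrt(-2 * log(I1(kappa) / I0(kappa)))` radians; `sigma` is that
#' SD expressed back in orientation degrees, i.e. the doubled-space circular
#' SD equals `2 * sigma` degrees.  `sd_to_kappa()` inverts the relation
#' numerically (monotone root find, residual below 1e-8 degrees);
#' `kappa_to_sd()` is the closed forward form.
#'
#' @param sigma Numeric vector of SDs in degrees, each in `(0, 90]`.
#' @param kappa Numeric vector of non-negative concentrations.
#' @return `sd_to_kappa()`: concentrations; `kappa_to_sd()`: SDs in degrees.
#' @examples
#' kappa_to_sd(sd_to_kappa(8))  # 8
#' @export
sd_to_kappa <- function(sigma) {
  if (!is.numeric(sigma) || any(!is.finite(sigma))) {
    stop("`sigma` must be finite numeric.", call. = FALSE)
  }
  if (any(sigma <= 0 | sigma > 90)) {
    stop("`sigma` must lie in (0, 90].", call. = FALSE)
  }
  vapply(sigma, function(s) {
    stats::uniroot(
      function(k) kappa_to_sd(k) - s,
      lower = 1e-12, upper = 1e5, tol = 1e-12
    )$root
  }, numeric(1))
}

#' @rdname sd_to_kappa
#' @export
kappa_to_sd <- function(kappa) {
  if (any(kappa < 0)) stop("`kappa` must be non-negative.", call. = FALSE)
  r <- ifelse(
    kappa > 5e4,
    # asymptotic mean resultant length; scaled besselI underflows up here
    1 - 1 / (2 * kappa) - 1 / (8 * kappa^2),
    besselI(kappa, 1, expon.scaled = TRUE) /
      besselI(kappa, 0, expon.scaled = TRUE)
  )
  (180 / pi) * sqrt(-2 * log(r)) / 2
}

# log I0(kappa) without overflow
log_bessel_i0 <- function(kappa) {
  log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
}

# von Mises log-density per degree on the 180-degree orientation circle,
# parameterized directly by the doubled-space concentration kappa.
vm_lpdf_kappa <- function(x, kappa) {
  kappa * cos(x * pi / 90) - log_bessel_i0(kappa) - log(180)
}

#' Von Mises density on the 180-degree orientation circle
#'
#' Density (per degree) of report errors around zero, obtained by angle
#' doubling: `f(x) = exp(kappa * cos(2 * x * pi / 180)) / (180 * I0(kappa))`
#' with `kappa = sd_to_kappa(sigma)`.  Integrates to 1 over any 180-degree
#' window.
#'
#' @param x Numeric vector of errors in degrees.
#' @param sigma Scalar SD in degrees, in `(0, 90]`.
#' @return Numeric vector of densities (per degree).
#' @export
vm_pdf_180 <- function(x, sigma) {
  if (length(sigma) != 1L) stop("`sigma` must be a scalar.", call. = FALSE)
  exp(vm_lpdf_kappa(x, sd_to_kappa(sigma)))
}

#' Draw von Mises orientation noise
#'
#' Samples from the angle-doubled von Mises on the 180-degree circle with
#' mean `mu` and SD `sigma`, via the Best-Fisher (1979) rejection sampler on
#' the doubled circle.  Uses the current RNG state.
#'
#' @param n Number of draws.
#' @param mu Mean orientation in degrees.
#' @param sigma SD in degrees, in `(0, 90]`.
#' @return Orientations in degrees in `(0, 180]`.
#' @export
rvm180 <- function(n, mu = 0, sigma = 8) {
  kappa <- sd_to_kappa(sigma)
  theta2 <- rvm_rad(n, kappa)            # doubled angle in (-pi, pi]
  ori <- mu + theta2 * (90 / pi)         # halve back to orientation degrees
  wrap_0_180(ori)
}

# map any orientation to the canonical stimulus space (0, 180]
wrap_0_180 <- function(x) {
  180 - ((-x) %% 180)
}

# Best-Fisher sampler for von Mises(0, kappa) in radians on the full circle
rvm_rad <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmax(pmin(f[ok], 1), -1)))
  }
  out[seq_len(n)]
}

#' Descriptive statistics of wrapped report errors
#'
#' `mean_error()` is by default the arithmetic mean of the wrapped errors —
#' the conventional bias summary when errors are concentrated near zero; a
#' circular variant (doubled-angle circular mean, halved back) is available.
#' `precision()` is the inverse spread of the errors, by default `1 / SD`
#' (sample SD of the wrapped errors); `type = "variance"` gives
#' `1 / variance`.
#'
#' @param errors Numeric vector of signed errors in degrees.
#' @param type For `mean_error()`: `"linear"` (default) or `"circular"`.
#'   For `precision()`: `"sd"` (default) or `"variance"`.
#' @return A scalar: degrees for `mean_error()`, 1/degrees (or 1/degrees^2)
#'   for `precision()`.
#' @export
mean_error <- function(errors, type = c("linear", "circular")) {
  type <- match.arg(type)
  if (length(errors) == 0L) stop("`errors` must be non-empty.", call. = FALSE)
  e <- wrap180(errors)
  if (type == "linear") return(mean(e))
  # circular: double, take mean resultant direction, halve back
  a <- e * pi / 90
  wrap180(atan2(mean(sin(a)), mean(cos(a))) * 90 / pi)
}

#' @rdname mean_error
#' @export
precision <- function(errors, type = c("sd", "variance")) {
  type <- match.arg(type)
  if (length(errors) < 2L) stop("need at least 2 errors.", call. = FALSE)
  e <- wrap180(errors)
  s <- stats::sd(e)
  if (s == 0) stop("errors have zero variance.", call. = FALSE)
  if (type == "sd") 1 / s else 1 / s^2
}

`%||%` <- function(x, y) if (is.null(x)) y else x
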