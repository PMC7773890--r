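#' Circular helpers for orientation and location features
#'
#' Orientation is 180-degree periodic; all von Mises computations double the
#' angle onto the full circle first. Location indices are mapped to angles on
#' the 360-degree circle. These helpers are internal but exported because the
#' test suite and downstream analyses use them directly.
#'
#' @name circular-helpers
NULL

#' Wrap signed degrees onto a half-open interval centred on zero
#'
#' @param x numeric vector of angles in degrees.
#' @param period circle period in degrees (180 for orientation, 360 for
#'   location).
#' @return angles wrapped into `(-period/2, +period/2]`.
#' @export
wrap_signed <- function(x, period = 180) {
  half <- period / 2
  w <- ((x + half) %% period) - half
  # map the -half boundary onto +half so the interval is half-open on the left
  w[w <= -half] <- w[w <= -half] + period
  w
}

#' Signed circular difference a - b on a circle of the given period
#' @param a,b angles in degrees.
#' @param period circle period in degrees.
#' @return signed difference in `(-period/2, +period/2]`.
#' @export
circ_diff <- function(a, b, period = 180) {
  wrap_signed(a - b, period = period)
}

deg2rad <- function(x) x * pi / 180

#' von Mises log-density on the doubled orientation circle
#'
#' Errors `e` are signed orientation degrees in (-90, 90]; they are doubled
#' and converted to radians before evaluation, so the concentration `kappa`
#' is expressed on the doubled circle (matching how mixture-model
#' concentrations are conventionally reported for orientation data).
#'
#' @param e signed orientation errors in degrees.
#' @param kappa von Mises concentration (rad^-1, doubled circle).
#' @return log-density values (density with respect to the doubled-circle
#'   angle in radians, so the uniform density is 1/(2*pi)).
#' @export
dvm_orientation_log <- function(e, kappa) {
  theta <- deg2rad(2 * e)
  kappa * cos(theta) - log(2 * pi) - log_bessel_i0(kappa)
}

# log I0(kappa), stable for large kappa via the exponentially scaled Bessel
log_bessel_i0 <- function(kappa) {
  log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
}

#' Inverse of the first moment ratio A1 of the von Mises distribution
#'
#' Given a mean resultant length `r`, returns the concentration `kappa` such
#' that `A1(kappa) = I1(kappa)/I0(kappa) = r`, using the standard piecewise
#' approximation (Fisher 1993). Used by the EM concentration update.
#'
#' @param r mean resultant length in `[0, 1)`.
#' @return approximate concentration (nonnegative).
#' @export
a1inv <- function(r) {
  r <- pmin(pmax(r, 0), 1 - 1e-12)
  ifelse(r < 0.53,
         2 * r + r^3 + 5 * r^5 / 6,
         ifelse(r < 0.85,
                -0.4 + 1.39 * r + 0.43 / (1 - r),
                1 / (r^3 - 4 * r^2 + 3 * r)))
}

#' Draw from a von Mises distribution (Best-Fisher rejection sampler)
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration; `kappa = 0` gives the uniform distribution.
#' @return angles in radians in `(-pi, pi]` relative to 0, shifted by `mu`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) {
    return(wrap_signed((mu + stats::runif(n, -pi, pi)) * 180 / pi, 360) * pi / 180)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rr <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    vals <- sign(u3[ok] - 0.5) * acos(f[ok])
    take <- min(length(vals), n - got)
    if (take > 0) out[(got + 1):(got + take)] <- vals[seq_len(take)]
    got <- got + take
  }
  wrap_signed((mu + out) * 180 / pi, 360) * pi / 180
}
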