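#' Fit an exponentiated cosine to a channel tuning function
#'
#' Fits `f(x) = alpha * exp(kappa * (cos(mu - x) - 1)) + beta` with the
#' center `mu` fixed at 0, by combining ordinary least squares with a grid
#' search: for each concentration `kappa` on the grid 1..30 in steps of 0.1
#' (291 values, both endpoints included), the unit response (`alpha = 1`,
#' `beta = 0`) and a constant term form the design matrix, `alpha` and
#' `beta` are estimated by OLS, and the `(kappa, alpha, beta)` triple with
#' the smallest residual sum of squares is returned. Ties on the SSE are
#' broken toward the smallest `kappa`. `alpha` is unconstrained: a negative
#' amplitude is meaningful for the one-tailed bootstrap tests.
#'
#' The CTF offsets (degrees on a circle of the given period) are mapped
#' uniformly onto the full circle before the cosine is evaluated, so a
#' 180-degree orientation circle and a 360-degree location circle are both
#' fitted over a full period.
#'
#' @param ctf a `ctf` object from [reconstruct_ctf()], or a numeric vector
#'   of 180 values (then assumed to span a full period uniformly).
#' @param kappa_grid concentration grid (default `seq(1, 30, by = 0.1)`).
#' @return an object of class `ctf_fit`: `alpha`, `beta`, `kappa`,
#'   `mu` (always 0), `sse`, plus the data and fitted values.
#' @export
#' @examples
#' x <- seq(-90, 89)                     # orientation offsets
#' y <- 2 * exp(5 * (cos(2 * pi * x / 180) - 1)) + 0.5
#' fit_exp_cosine(y)                     # recovers alpha 2, beta 0.5, kappa 5
fit_exp_cosine <- function(ctf, kappa_grid = seq(1, 30, by = 0.1)) {
  if (inherits(ctf, "ctf")) {
    y <- ctf$values
    x_rad <- 2 * pi * ctf$offsets / ctf$period
  } else {
    y <- as.numeric(ctf)
    n <- length(y)
    x_rad <- 2 * pi * (seq_len(n) - 1 - floor(n / 2)) / n
  }
  if (any(!is.finite(y))) stop("CTF values must all be finite")
  n <- length(y)

  # unit responses for every kappa on the grid: n x G matrix
  U <- exp(outer(cos(x_rad) - 1, kappa_grid))
  # closed-form 2-parameter OLS per grid point
  su <- colSums(U)          # sum of predictor
  suu <- colSums(U^2)       # predictor sum of squares
  suy <- colSums(U * y)     # cross product
  sy <- sum(y)
  det <- suu * n - su^2
  alpha <- (n * suy - su * sy) / det
  beta <- (suu * sy - su * suy) / det
  sse <- sum(y^2) - 2 * (alpha * suy + beta * sy) +
    alpha^2 * suu + 2 * alpha * beta * su + beta^2 * n
  best <- which.min(sse)    # which.min takes the first (smallest kappa) tie
  fitted <- alpha[best] * U[, best] + beta[best]
  structure(list(alpha = alpha[best], beta = beta[best],
                 kappa = kappa_grid[best], mu = 0,
                 sse = sse[best], kappa_grid = range(kappa_grid),
                 x_rad = x_rad, y = y, fitted = fitted),
            class = "ctf_fit")
}

#' Amplitude of a fitted channel tuning function
#'
#' Returns `alpha`, the height of the tuning function above its baseline.
#' The sign is preserved: inverted reconstructions yield negative
#' amplitudes, which the bootstrap tests count toward the null tail.
#'
#' @param fit a `ctf_fit`.
#' @return the amplitude (a single number).
#' @export
amplitude <- function(fit) {
  stopifnot(inherits(fit, "ctf_fit"))
  fit$alpha
}

#' @export
print.ctf_fit <- function(x, ...) {
  cat(sprintf(
    "exponentiated-cosine CTF fit: alpha = %.4f, beta = %.4f, kappa = %.1f (mu fixed at 0), SSE = %.4g\n",
    x$alpha, x$beta, x$kappa, x$sse))
  invisible(x)
}

#' @export
coef.ctf_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta, kappa = object$kappa,
    mu = object$mu)
}

#' @export
predict.ctf_fit <- function(object, x_rad = NULL, ...) {
  if (is.null(x_rad)) x_rad <- object$x_rad
  object$alpha * exp(object$kappa * (cos(x_rad) - 1)) + object$beta
}

#' @export
residuals.ctf_fit <- function(object, ...) {
  object$y - object$fitted
}

#' @export
plot.ctf_fit <- function(x, ...) {
  deg <- x$x_rad * 180 / pi
  graphics::plot(deg, x$y, pch = 16, cex = 0.5,
                 xlab = "offset (deg, full circle)",
                 ylab = "channel response", ...)
  graphics::lines(deg, x$fitted, col = 2)
  invisible(x)
}
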