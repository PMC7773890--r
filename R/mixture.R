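#' Log-likelihood of the mixture model of continuous-report error
#'
#' The error distribution is a mixture of (i) target responses: von Mises
#' centred on the target with concentration `kappa` on the doubled-angle
#' circle, weight `pT`; (ii) swap responses: an equal-weight average of von
#' Mises components centred on each non-target offset, total weight `pN`;
#' and (iii) uniform guesses, weight `pU`. Orientation angles are doubled
#' before evaluation so that densities live on the full 360-degree circle;
#' the uniform density is `1/(2*pi)`.
#'
#' @param errors signed response errors in degrees, in `(-90, +90]`.
#' @param offsets trials x m matrix of signed non-target offsets (degrees),
#'   or NULL/empty for the two-factor model. NA entries are ignored.
#' @param pT,pN,pU mixture proportions (must lie on the simplex).
#' @param kappa von Mises concentration (rad^-1, doubled circle).
#' @return the summed log-likelihood (a single number).
#' @export
mixture_loglik <- function(errors, offsets, pT, pN, pU, kappa) {
  if (min(pT, pN, pU) < -1e-12 || abs(pT + pN + pU - 1) > 1e-6) {
    stop("(pT, pN, pU) must be nonnegative and sum to 1")
  }
  if (pN > 0 && (is.null(offsets) || length(offsets) == 0)) {
    stop("pN > 0 requires non-target offsets")
  }
  dens <- pT * vm_density(errors, kappa) + pU / (2 * pi)
  if (!is.null(offsets) && length(offsets) > 0 && pN > 0) {
    offsets <- as.matrix(offsets)
    swap <- rowMeans(vm_density(errors - offsets, kappa), na.rm = TRUE)
    swap[is.nan(swap)] <- 0  # trials with no recorded non-target
    dens <- dens + pN * swap
  }
  sum(log(dens))
}

# von Mises density of orientation deviations (degrees), doubled circle,
# computed with the exponentially scaled Bessel for stability at large kappa
vm_density <- function(dev_deg, kappa) {
  theta <- deg2rad(2 * dev_deg)
  exp(kappa * (cos(theta) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Fit the two- or three-factor mixture model by expectation-maximization
#'
#' Maximum-likelihood estimates of the mixture proportions and of the von
#' Mises concentration are obtained by EM over component responsibilities,
#' with the concentration updated each iteration by inverting the weighted
#' mean resultant length (A1-inverse approximation). The best of
#' `n_starts` random initializations is kept. The two-factor model fixes
#' `pN = 0`, so the estimated proportions satisfy `pU + pT = 1`; the
#' three-factor model adds the swap component and requires non-target
#' offsets. Trials with missing responses should be excluded beforehand;
#' NA errors are dropped with a warning.
#'
#' @param responses a `response_table` from [simulate_behavior()], or any
#'   data.frame with columns `error` and (for three factors) `offset_1`,
#'   `offset_2`.
#' @param n_factors 2 or 3.
#' @param n_starts random initializations (default 10).
#' @param seed integer seed for the initializations.
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter EM iteration cap (default 500).
#' @param kappa_floor,kappa_cap bounds on the concentration estimate.
#' @return an object of class `mixture_fit`: estimates `pT`, `pN`, `pU`,
#'   `kappa`, the maximized `loglik`, `n_trials`, a `converged` flag,
#'   `n_factors`, and the per-iteration log-likelihood trace of the winning
#'   start (`loglik_trace`).
#' @export
#' @examples
#' sched <- make_schedule(6, 6, 1, 2, "1O", seed = 2)
#' resp <- simulate_behavior(sched, group_profile(pT = 0.9, pN = 0,
#'                                                kappa_mix = 8), seed = 3)
#' fit <- fit_mixture(resp, n_factors = 2, seed = 4)
#' coef(fit)
fit_mixture <- function(responses, n_factors = 3, n_starts = 10, seed = 1L,
                        tol = 1e-6, max_iter = 500,
                        kappa_floor = 0.05, kappa_cap = 200) {
  stopifnot(n_factors %in% c(2, 3))
  errors <- responses$error
  if (anyNA(errors)) {
    warning("dropping ", sum(is.na(errors)), " trials with missing responses")
    keep <- !is.na(errors)
    responses <- responses[keep, , drop = FALSE]
    errors <- responses$error
  }
  offsets <- NULL
  if (n_factors == 3) {
    offsets <- nontarget_offsets(responses)
    if (all(is.na(offsets))) {
      stop("three-factor model requires non-target offsets")
    }
  }
  n <- length(errors)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- random_simplex_init(n_factors)
    kappa0 <- stats::runif(1, 0.5, 30)
    fit <- em_mixture(errors, offsets, init, kappa0, n_factors,
                      tol, max_iter, kappa_floor, kappa_cap)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(c(best,
              list(n_trials = n, n_factors = n_factors,
                   n_starts = n_starts, seed = seed)),
            class = "mixture_fit")
}

random_simplex_init <- function(n_factors) {
  if (n_factors == 2) {
    pT <- stats::runif(1, 0.3, 0.95)
    c(pT = pT, pN = 0, pU = 1 - pT)
  } else {
    u <- c(stats::runif(1, 0.4, 1), stats::runif(2, 0.02, 0.4))
    u <- u / sum(u)
    c(pT = u[1], pN = u[2], pU = u[3])
  }
}

em_mixture <- function(errors, offsets, p0, kappa0, n_factors,
                       tol, max_iter, kappa_floor, kappa_cap) {
  n <- length(errors)
  pT <- p0[["pT"]]; pN <- p0[["pN"]]; pU <- p0[["pU"]]
  kappa <- kappa0
  has_swap <- n_factors == 3
  if (has_swap) {
    offsets <- as.matrix(offsets)
    m_i <- rowSums(!is.na(offsets))          # non-targets per trial
    dev <- errors - offsets                  # trials x m deviations
  }
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dT <- pT * vm_density(errors, kappa)
    dU <- rep(pU / (2 * pi), n)
    if (has_swap) {
      dNj <- vm_density(dev, kappa) * (pN / m_i)  # per non-target component
      dNj[is.na(dNj)] <- 0
      dN <- rowSums(dNj)
    } else {
      dN <- 0
    }
    tot <- dT + dN + dU
    ll <- sum(log(tot))
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll

    rT <- dT / tot
    rU <- dU / tot
    pT <- mean(rT); pU <- mean(rU)
    if (has_swap) {
      rN <- dNj / tot
      pN <- sum(rN) / n
    } else {
      pN <- 0
    }
    # renormalize against accumulated rounding
    ssum <- pT + pN + pU
    pT <- pT / ssum; pN <- pN / ssum; pU <- pU / ssum
    # concentration update: weighted mean resultant of all von Mises parts
    w_cos <- sum(rT * cos(deg2rad(2 * errors)))
    w_tot <- sum(rT)
    if (has_swap) {
      cterm <- rN * cos(deg2rad(2 * dev))
      w_cos <- w_cos + sum(cterm[!is.na(cterm)])
      w_tot <- w_tot + sum(rN)
    }
    rbar <- if (w_tot > 0) w_cos / w_tot else 0
    kappa <- min(max(a1inv(max(rbar, 0)), kappa_floor), kappa_cap)
  }
  list(pT = pT, pN = pN, pU = pU, kappa = kappa,
       loglik = trace[length(trace)], converged = converged,
       loglik_trace = trace)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("%d-factor von Mises mixture fit (%d trials)\n",
              x$n_factors, x$n_trials))
  cat(sprintf("  pT = %.3f  pN = %.3f  pU = %.3f  kappa = %.2f rad^-1\n",
              x$pT, x$pN, x$pU, x$kappa))
  cat(sprintf("  log-likelihood %.3f  (%s, %d starts)\n", x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_starts))
  invisible(x)
}

#' @export
coef.mixture_fit <- function(object, ...) {
  c(pT = object$pT, pN = object$pN, pU = object$pU, kappa = object$kappa)
}

#' @export
logLik.mixture_fit <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- if (object$n_factors == 2) 2 else 3
  attr(val, "nobs") <- object$n_trials
  class(val) <- "logLik"
  val
}

#' @export
summary.mixture_fit <- function(object, ...) {
  out <- c(coef(object),
           loglik = object$loglik, n_trials = object$n_trials,
           converged = as.numeric(object$converged))
  class(out) <- "summary.mixture_fit"
  out
}

#' @export
print.summary.mixture_fit <- function(x, ...) {
  print(unclass(x)); invisible(x)
}

#' Classify subjects into swap-error groups
#'
#' Two grouping modes are supported. `extreme_thresholds` reproduces an
#' extreme-groups screening design: subjects with swap rates below 0.05 are
#' labelled `"low"`, above 0.12 `"high"`, and the rest `"unclassified"`.
#' `median_split` assigns values at or below the sample median to `"low"`
#' and the rest to `"high"`; a degenerate split (one group empty) is
#' flagged with a warning.
#'
#' @param pN_values per-subject swap-error rates in `[0, 1]`.
#' @param mode `"extreme_thresholds"` or `"median_split"`.
#' @return character vector of labels with attribute `degenerate` for
#'   median splits.
#' @export
classify_groups <- function(pN_values,
                            mode = c("extreme_thresholds", "median_split")) {
  mode <- match.arg(mode)
  if (length(pN_values) == 0) stop("pN_values must be nonempty")
  if (any(pN_values < 0 | pN_values > 1)) {
    stop("pN values must lie in [0, 1]")
  }
  if (mode == "extreme_thresholds") {
    labels <- rep("unclassified", length(pN_values))
    labels[pN_values < 0.05] <- "low"
    labels[pN_values > 0.12] <- "high"
    return(labels)
  }
  med <- stats::median(pN_values)
  labels <- ifelse(pN_values <= med, "low", "high")
  degenerate <- length(unique(labels)) < 2
  if (degenerate) warning("degenerate median split: one group is empty")
  structure(labels, degenerate = degenerate)
}
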