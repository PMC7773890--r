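#' Bootstrap inference for channel-tuning-function amplitudes
#'
#' Subject-level CTFs are resampled with replacement, averaged, and the
#' average refitted with the exponentiated cosine on each iteration. The
#' one-tailed p-value is the proportion of iterations whose fitted
#' amplitude is less than or equal to 0 (ties count toward the tail).
#' Subject CTFs are put into a canonical (lexicographic) order before
#' resampling so the result is invariant to the order in which subjects
#' are supplied.
#'
#' @param ctfs per-subject CTFs: a subjects x points matrix, or a list of
#'   `ctf` objects / numeric vectors.
#' @param n_iters bootstrap iterations (default 2500).
#' @param seed integer seed.
#' @return an object of class `bootstrap_result`: per-iteration `values`
#'   (amplitudes), `p`, `n_iters`, `seed`, `statistic`.
#' @export
bootstrap_amplitude_p <- function(ctfs, n_iters = 2500, seed = 1L) {
  M <- ctf_matrix(ctfs)
  if (nrow(M) < 2) stop("bootstrap requires at least 2 subjects")
  M <- canonical_order(M)
  set.seed(seed)
  vals <- vapply(seq_len(n_iters), function(i) {
    idx <- sample.int(nrow(M), replace = TRUE)
    amplitude(fit_exp_cosine(colMeans(M[idx, , drop = FALSE])))
  }, numeric(1))
  new_bootstrap_result(vals, p = mean(vals <= 0), n_iters = n_iters,
                       seed = seed, statistic = "amplitude")
}

#' Bootstrap test of a group difference in CTF amplitude
#'
#' Each group is resampled independently with replacement; group-average
#' CTFs are fitted and the difference (first group minus second group) of
#' amplitudes recorded. The one-tailed p-value is the proportion of
#' iterations with a difference less than or equal to 0 — i.e. the test of
#' whether the first (conventionally low swap-error) group exceeds the
#' second.
#'
#' @param ctfs_low,ctfs_high per-subject CTFs for the two groups (matrix or
#'   list, as in [bootstrap_amplitude_p()]).
#' @inheritParams bootstrap_amplitude_p
#' @return a `bootstrap_result` whose `values` are the per-iteration
#'   amplitude differences.
#' @export
bootstrap_group_difference <- function(ctfs_low, ctfs_high,
                                       n_iters = 2500, seed = 1L) {
  A <- canonical_order(ctf_matrix(ctfs_low))
  B <- canonical_order(ctf_matrix(ctfs_high))
  if (nrow(A) < 2 || nrow(B) < 2) stop("each group needs >= 2 subjects")
  set.seed(seed)
  vals <- vapply(seq_len(n_iters), function(i) {
    ia <- sample.int(nrow(A), replace = TRUE)
    ib <- sample.int(nrow(B), replace = TRUE)
    amplitude(fit_exp_cosine(colMeans(A[ia, , drop = FALSE]))) -
      amplitude(fit_exp_cosine(colMeans(B[ib, , drop = FALSE])))
  }, numeric(1))
  new_bootstrap_result(vals, p = mean(vals <= 0), n_iters = n_iters,
                       seed = seed, statistic = "amplitude difference (low - high)")
}

#' Bootstrap test of a group difference in recall specificity
#'
#' Like [bootstrap_group_difference()], but the per-group statistic on each
#' iteration is the recall specificity of the resampled group: the
#' amplitude of the group-average probed CTF minus the amplitude of the
#' group-average non-probed CTF.
#'
#' @param low,high per-group lists with elements `probed` and `nonprobed`,
#'   each a subjects x points CTF matrix (aligned by subject).
#' @inheritParams bootstrap_amplitude_p
#' @return a `bootstrap_result` whose `values` are per-iteration
#'   specificity differences (low - high).
#' @export
bootstrap_specificity_difference <- function(low, high,
                                             n_iters = 2500, seed = 1L) {
  spec_stat <- function(pair, idx) {
    amplitude(fit_exp_cosine(colMeans(pair$probed[idx, , drop = FALSE]))) -
      amplitude(fit_exp_cosine(colMeans(pair$nonprobed[idx, , drop = FALSE])))
  }
  low <- canonical_pair(low); high <- canonical_pair(high)
  if (nrow(low$probed) < 2 || nrow(high$probed) < 2) {
    stop("each group needs >= 2 subjects")
  }
  set.seed(seed)
  vals <- vapply(seq_len(n_iters), function(i) {
    ia <- sample.int(nrow(low$probed), replace = TRUE)
    ib <- sample.int(nrow(high$probed), replace = TRUE)
    spec_stat(low, ia) - spec_stat(high, ib)
  }, numeric(1))
  new_bootstrap_result(vals, p = mean(vals <= 0), n_iters = n_iters,
                       seed = seed,
                       statistic = "specificity difference (low - high)")
}

new_bootstrap_result <- function(values, p, n_iters, seed, statistic) {
  structure(list(values = values, p = p, n_iters = n_iters, seed = seed,
                 statistic = statistic),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap (%d iterations, seed %d): %s\n", x$n_iters,
              x$seed, x$statistic))
  cat(sprintf("  mean statistic %.4f, one-tailed p = %.4f\n",
              mean(x$values), x$p))
  invisible(x)
}

# coerce CTF inputs to a subjects x points matrix
ctf_matrix <- function(ctfs) {
  if (is.matrix(ctfs)) return(ctfs)
  if (inherits(ctfs, "ctf")) ctfs <- list(ctfs)
  rows <- lapply(ctfs, function(x) if (inherits(x, "ctf")) x$values else
    as.numeric(x))
  do.call(rbind, rows)
}

canonical_order <- function(M) {
  M[do.call(order, as.data.frame(M)), , drop = FALSE]
}

canonical_pair <- function(pair) {
  p <- ctf_matrix(pair$probed); np <- ctf_matrix(pair$nonprobed)
  ord <- do.call(order, as.data.frame(cbind(p, np)))
  list(probed = p[ord, , drop = FALSE], nonprobed = np[ord, , drop = FALSE])
}

#' Per-subject recall specificity scores
#'
#' The specificity of recall is the amplitude of the probed item's
#' reconstruction minus the amplitude of a non-probed item's
#' reconstruction, both at the recall epoch. The non-probed reconstruction
#' is built upstream by recentering each trial on one randomly selected
#' non-probed item (see [select_nonprobed()] and the `test_selection`
#' argument of [reconstruct_ctf()]); this function fits and differences
#' the per-subject CTF pairs.
#'
#' @param probed_ctfs,nonprobed_ctfs per-subject CTFs (matrix or list,
#'   aligned by subject).
#' @param feature label stored with the scores (`"orientation"` or
#'   `"location"`).
#' @return a `data.frame` with `subject`, `probed_amp`, `nonprobed_amp`,
#'   `difference` (probed minus non-probed, exactly).
#' @export
recall_specificity <- function(probed_ctfs, nonprobed_ctfs,
                               feature = "orientation") {
  P <- ctf_matrix(probed_ctfs); N <- ctf_matrix(nonprobed_ctfs)
  if (nrow(P) != nrow(N)) stop("probed and non-probed CTFs must align")
  pa <- apply(P, 1, function(v) amplitude(fit_exp_cosine(v)))
  na <- apply(N, 1, function(v) amplitude(fit_exp_cosine(v)))
  out <- data.frame(subject = seq_len(nrow(P)), probed_amp = pa,
                    nonprobed_amp = na, difference = pa - na)
  attr(out, "feature") <- feature
  out
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment of a vector of p-values, with rejection flags at the
#' given level.
#'
#' @param p_values raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `p_adjusted` (monotone in the raw p-values) and
#'   `reject` (logical).
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1 | !is.finite(p_values))) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, reject = adj <= q)
}

#' Within-subject (repeated-measures) correlation
#'
#' The ANCOVA-style correlation of two variables measured in every subject
#' under multiple conditions: both variables are centred within subject,
#' removing between-subject differences, and the common-slope association
#' is summarized by `r` from the within-subject sums of products. The
#' p-value comes from the F test on the common slope with
#' `sum(k_i) - n_subjects - 1` error degrees of freedom (equal to
#' `N*(k-1) - 1` in a balanced design with `k` conditions).
#'
#' @param x,y numeric vectors, one entry per subject x condition.
#' @param subject subject identifier of the same length.
#' @return list with `r`, `df`, `p`, `n_subjects`.
#' @export
within_subject_correlation <- function(x, y, subject) {
  stopifnot(length(x) == length(y), length(x) == length(subject))
  subject <- as.factor(subject)
  counts <- table(subject)
  if (any(counts < 2)) {
    warning("excluding ", sum(counts < 2),
            " subject(s) with fewer than 2 conditions")
    keep <- subject %in% names(counts)[counts >= 2]
    x <- x[keep]; y <- y[keep]; subject <- droplevels(subject[keep])
  }
  if (nlevels(subject) < 3) stop("need at least 3 subjects")
  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
  if (sxx == 0 || syy == 0) stop("a variable is constant within subjects")
  r <- sxy / sqrt(sxx * syy)
  df <- length(x) - nlevels(subject) - 1
  Fstat <- r^2 / (1 - r^2) * df
  p <- stats::pf(Fstat, 1, df, lower.tail = FALSE)
  list(r = r, df = df, p = p, n_subjects = nlevels(subject))
}

#' Squared rank or product-moment correlation
#'
#' Thin wrapper around [stats::cor.test()] that reports the coefficient of
#' determination (squared correlation), as group-level brain-behavior
#' correlations are conventionally reported.
#'
#' @param x,y numeric vectors of equal length (>= 4).
#' @param method `"spearman"` or `"pearson"`.
#' @return list with `r`, `R2`, `p`, `method`.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 4) {
    stop("x and y must have equal length >= 4")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  r <- unname(ct$estimate)
  list(r = r, R2 = r^2, p = ct$p.value, method = method)
}

#' Recommend a correlation method from marginal normality
#'
#' Shapiro-Wilk tests on both variables: if either is significantly
#' non-normal at the given level, Spearman is recommended, otherwise
#' Pearson.
#'
#' @param x,y numeric vectors.
#' @param alpha significance level for the normality gate.
#' @return `"spearman"` or `"pearson"`.
#' @export
recommend_correlation_method <- function(x, y, alpha = 0.05) {
  px <- stats::shapiro.test(x)$p.value
  py <- stats::shapiro.test(y)$p.value
  if (min(px, py) < alpha) "spearman" else "pearson"
}
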