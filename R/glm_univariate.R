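#' Build a boxcar design matrix for epoch regressors
#'
#' One regressor per condition x epoch (sample, delay, response; boxcars of
#' 4, 8 and 4 s), each convolved with the canonical double-gamma HRF and
#' sampled at the TR. Multiple schedules (e.g. a 3O block followed by a 1O
#' block) are concatenated in time in the order given. An intercept column
#' is appended.
#'
#' @param schedules a `trial_schedule` or a list of them.
#' @param tr_s repetition time in seconds (default 2).
#' @return an object of class `design_matrix`: `X` (TRs x regressors with
#'   column names like `Sample_3O`), `tr_s`, `n_tr`.
#' @export
build_design_matrix <- function(schedules, tr_s = 2) {
  if (tr_s <= 0) stop("TR must be positive")
  if (inherits(schedules, "trial_schedule")) schedules <- list(schedules)
  if (length(schedules) == 0 || sum(vapply(schedules, nrow, 0L)) == 0) {
    stop("empty schedule")
  }
  trs_per_trial <- 12L
  n_per <- vapply(schedules, nrow, integer(1)) * trs_per_trial
  n_tr <- sum(n_per)
  offsets <- cumsum(c(0L, n_per[-length(n_per)]))

  epochs <- list(Sample = c(0, 4), Delay = c(4, 12), Response = c(12, 16))
  conds <- unique(vapply(schedules, function(s) s$condition[1], ""))
  cols <- list()
  for (cond in conds) {
    for (ep in names(epochs)) {
      box <- numeric(n_tr)
      for (j in seq_along(schedules)) {
        s <- schedules[[j]]
        if (s$condition[1] != cond) next
        for (i in seq_len(nrow(s))) {
          t0 <- s$onset_sample[i] + epochs[[ep]][1]
          t1 <- s$onset_sample[i] + epochs[[ep]][2]
          bins <- offsets[j] + which((seq_len(n_per[j]) - 1) * tr_s >= t0 &
                                       (seq_len(n_per[j]) - 1) * tr_s < t1)
          box[bins] <- 1
        }
      }
      cols[[paste0(ep, "_", cond)]] <- box
    }
  }
  Xraw <- do.call(cbind, cols)
  X <- convolve_rows_hrf(t(Xraw), tr_s = tr_s)
  X <- t(X)
  colnames(X) <- names(cols)
  if (any(colSums(abs(X)) == 0)) stop("all-zero regressor in design")
  X <- cbind(X, intercept = 1)
  structure(list(X = X, tr_s = tr_s, n_tr = n_tr),
            class = "design_matrix")
}

#' Build a contrast weight vector by regressor name
#' @param design a `design_matrix`.
#' @param plus,minus character vectors of regressor names entering with
#'   weight +1 and -1.
#' @return numeric contrast vector aligned with the design columns.
#' @export
contrast_vector <- function(design, plus, minus = character(0)) {
  nm <- colnames(design$X)
  bad <- setdiff(c(plus, minus), nm)
  if (length(bad)) stop("unknown regressors: ", paste(bad, collapse = ", "))
  w <- numeric(length(nm)); names(w) <- nm
  w[plus] <- 1; w[minus] <- -1
  w
}

#' Per-voxel GLM contrast t-values
#'
#' Ordinary least squares per voxel;
#' `t = c' b / sqrt(sigma2 * c' (X'X)^-1 c)` with residual degrees of
#' freedom `TRs - rank(X)`.
#'
#' @param data a `voxel_dataset` or a voxels x TRs matrix.
#' @param design a `design_matrix` (or plain matrix).
#' @param contrast weight vector over design columns.
#' @return numeric vector of t-values, one per voxel.
#' @export
fit_glm_contrast <- function(data, design, contrast) {
  Y <- if (inherits(data, "voxel_dataset")) data$signal else as.matrix(data)
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (ncol(Y) != nrow(X)) stop("data TRs and design rows disagree")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear regressors: ",
         paste(dropped, collapse = ", "))
  }
  XtXinv <- chol2inv(qr.R(qrX))
  beta <- XtXinv %*% crossprod(X, t(Y))       # p x voxels
  resid <- t(Y) - X %*% beta
  df <- nrow(X) - qrX$rank
  sigma2 <- colSums(resid^2) / df
  cb <- as.numeric(crossprod(contrast, beta))
  se <- sqrt(pmax(sigma2 * as.numeric(t(contrast) %*% XtXinv %*% contrast),
                  .Machine$double.xmin))
  cb / se
}

#' Select the top-k voxels of a contrast t-map
#'
#' @param tmap per-voxel t-values.
#' @param mask voxel indices eligible for selection (default all).
#' @param k number of voxels to keep (the conventional functional-ROI size
#'   is 400). Ties at the cutoff are broken toward the lowest voxel index;
#'   `k` larger than the mask triggers a warning and returns the whole
#'   mask.
#' @param contrast_label optional label stored with the selection.
#' @return an object of class `roi_selection`: `indices` (into the full
#'   voxel set), `t_values` (non-increasing), `k`, `contrast_label`.
#' @export
select_roi_topk <- function(tmap, mask = seq_along(tmap), k = 400,
                            contrast_label = "") {
  if (k < 1) stop("k must be >= 1")
  if (k > length(mask)) {
    warning("k exceeds mask size; returning all ", length(mask),
            " masked voxels")
    k <- length(mask)
  }
  tv <- tmap[mask]
  ord <- order(-tv, mask)          # descending t, ascending index on ties
  keep <- ord[seq_len(k)]
  structure(list(indices = mask[keep], t_values = tv[keep], k = k,
                 contrast_label = contrast_label),
            class = "roi_selection")
}

#' @export
print.roi_selection <- function(x, ...) {
  cat(sprintf("ROI: %d voxels%s; t in [%.2f, %.2f]\n", length(x$indices),
              if (nzchar(x$contrast_label))
                paste0(" (", x$contrast_label, ")") else "",
              min(x$t_values), max(x$t_values)))
  invisible(x)
}

#' Trial-averaged signal-change time course within an ROI
#'
#' Averages the 12-TR trial time course over ROI voxels and over trials of
#' one condition, then subtracts the first-TR value and scales by 100, so
#' the curve is 0 at TR1. On run-z-scored data this is "percent signal
#' change from the first TR" in z units x 100.
#'
#' @param dataset a `voxel_dataset`.
#' @param roi an `roi_selection` or a vector of voxel indices.
#' @param condition condition label to average (default: all trials).
#' @return numeric vector of 12 values (TR1..TR12), zero at TR1.
#' @export
trial_average_psc <- function(dataset, roi, condition = NULL) {
  stopifnot(inherits(dataset, "voxel_dataset"))
  idx <- if (inherits(roi, "roi_selection")) roi$indices else roi
  if (length(idx) == 0) stop("empty ROI")
  trials <- seq_len(max(dataset$tr_labels$trial))
  if (!is.null(condition)) {
    trials <- trials[dataset$schedule$condition == condition]
    if (length(trials) == 0) stop("no trials of condition ", condition)
  }
  curve <- vapply(1:12, function(tr) {
    mean(trial_tr_matrix(dataset, tr, trials)[idx, , drop = FALSE])
  }, numeric(1))
  (curve - curve[1]) * 100
}

#' Remove polynomial trends per run
#'
#' Residualizes each voxel's time series against linear, quadratic and
#' cubic polynomials of time, separately within each run — the standard
#' drift-removal step preceding z-scoring.
#'
#' @param dataset a `voxel_dataset`.
#' @param degree polynomial degree (default 3).
#' @return the dataset with detrended `signal`.
#' @export
detrend_runs <- function(dataset, degree = 3) {
  stopifnot(inherits(dataset, "voxel_dataset"))
  runs <- dataset$tr_labels$run
  for (r in unique(runs)) {
    cols <- which(runs == r)
    P <- cbind(1, stats::poly(seq_along(cols), degree))
    Y <- t(dataset$signal[, cols, drop = FALSE])
    dataset$signal[, cols] <- t(Y - P %*% solve(crossprod(P), crossprod(P, Y)))
  }
  dataset
}
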