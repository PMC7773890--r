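#' Remove the common baseline pattern from a voxel response matrix
#'
#' Projects every condition's response pattern onto the orthogonal
#' complement of the mean pattern: `B - m (m^T B) / (m^T m)`, where `m` is
#' the row-wise (per-voxel) mean of `B` across conditions. After removal
#' the mean pattern carries no signal (`m^T B = 0`), so condition
#' differences rather than overall responsiveness drive the encoding
#' model. Applied per run before training. When `m` is the zero vector the
#' input is returned unchanged.
#'
#' @param B voxels x conditions (or trials) matrix.
#' @return matrix of the same shape, with columns orthogonal to `m`.
#' @export
remove_baseline <- function(B) {
  B <- as.matrix(B)
  if (length(B) == 0) stop("empty response matrix")
  m <- rowMeans(B)
  nm2 <- sum(m^2)
  if (nm2 == 0) return(B)
  B - m %*% (t(m) %*% B) / nm2
}

#' Estimate inverted-encoding-model weights
#'
#' Least-squares estimate of the weight matrix mapping channel responses to
#' voxel responses: `W = B1 C1^T (C1 C1^T)^-1`, the minimizer of
#' `||B1 - W C1||_F`.
#'
#' @param B1 voxels x trials training data.
#' @param C1 channels x trials channel responses of the training stimuli.
#' @return an object of class `iem_weights` with element `W`
#'   (voxels x channels).
#' @export
train_iem <- function(B1, C1) {
  B1 <- as.matrix(B1); C1 <- as.matrix(C1)
  if (ncol(B1) != ncol(C1)) stop("B1 and C1 must share the trial dimension")
  if (ncol(C1) < nrow(C1)) {
    stop("need at least as many training trials as channels")
  }
  G <- C1 %*% t(C1)
  cn <- kappa(G, exact = FALSE)
  if (!is.finite(cn) || cn > 1e8) {
    row_norm <- sqrt(rowSums(C1^2))
    stop("C1 C1^T is ill-conditioned (condition number ", format(cn),
         "); weakest channels: ",
         paste(order(row_norm)[seq_len(min(3, nrow(C1)))], collapse = ", "))
  }
  W <- B1 %*% t(C1) %*% solve(G)
  structure(list(W = W, k = nrow(C1), n_train = ncol(C1)),
            class = "iem_weights")
}

#' Invert estimated weights to reconstruct channel responses
#'
#' `C2 = (W^T W)^-1 W^T B2`. On the range of `W` (i.e. when `B2 = W C`)
#' this recovers `C` exactly.
#'
#' @param W an `iem_weights` object or a voxels x channels matrix.
#' @param B2 voxels x trials test data.
#' @return channels x trials matrix of estimated channel responses.
#' @export
invert_iem <- function(W, B2) {
  if (inherits(W, "iem_weights")) W <- W$W
  W <- as.matrix(W); B2 <- as.matrix(B2)
  if (nrow(W) < ncol(W)) stop("W must have at least as many voxels as channels")
  cn <- kappa(W, exact = FALSE)
  if (!is.finite(cn) || cn > 1e8) stop("W is rank deficient")
  solve(crossprod(W), crossprod(W, B2))
}

# Moore-Penrose pseudoinverse of a symmetric PSD matrix via its
# eigendecomposition; eigenvalues below tol * max are treated as null
pinv_sym <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) return(matrix(0, nrow(S), ncol(S)))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

# baseline-remove the voxels x trials matrix separately within each run
remove_baseline_by_run <- function(B, runs) {
  for (r in unique(runs)) {
    idx <- which(runs == r)
    B[, idx] <- remove_baseline(B[, idx, drop = FALSE])
  }
  B
}

#' Reconstruct channel tuning functions from voxel data
#'
#' Implements the full inverted-encoding reconstruction at one within-trial
#' TR: per-run baseline removal, location-specific model training on the
#' training condition, inversion on the test condition, circular recentering
#' of every test trial's estimated channel response onto the tested feature,
#' and aggregation over `n_shift_iters` bases whose channel centers are
#' rigidly shifted by `period / n_shift_iters` degrees per iteration,
#' yielding a smooth 180-point tuning function. Channel responses are
#' computed from the presented (jittered) stimulus features; the jitter
#' also keeps the channel design well conditioned at basis alignments that
#' would be exactly degenerate for un-jittered features midway between
#' channels. Any residual near-degenerate shift is handled by
#' Moore-Penrose pseudoinversion, which drops the null direction instead
#' of amplifying it.
#'
#' For `feature = "orientation"` a separate model is trained for each sample
#' location on the training trials at that location, and each test trial is
#' reconstructed with the model matching the tested item's location; the
#' per-offset estimates from all location-specific models are averaged. For
#' `feature = "location"` a single model is trained on all training trials
#' (each training trial's location is the feature).
#'
#' When training and test condition coincide, the per-location trials are
#' split into a training set (`train_frac`, 81 of 90 by default) and a test
#' set, repeated over `n_splits` random splits and averaged. Across
#' conditions (e.g. train `"1O"`, test `"3O"`), all training trials are
#' used and all test trials reconstructed once.
#'
#' @param dataset a `voxel_dataset` (its `schedule` supplies conditions,
#'   features and runs).
#' @param basis a `channel_basis` (period 180 for orientation, 360 for
#'   location).
#' @param tr_index within-trial TR (1..12) at which to train and test.
#' @param train_condition,test_condition condition labels in the schedule.
#' @param feature `"orientation"` or `"location"`.
#' @param test_selection per-test-trial item index to reconstruct and
#'   recenter on (defaults to the probed item). May be a named list of such
#'   vectors, in which case one CTF per element is returned, all sharing
#'   the same trained models.
#' @param train_frac fraction of per-location trials used for training when
#'   train and test conditions coincide (0.9 reproduces an 81/9 split of 90
#'   trials).
#' @param n_splits number of random splits averaged in the same-condition
#'   case.
#' @param n_shift_iters number of successive one-bin (`period/180` degree)
#'   basis shifts aggregated (default 180, a full cycle giving `k`
#'   estimates per point). Any multiple of the channel spacing in bins
#'   (e.g. 30 for 6 channels) still covers all 180 points, with
#'   proportionally fewer estimates per point.
#' @param seed integer seed for the split randomization.
#' @return an object of class `ctf` (or a named list of them): `offsets`
#'   (degrees, length 180, 0 = tested feature), `values`, `feature`,
#'   `period`, `tr_index`, `n_test`.
#' @export
reconstruct_ctf <- function(dataset, basis, tr_index,
                            train_condition = "1O", test_condition = "1O",
                            feature = c("orientation", "location"),
                            test_selection = NULL,
                            train_frac = 0.9, n_splits = 10,
                            n_shift_iters = 180, seed = 1L) {
  feature <- match.arg(feature)
  stopifnot(inherits(dataset, "voxel_dataset"))
  sched <- dataset$schedule
  n_locations <- attr(sched, "n_locations")
  if (is.null(n_locations)) n_locations <- max(sched$loc_1, na.rm = TRUE)

  if (!isTRUE(attr(dataset, "zscored"))) dataset <- zscore_runs(dataset)
  B_all <- trial_tr_matrix(dataset, tr_index)
  runs <- sched$run
  B_all <- remove_baseline_by_run(B_all, runs)

  train_idx <- which(sched$condition == train_condition)
  test_idx <- which(sched$condition == test_condition)
  if (length(test_idx) == 0) stop("no trials of condition ", test_condition)

  feat_m <- as.matrix(sched[, c("sample_1", "sample_2", "sample_3")])
  loc_m <- as.matrix(sched[, c("loc_1", "loc_2", "loc_3")])

  # training features: 1-item training condition uses its single item
  train_feat <- if (feature == "orientation") feat_m[train_idx, 1] else
    location_angle(loc_m[train_idx, 1], n_locations)
  train_loc <- loc_m[train_idx, 1]

  selections <- test_selection
  single <- FALSE
  if (is.null(selections)) {
    selections <- list(ctf = sched$probed_index[test_idx])
    single <- TRUE
  } else if (!is.list(selections)) {
    selections <- list(ctf = selections)
    single <- TRUE
  }
  sel_feat <- lapply(selections, function(sel) {
    rows <- cbind(seq_along(test_idx), sel)
    if (feature == "orientation") feat_m[test_idx, , drop = FALSE][rows]
    else location_angle(loc_m[test_idx, , drop = FALSE][rows], n_locations)
  })
  sel_loc <- lapply(selections, function(sel) {
    loc_m[test_idx, , drop = FALSE][cbind(seq_along(test_idx), sel)]
  })

  step <- basis$period / 180
  same_cond <- train_condition == test_condition
  n_bins <- 180L
  acc <- lapply(selections, function(.) numeric(n_bins))
  cnt <- lapply(selections, function(.) numeric(n_bins))

  set.seed(seed)
  model_groups <- if (feature == "orientation") seq_len(n_locations) else 0L
  for (g in model_groups) {
    tr_g <- if (feature == "orientation") which(train_loc == g) else
      seq_along(train_idx)
    splits <- make_splits(tr_g, same_cond, train_frac, n_splits)
    for (sp in splits) {
      B1 <- B_all[, train_idx[sp$train], drop = FALSE]
      th_train <- train_feat[sp$train]
      if (length(sp$train) < basis$k) {
        stop("location model ", g, ": only ", length(sp$train),
             " training trials for ", basis$k, " channels")
      }
      for (s in seq_len(n_shift_iters) - 1L) {
        shift <- s * step
        C1 <- basis_response(basis, th_train, shift)
        W <- B1 %*% t(C1) %*% pinv_sym(C1 %*% t(C1))
        WtW_inv <- pinv_sym(crossprod(W))
        for (nm in names(selections)) {
          # test trials handled by this model group
          tt <- if (same_cond) {
            sp$test
          } else {
            if (feature == "orientation") which(sel_loc[[nm]] == g) else
              seq_along(test_idx)
          }
          if (length(tt) == 0) next
          C2 <- WtW_inv %*% crossprod(W, B_all[, test_idx[tt], drop = FALSE])
          th_test <- sel_feat[[nm]][tt]
          u <- outer(round((basis$centers + shift) / step),
                     round(th_test / step), "-") %% n_bins + 1L
          sums <- rowsum(as.vector(C2), group = as.vector(u))
          ids <- as.integer(rownames(sums))
          acc[[nm]][ids] <- acc[[nm]][ids] + sums[, 1]
          cnt[[nm]][ids] <- cnt[[nm]][ids] +
            tabulate(as.vector(u), nbins = n_bins)[ids]
        }
      }
    }
  }

  # offsets span [-period/2, period/2), i.e. -90..+89 for orientation
  off_axis <- ((seq_len(n_bins) - 1L) * step + basis$period / 2) %%
    basis$period - basis$period / 2
  ord <- order(off_axis)
  out <- lapply(names(selections), function(nm) {
    vals <- acc[[nm]] / pmax(cnt[[nm]], 1)
    vals[cnt[[nm]] == 0] <- NA_real_
    structure(list(offsets = off_axis[ord], values = vals[ord],
                   feature = feature, period = basis$period,
                   tr_index = tr_index, n_test = length(test_idx),
                   train_condition = train_condition,
                   test_condition = test_condition, seed = seed),
              class = "ctf")
  })
  names(out) <- names(selections)
  if (single) out[[1]] else out
}

# training/test splits within one model group: same-condition analyses use
# n_splits random train_frac splits; cross-condition analyses train on all
make_splits <- function(tr_g, same_cond, train_frac, n_splits) {
  if (!same_cond) return(list(list(train = tr_g, test = integer(0))))
  n <- length(tr_g)
  n_train <- round(train_frac * n)
  lapply(seq_len(n_splits), function(i) {
    tr <- sort(sample(tr_g, n_train))
    # positions index the training condition, which here is also the test
    # condition, so held-out positions are valid test-trial positions
    list(train = tr, test = setdiff(tr_g, tr))
  })
}

#' @export
print.ctf <- function(x, ...) {
  cat(sprintf("channel tuning function (%s, TR%d, %d points)\n",
              x$feature, x$tr_index, length(x$values)))
  cat(sprintf("  train %s -> test %s, %d test trials; value at 0 = %.4f\n",
              x$train_condition, x$test_condition, x$n_test,
              x$values[which(x$offsets == 0)]))
  invisible(x)
}

#' @export
plot.ctf <- function(x, ...) {
  graphics::plot(x$offsets, x$values, type = "l",
                 xlab = sprintf("offset from tested %s (deg)", x$feature),
                 ylab = "channel response", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Randomly select one non-probed item per multi-item trial
#'
#' @param schedule a `trial_schedule` with set size 3 (or a subset of its
#'   rows).
#' @param seed integer seed.
#' @return integer vector of item indices (per trial), never the probed one.
#' @export
select_nonprobed <- function(schedule, seed = 1L) {
  set_size <- attr(schedule, "set_size")
  if (is.null(set_size)) set_size <- 3L
  if (set_size != 3) stop("non-probed selection requires 3-item trials")
  set.seed(seed)
  vapply(seq_len(nrow(schedule)), function(i) {
    sample(setdiff(seq_len(set_size), schedule$probed_index[i]), 1L)
  }, integer(1))
}
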