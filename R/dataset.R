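#' Concatenate voxel datasets in time
#'
#' Joins two datasets simulated for the same voxels (e.g. a 3O block and a
#' 1O block sharing ground-truth weights) into one timeline: signals are
#' concatenated, trial and run labels renumbered, and schedule onsets
#' shifted.
#'
#' @param ... `voxel_dataset` objects with the same number of voxels.
#' @return a combined `voxel_dataset` whose schedule carries every trial's
#'   condition.
#' @export
concat_datasets <- function(...) {
  ds <- list(...)
  stopifnot(length(ds) >= 1, all(vapply(ds, inherits, TRUE, "voxel_dataset")))
  nv <- vapply(ds, function(d) nrow(d$signal), integer(1))
  if (length(unique(nv)) != 1) stop("datasets must share the voxel set")
  trial_off <- 0L; run_off <- 0L; time_off <- 0
  sig <- list(); labs <- list(); scheds <- list()
  for (d in ds) {
    sig[[length(sig) + 1]] <- d$signal
    lab <- d$tr_labels
    lab$trial <- lab$trial + trial_off
    lab$run <- lab$run + run_off
    labs[[length(labs) + 1]] <- lab
    s <- as.data.frame(d$schedule)
    s$trial_id <- s$trial_id + trial_off
    s$run <- s$run + run_off
    for (col in c("onset_sample", "onset_delay", "onset_response",
                  "onset_iti")) {
      s[[col]] <- s[[col]] + time_off
    }
    scheds[[length(scheds) + 1]] <- s
    trial_off <- trial_off + max(d$tr_labels$trial)
    run_off <- run_off + max(d$tr_labels$run)
    time_off <- time_off + ncol(d$signal) * 2
  }
  sched <- do.call(rbind, scheds)
  attr(sched, "n_locations") <- attr(ds[[1]]$schedule, "n_locations")
  class(sched) <- c("trial_schedule", "data.frame")
  structure(list(signal = do.call(cbind, sig),
                 tr_labels = do.call(rbind, labs),
                 truth = ds[[1]]$truth,
                 schedule = sched),
            class = "voxel_dataset")
}

#' Restrict a voxel dataset to a subset of voxels
#'
#' @param dataset a `voxel_dataset`.
#' @param roi an `roi_selection` or vector of voxel indices.
#' @return the dataset with only the selected voxels (truth weights
#'   subset accordingly).
#' @export
subset_voxels <- function(dataset, roi) {
  stopifnot(inherits(dataset, "voxel_dataset"))
  idx <- if (inherits(roi, "roi_selection")) roi$indices else roi
  if (length(idx) == 0) stop("empty voxel subset")
  dataset$signal <- dataset$signal[idx, , drop = FALSE]
  if (!is.null(dataset$truth$w_ori)) {
    dataset$truth$w_ori <- dataset$truth$w_ori[idx, , drop = FALSE]
    dataset$truth$w_loc <- dataset$truth$w_loc[idx, , drop = FALSE]
  }
  dataset
}

#' Z-score each voxel within run
#'
#' Standardizes every voxel's time series to mean 0, SD 1 separately
#' within each run — the standard preprocessing step before encoding-model
#' analysis, and the scale on which the baseline-removal projection is
#' well behaved. Idempotent. Voxels constant within a run are left at 0.
#'
#' @param dataset a `voxel_dataset`.
#' @return the dataset with standardized `signal` and attribute
#'   `zscored = TRUE`.
#' @export
zscore_runs <- function(dataset) {
  stopifnot(inherits(dataset, "voxel_dataset"))
  runs <- dataset$tr_labels$run
  for (r in unique(runs)) {
    cols <- which(runs == r)
    X <- dataset$signal[, cols, drop = FALSE]
    mu <- rowMeans(X)
    sd <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
    sd[sd == 0] <- 1
    dataset$signal[, cols] <- (X - mu) / sd
  }
  attr(dataset, "zscored") <- TRUE
  dataset
}

#' @export
print.voxel_dataset <- function(x, ...) {
  cat(sprintf("voxel dataset: %d voxels x %d TRs (%d trials, TR = 2 s)\n",
              nrow(x$signal), ncol(x$signal), max(x$tr_labels$trial)))
  invisible(x)
}
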