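#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma impulse response (response peak near 6 s,
#' undershoot near 16 s, undershoot ratio 1/6), evaluated at the supplied
#' times and normalized to unit peak.
#'
#' @param t times in seconds (>= 0).
#' @param peak_delay,undershoot_delay gamma shape parameters (seconds).
#' @param ratio undershoot amplitude relative to the peak.
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak_delay = 6, undershoot_delay = 16,
                             ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_delay, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_delay, rate = 1)
  h / max(h)
}

# convolve each row of a drive matrix with the HRF at TR resolution
convolve_rows_hrf <- function(drive, tr_s = 2, span_s = 32) {
  kern <- hrf_double_gamma(seq(0, span_s, by = tr_s))
  t(apply(drive, 1, function(x) {
    stats::convolve(x, rev(kern), type = "open")[seq_along(x)]
  }))
}

#' Simulate channel-tuned voxel time series for a trial schedule
#'
#' Generates a voxels x TRs array (TR = 2 s, 12 TRs per trial, trials
#' concatenated) from a linear channel model: each voxel's noiseless drive
#' is its random nonnegative weight vector times the channel responses to
#' the trial's sample features, with epoch-specific gains. During the 4-s
#' sample epoch all items contribute orientation and location signal at
#' full gain; during the 8-s delay only location signal remains, scaled by
#' `profile$delay_location_gain`; during the 4-s response epoch the probed
#' item contributes at `profile$probed_gain` and non-probed items at
#' `profile$nonprobed_gain`; the 8-s inter-trial interval is silent. The
#' epoch drive is convolved with the canonical double-gamma HRF sampled at
#' the TR, and independent Gaussian noise of standard deviation `noise_sd`
#' is added per voxel and TR. Channel responses are computed from the
#' presented (jittered) orientations, as voxels respond to the stimulus
#' actually shown.
#'
#' @param schedule a `trial_schedule`.
#' @param profile a [group_profile()] supplying the epoch gains.
#' @param n_voxels number of voxels (>= total channel count).
#' @param basis_orientation orientation `channel_basis`.
#' @param basis_location location `channel_basis` (360-degree period).
#' @param noise_sd Gaussian noise SD per TR (>= 0).
#' @param seed integer seed for weights and noise.
#' @param weights optional list with `w_ori` and `w_loc` matrices
#'   (voxels x channels) to reuse across datasets simulated for the same
#'   synthetic subject; drawn uniformly on `[0, 1]` when NULL.
#' @return a list of class `voxel_dataset`: `signal` (voxels x TRs),
#'   `tr_labels` (`data.frame` with `trial`, `tr` 1..12, `run`), `truth`
#'   (ground-truth weight matrices and `noise_sd`), and the generating
#'   `schedule`.
#' @export
simulate_bold <- function(schedule, profile, n_voxels,
                          basis_orientation, basis_location,
                          noise_sd = 0.5, seed = 1L, weights = NULL) {
  stopifnot(inherits(schedule, "trial_schedule"))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  k_ori <- basis_orientation$k
  k_loc <- basis_location$k
  if (n_voxels < k_ori + k_loc) {
    stop("n_voxels must be at least the total channel count (",
         k_ori + k_loc, ")")
  }
  set.seed(seed)
  n_trials <- nrow(schedule)
  trs_per_trial <- 12L
  n_tr <- n_trials * trs_per_trial
  set_size <- attr(schedule, "set_size")
  n_locations <- attr(schedule, "n_locations")

  feats <- schedule_items(schedule, "sample")
  locs <- schedule_items(schedule, "loc")

  # per-trial channel drives (sum over items), one set per epoch role
  drive_ori <- matrix(0, k_ori, n_tr)
  drive_loc <- matrix(0, k_loc, n_tr)
  sample_bins <- 1:2; delay_bins <- 3:6; resp_bins <- 7:8
  for (i in seq_len(n_trials)) {
    cols <- (i - 1) * trs_per_trial
    co <- basis_response(basis_orientation, feats[i, seq_len(set_size)])
    cl <- basis_response(basis_location,
                         location_angle(locs[i, seq_len(set_size)],
                                        n_locations))
    gains_resp <- rep(profile$nonprobed_gain, set_size)
    gains_resp[schedule$probed_index[i]] <- profile$probed_gain
    drive_ori[, cols + sample_bins] <- rowSums(co)
    drive_loc[, cols + sample_bins] <- rowSums(cl)
    drive_loc[, cols + delay_bins] <- rowSums(cl) * profile$delay_location_gain
    drive_ori[, cols + resp_bins] <- co %*% gains_resp
    drive_loc[, cols + resp_bins] <- cl %*% gains_resp
  }
  conv_ori <- convolve_rows_hrf(drive_ori)
  conv_loc <- convolve_rows_hrf(drive_loc)

  if (is.null(weights)) {
    w_ori <- matrix(stats::runif(n_voxels * k_ori), n_voxels, k_ori)
    w_loc <- matrix(stats::runif(n_voxels * k_loc), n_voxels, k_loc)
  } else {
    w_ori <- weights$w_ori; w_loc <- weights$w_loc
    stopifnot(nrow(w_ori) == n_voxels, ncol(w_ori) == k_ori,
              nrow(w_loc) == n_voxels, ncol(w_loc) == k_loc)
  }
  signal <- w_ori %*% conv_ori + w_loc %*% conv_loc
  if (noise_sd > 0) {
    signal <- signal + matrix(stats::rnorm(length(signal), 0, noise_sd),
                              nrow(signal), ncol(signal))
  }
  tr_labels <- data.frame(
    trial = rep(seq_len(n_trials), each = trs_per_trial),
    tr = rep(seq_len(trs_per_trial), n_trials),
    run = rep(schedule$run, each = trs_per_trial)
  )
  log_call("simulate_bold",
           list(n_trials = n_trials, n_voxels = n_voxels,
                noise_sd = noise_sd, seed = seed,
                profile = unclass(profile)))
  structure(list(signal = signal, tr_labels = tr_labels,
                 truth = list(w_ori = w_ori, w_loc = w_loc,
                              noise_sd = noise_sd),
                 schedule = schedule),
            class = "voxel_dataset")
}

#' Extract the voxels x trials matrix at one within-trial TR
#'
#' @param dataset a `voxel_dataset`.
#' @param tr_index within-trial TR (1..12; TR1 is the first volume at
#'   sample onset).
#' @param trials optional trial subset.
#' @return voxels x trials matrix.
#' @export
trial_tr_matrix <- function(dataset, tr_index, trials = NULL) {
  stopifnot(inherits(dataset, "voxel_dataset"))
  if (tr_index < 1 || tr_index > 12) stop("tr_index must be within 1..12")
  n_trials <- max(dataset$tr_labels$trial)
  if (is.null(trials)) trials <- seq_len(n_trials)
  cols <- (trials - 1L) * 12L + tr_index
  dataset$signal[, cols, drop = FALSE]
}
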