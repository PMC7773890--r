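#' Simulate continuous-report responses from the mixture generative model
#'
#' For each trial the response is, with probability `pT`, the probed item's
#' orientation plus von Mises noise (concentration `kappa_mix` on the
#' doubled-angle circle); with probability `pN`, a uniformly chosen
#' non-probed item's orientation plus the same noise (a "swap" response);
#' and with probability `pU`, uniform on the orientation circle. The
#' generating component of every trial is recorded so that simulation-based
#' tests can score recovery against ground truth.
#'
#' @param schedule a `trial_schedule` from [make_schedule()].
#' @param profile a [group_profile()]; `pN` must be 0 for single-item
#'   schedules.
#' @param seed integer seed.
#' @return a `data.frame` of class `response_table` with columns `trial_id`,
#'   `response` (degrees in `[0, 180)`), `error` (signed degrees in
#'   `(-90, +90]` relative to the probed item), `component` (`"T"`, `"N"`,
#'   `"U"`), and non-target offsets `offset_1`, `offset_2` (signed degrees
#'   of each non-probed item relative to the probed item; NA for
#'   single-item trials).
#' @export
simulate_behavior <- function(schedule, profile, seed = 1L) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(profile, "group_profile"))
  set_size <- attr(schedule, "set_size")
  if (set_size == 1 && profile$pN > 0) {
    stop("pN > 0 is inconsistent with single-item trials (no non-target)")
  }
  set.seed(seed)
  n <- nrow(schedule)
  feats <- probed_features(schedule, what = "sample")
  target <- feats$probed
  nonprobed <- feats$nonprobed

  component <- sample(c("T", "N", "U"), n, replace = TRUE,
                      prob = c(profile$pT, profile$pN, profile$pU))
  # noise on the doubled circle, halved back to orientation degrees;
  # an infinite concentration degenerates to exact recall
  kappa <- profile$kappa_mix
  noise_deg <- if (is.finite(kappa)) {
    rvonmises(n, 0, min(kappa, 1e4)) * 90 / pi
  } else {
    numeric(n)
  }

  centre <- target
  is_swap <- component == "N"
  if (any(is_swap)) {
    pick <- sample.int(ncol(nonprobed), sum(is_swap), replace = TRUE)
    centre[is_swap] <- nonprobed[cbind(which(is_swap), pick)]
  }
  response <- (centre + noise_deg) %% 180
  is_guess <- component == "U"
  response[is_guess] <- stats::runif(sum(is_guess), 0, 180)

  err <- circ_diff(response, target, period = 180)
  offsets <- matrix(NA_real_, n, 2)
  if (ncol(nonprobed) > 0) {
    for (j in seq_len(ncol(nonprobed))) {
      offsets[, j] <- circ_diff(nonprobed[, j], target, period = 180)
    }
  }
  log_call("simulate_behavior",
           list(n_trials = n, profile = unclass(profile), seed = seed))
  structure(data.frame(trial_id = schedule$trial_id,
                       response = response,
                       error = err,
                       component = component,
                       offset_1 = offsets[, 1],
                       offset_2 = offsets[, 2],
                       stringsAsFactors = FALSE),
            class = c("response_table", "data.frame"),
            profile = profile, seed = seed)
}

#' Collect per-trial non-target offsets as a matrix
#' @param responses a `response_table`.
#' @return trials x 2 matrix of signed offsets (all NA for 1-item designs).
#' @export
nontarget_offsets <- function(responses) {
  as.matrix(responses[, c("offset_1", "offset_2"), drop = FALSE])
}
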