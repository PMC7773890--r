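#' Generate a balanced delayed-recall trial schedule
#'
#' Builds a trial schedule for a continuous-report (delayed-estimation)
#' working-memory experiment in which every (base orientation x location)
#' cell is probed exactly `probed_repeats_per_cell` times. Base orientations
#' are evenly spaced on the 180-degree orientation circle
#' (`(0:(n_orientations-1)) * 180/n_orientations`); locations are integer
#' indices `1..n_locations`. On multi-item trials the non-probed items take
#' distinct locations and orientations drawn without replacement from the
#' remaining pools. A per-sample jitter, uniform over {+-1..+-5} degrees, is
#' added to each base orientation. Epoch onsets follow the fixed trial
#' structure: 4 s sample, 8 s delay, 4 s response, 8 s inter-trial interval
#' (24 s per trial, 12 volumes at a 2 s TR).
#'
#' @param n_orientations number of base orientations (e.g. 9 or 6).
#' @param n_locations number of possible sample locations (e.g. 4 or 6).
#' @param set_size items per trial (1 or 3 in the designs emulated here).
#' @param probed_repeats_per_cell times each (orientation x location) cell
#'   is probed.
#' @param condition trial-type label: `"1O"`, `"3O"`, or `"1O1C1L"`.
#' @param seed integer seed controlling trial order, non-probed item draws
#'   and jitter.
#' @return a `data.frame` of class `trial_schedule`, one row per trial, with
#'   columns `trial_id`, `condition`, `probed_index`, `sample_1..3` (jittered
#'   orientations, NA beyond `set_size`), `base_1..3`, `jitter_1..3`,
#'   `loc_1..3`, `run`, and epoch onsets `onset_sample`, `onset_delay`,
#'   `onset_response`, `onset_iti` (seconds). Attributes record the design
#'   parameters.
#' @export
#' @examples
#' sched <- make_schedule(6, 6, 3, 3, "3O", seed = 1)
#' nrow(sched)  # 108 trials
make_schedule <- function(n_orientations, n_locations, set_size,
                          probed_repeats_per_cell,
                          condition = c("1O", "3O", "1O1C1L"),
                          seed = 1L) {
  condition <- match.arg(condition)
  if (n_orientations < 1 || n_locations < 1 || set_size < 1 ||
      probed_repeats_per_cell < 1) {
    stop("design counts must all be >= 1")
  }
  if (set_size > n_locations) {
    stop("set_size (", set_size, ") exceeds n_locations (", n_locations,
         "): items within a trial must occupy distinct locations")
  }
  expected_size <- switch(condition, "1O" = 1L, "3O" = 3L, "1O1C1L" = 3L)
  if (set_size != expected_size) {
    stop("condition ", condition, " requires set size ", expected_size)
  }

  base_oris <- (seq_len(n_orientations) - 1) * (180 / n_orientations)
  cells <- expand.grid(ori = base_oris, loc = seq_len(n_locations))
  cells <- cells[rep(seq_len(nrow(cells)), probed_repeats_per_cell), ]
  n_trials <- nrow(cells)

  set.seed(seed)
  ord <- sample.int(n_trials)
  cells <- cells[ord, ]

  max_items <- 3L
  base <- matrix(NA_real_, n_trials, max_items)
  locs <- matrix(NA_integer_, n_trials, max_items)
  for (i in seq_len(n_trials)) {
    b <- cells$ori[i]
    l <- cells$loc[i]
    if (set_size > 1) {
      other_oris <- sample(setdiff(base_oris, b), set_size - 1)
      other_locs <- sample(setdiff(seq_len(n_locations), l), set_size - 1)
      b <- c(b, other_oris)
      l <- c(l, other_locs)
    }
    # probed item position within the sample list is itself randomized
    pos <- sample.int(set_size)
    base[i, seq_len(set_size)] <- b[order(pos)]
    locs[i, seq_len(set_size)] <- l[order(pos)]
  }
  # probed position = where the probed cell's (orientation, location) landed
  probed_index <- rep(1L, n_trials)
  if (set_size > 1) {
    for (i in seq_len(n_trials)) {
      probed_index[i] <- which(base[i, ] == cells$ori[i] &
                                 locs[i, ] == cells$loc[i])[1]
    }
  }

  jit <- matrix(NA_real_, n_trials, max_items)
  present <- !is.na(base)
  jit[present] <- sample(c(-5:-1, 1:5), sum(present), replace = TRUE)

  trial_s <- 24
  onset <- (seq_len(n_trials) - 1) * trial_s
  out <- data.frame(
    trial_id = seq_len(n_trials),
    condition = condition,
    probed_index = as.integer(probed_index),
    sample_1 = base[, 1] + ifelse(is.na(jit[, 1]), 0, jit[, 1]),
    sample_2 = base[, 2] + ifelse(is.na(jit[, 2]), 0, jit[, 2]),
    sample_3 = base[, 3] + ifelse(is.na(jit[, 3]), 0, jit[, 3]),
    base_1 = base[, 1], base_2 = base[, 2], base_3 = base[, 3],
    jitter_1 = jit[, 1], jitter_2 = jit[, 2], jitter_3 = jit[, 3],
    loc_1 = locs[, 1], loc_2 = locs[, 2], loc_3 = locs[, 3],
    run = ((seq_len(n_trials) - 1) %/% 18L) + 1L,
    onset_sample = onset,
    onset_delay = onset + 4,
    onset_response = onset + 12,
    onset_iti = onset + 16,
    stringsAsFactors = FALSE
  )
  log_call("make_schedule",
           list(n_orientations = n_orientations, n_locations = n_locations,
                set_size = set_size,
                probed_repeats_per_cell = probed_repeats_per_cell,
                condition = condition, seed = seed))
  structure(out,
            class = c("trial_schedule", "data.frame"),
            n_orientations = n_orientations,
            n_locations = n_locations,
            set_size = set_size,
            probed_repeats_per_cell = probed_repeats_per_cell,
            seed = seed)
}

#' Extract per-trial sample matrices from a schedule
#'
#' @param schedule a `trial_schedule`.
#' @param what `"base"` for un-jittered orientations, `"sample"` for
#'   jittered ones, `"loc"` for location indices.
#' @return trials x set_size matrix.
#' @export
schedule_items <- function(schedule, what = c("base", "sample", "loc")) {
  what <- match.arg(what)
  ss <- attr(schedule, "set_size")
  cols <- paste0(what, "_", seq_len(ss))
  as.matrix(schedule[, cols, drop = FALSE])
}

#' Per-trial probed and non-probed features
#' @param schedule a `trial_schedule`.
#' @param what as in [schedule_items()].
#' @return list with `probed` (vector) and `nonprobed` (matrix, 0 columns for
#'   single-item trials).
#' @export
probed_features <- function(schedule, what = "base") {
  m <- schedule_items(schedule, what)
  idx <- schedule$probed_index
  n <- nrow(m)
  probed <- m[cbind(seq_len(n), idx)]
  if (ncol(m) == 1) {
    nonprobed <- matrix(numeric(0), n, 0)
  } else {
    nonprobed <- t(vapply(seq_len(n),
                          function(i) m[i, -idx[i]],
                          numeric(ncol(m) - 1)))
  }
  list(probed = probed, nonprobed = nonprobed)
}

#' Group-level behavioral and signal profile for the synthetic generator
#'
#' Encapsulates the mixture proportions and concentration that drive
#' behavioral simulation, plus the epoch signal gains that drive the voxel
#' simulator: `probed_gain` and `nonprobed_gain` scale the recall-epoch
#' signal of the probed and non-probed items, and `delay_location_gain`
#' scales the delay-epoch location signal.
#'
#' @param label group label, conventionally `"low_swap"` or `"high_swap"`.
#' @param pT,pN,pU mixture proportions (must sum to 1).
#' @param kappa_mix von Mises concentration of target/swap responses
#'   (rad^-1, doubled-angle circle).
#' @param probed_gain,nonprobed_gain,delay_location_gain nonnegative signal
#'   multipliers.
#' @return a list of class `group_profile`.
#' @export
group_profile <- function(label = "low_swap", pT = 0.9, pN = 0.02,
                          pU = 1 - pT - pN, kappa_mix = 10,
                          probed_gain = 1, nonprobed_gain = 0.1,
                          delay_location_gain = 1) {
  if (abs(pT + pN + pU - 1) > 1e-9) stop("pT + pN + pU must equal 1")
  if (min(pT, pN, pU) < 0) stop("mixture proportions must be nonnegative")
  if (min(probed_gain, nonprobed_gain, delay_location_gain) < 0) {
    stop("gains must be nonnegative")
  }
  structure(list(label = label, pT = pT, pN = pN, pU = pU,
                 kappa_mix = kappa_mix, probed_gain = probed_gain,
                 nonprobed_gain = nonprobed_gain,
                 delay_location_gain = delay_location_gain),
            class = "group_profile")
}
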