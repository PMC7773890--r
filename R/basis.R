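#' Construct a channel basis of half-rectified, exponentiated cosines
#'
#' Each of the `k` channels has an idealized tuning curve
#' `max(0, cos(pi * (theta - c_i) / period))^exponent`, with centers evenly
#' spaced at `c_i = (i - 1) * period / k`. On the 180-degree orientation
#' circle a feature orthogonal to a channel's center (90 degrees away)
#' therefore drives it exactly 0; the channel's own center drives it 1.
#' The default exponent of 7 is the total power applied to the
#' half-rectified cosine; it is a parameter so steeper profiles (e.g. 14)
#' can be explored.
#'
#' @param k number of channels (>= 2).
#' @param period feature-circle period in degrees: 180 for orientation,
#'   360 for location.
#' @param exponent positive power applied to the rectified cosine.
#' @return an object of class `channel_basis` with elements `k`, `centers`,
#'   `period`, `exponent`.
#' @export
#' @examples
#' b <- make_basis(9, 180)     # experiment-1 orientation basis
#' basis_response(b, 0)[1]     # 1 at the channel's own center
make_basis <- function(k, period = 180, exponent = 7) {
  if (k < 2) stop("a channel basis needs k >= 2 channels")
  if (exponent < 1) stop("exponent must be >= 1")
  if (!period %in% c(180, 360)) stop("period must be 180 or 360 degrees")
  structure(list(k = as.integer(k),
                 centers = (seq_len(k) - 1) * period / k,
                 period = period,
                 exponent = exponent),
            class = "channel_basis")
}

#' Evaluate channel responses to features
#'
#' @param basis a `channel_basis`.
#' @param theta feature values in degrees.
#' @param shift optional rigid shift (degrees) applied to all channel
#'   centers, used by the 1-degree shifting loop that builds smooth CTFs.
#' @return `k x length(theta)` matrix of channel responses in `[0, 1]`.
#' @export
basis_response <- function(basis, theta, shift = 0) {
  centers <- basis$centers + shift
  d <- wrap_signed(outer(centers, theta, function(c, t) t - c),
                   period = basis$period)
  resp <- cos(pi * d / basis$period)
  resp[resp < 0] <- 0
  resp ^ basis$exponent
}

#' Map location indices to angles on the 360-degree circle
#' @param loc integer location indices (1-based).
#' @param n_locations number of locations.
#' @return angles in degrees, `(loc - 1) * 360 / n_locations`.
#' @export
location_angle <- function(loc, n_locations) {
  (loc - 1) * 360 / n_locations
}
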