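#' Circular helpers
#'
#' Small circular-statistics utilities used throughout the package. Track
#' positions live on a circle of circumference `track_length` (cm); phases
#' live on a circle of 360 degrees.
#'
#' @name circular-helpers
#' @keywords internal
NULL

#' Wrap positions onto the half-open track interval
#'
#' @param x positions in cm (any real values).
#' @param track_length circumference of the circular track in cm.
#' @return positions in `[0, track_length)`.
#' @export
wrap_position <- function(x, track_length) {
  x %% track_length
}

#' Circular distance along the track
#'
#' Shortest distance between two track positions, measured along the circle.
#'
#' @param a,b positions in cm.
#' @param track_length circumference in cm.
#' @return distances in `[0, track_length / 2]`.
#' @export
circ_track_dist <- function(a, b, track_length) {
  d <- abs(a - b) %% track_length
  pmin(d, track_length - d)
}

#' Signed circular difference a - b along the track
#'
#' @inheritParams circ_track_dist
#' @return signed differences in `(-track_length/2, track_length/2]`.
#' @keywords internal
circ_track_diff <- function(a, b, track_length) {
  d <- (a - b) %% track_length
  ifelse(d > track_length / 2, d - track_length, d)
}

#' Circular mean of angles in degrees
#'
#' @param deg angles in degrees.
#' @param w optional non-negative weights.
#' @return mean angle in `[0, 360)` degrees, or `NA` if the resultant is 0.
#' @export
circ_mean_deg <- function(deg, w = NULL) {
  rad <- deg * pi / 180
  if (is.null(w)) w <- rep(1, length(rad))
  s <- sum(w * sin(rad))
  c_ <- sum(w * cos(rad))
  if (s == 0 && c_ == 0) return(NA_real_)
  (atan2(s, c_) * 180 / pi) %% 360
}

#' Mean resultant length of angles in degrees
#'
#' @param deg angles in degrees.
#' @return resultant length in `[0, 1]`.
#' @export
circ_r <- function(deg) {
  rad <- deg * pi / 180
  sqrt(mean(cos(rad))^2 + mean(sin(rad))^2)
}

#' Circular variance (1 - resultant length)
#'
#' @param deg angles in degrees.
#' @return circular variance in `[0, 1]`.
#' @export
circ_var <- function(deg) {
  1 - circ_r(deg)
}

#' Signed angular difference a - b in degrees
#'
#' @param a,b angles in degrees.
#' @return signed difference in `(-180, 180]`.
#' @keywords internal
circ_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Circular (rate-weighted) mean position on the track
#'
#' @param pos positions in cm.
#' @param w non-negative weights (e.g. firing rates).
#' @param track_length circumference in cm.
#' @return mean position in `[0, track_length)` cm.
#' @export
circ_mean_position <- function(pos, w, track_length) {
  ang <- pos / track_length * 2 * pi
  s <- sum(w * sin(ang))
  c_ <- sum(w * cos(ang))
  if (s == 0 && c_ == 0) return(NA_real_)
  (atan2(s, c_) / (2 * pi) * track_length) %% track_length
}
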