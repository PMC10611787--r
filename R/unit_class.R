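#' Spike-train autocorrelogram
#'
#' Counts of spike-pair lags at 1 ms resolution over +/- `window_ms`,
#' excluding zero-lag self pairs. Lag bin `b` covers `(b - 0.5, b + 0.5]` ms.
#'
#' @param spikes strictly increasing spike times in seconds.
#' @param bin_ms bin width in ms.
#' @param window_ms half-window in ms.
#' @return data.frame with `lag_ms` (bin centers, negative to positive) and
#'   `count`.
#' @export
autocorrelogram <- function(spikes, bin_ms = 1, window_ms = 100) {
  cross_correlogram(spikes, spikes, window_ms = window_ms, bin_ms = bin_ms,
                    drop_zero_self = TRUE)
}

#' Burst index of a unit
#'
#' Ratio of the mean autocorrelogram counts in the (3, 20] ms lag window to
#' the mean counts in the (20, 100] ms window (1 ms bins, symmetric lags
#' pooled). High values indicate bursty, pyramidal-like firing; a flat
#' (Poisson) autocorrelogram gives a value near 1.
#'
#' @param spikes spike times in seconds.
#' @param min_spikes minimum number of spikes required; below this the index
#'   is undefined (`NA`) and the unit stays unclassified.
#' @return a non-negative ratio, or `NA` if undefined (too few spikes, or an
#'   empty 20-100 ms window).
#' @export
burst_index <- function(spikes, min_spikes = 100) {
  if (length(spikes) < min_spikes) return(NA_real_)
  acg <- autocorrelogram(spikes, bin_ms = 1, window_ms = 100)
  lag <- abs(acg$lag_ms)
  num <- mean(acg$count[lag > 3 & lag <= 20])
  den <- mean(acg$count[lag > 20 & lag <= 100])
  if (!is.finite(den) || den == 0) return(NA_real_)
  num / den
}

#' Classify a unit from waveform width and burst index
#'
#' Putative interneuron: spike width at half maximum below 0.3 ms and burst
#' index below 2. Putative pyramidal cell: width above 0.3 ms and burst
#' index above 2. Everything else (including exact boundary values and
#' undefined inputs) is `unclassified` and excluded from downstream group
#' analyses.
#'
#' @param half_width_ms spike width at half maximum, ms.
#' @param burst_index burst index from [burst_index()].
#' @return `"interneuron"`, `"pyramidal"` or `"unclassified"` (vectorized).
#' @export
classify_unit <- function(half_width_ms, burst_index) {
  out <- rep("unclassified", length(half_width_ms))
  ok <- is.finite(half_width_ms) & is.finite(burst_index)
  out[ok & half_width_ms < 0.3 & burst_index < 2] <- "interneuron"
  out[ok & half_width_ms > 0.3 & burst_index > 2] <- "pyramidal"
  out
}

#' Depth offset of a unit relative to the ripple-power maximum
#'
#' Signed distance (micrometres; negative = deep) between the unit's
#' maximal-amplitude channel and the channel with maximal ripple-band power.
#'
#' @param unit_peak_channel channel name (or index) of the unit's maximal
#'   spike amplitude.
#' @param ripple_power_by_channel named numeric vector of ripple-band power
#'   per channel.
#' @param channel_depths named numeric vector, micrometre position per
#'   channel (larger = more superficial). `NULL` if geometry is unknown.
#' @return signed offset in micrometres, or `NA` when geometry is missing.
#' @export
depth_offset <- function(unit_peak_channel, ripple_power_by_channel,
                         channel_depths = NULL) {
  if (is.null(channel_depths)) return(NA_real_)
  ch <- as.character(unit_peak_channel)
  ref <- names(ripple_power_by_channel)[which.max(ripple_power_by_channel)]
  if (!(ch %in% names(channel_depths)) || !(ref %in% names(channel_depths))) {
    return(NA_real_)
  }
  unname(channel_depths[ch] - channel_depths[ref])
}

#' Classify all units of a session
#'
#' Computes the burst index per unit and combines it with the per-unit
#' half-width metadata carried by the session.
#'
#' @param s an `ephys_session` whose `unit_meta` has columns `unit_id` and
#'   `half_width_ms`.
#' @param min_spikes minimum spike count for a defined burst index.
#' @return data.frame (`unit_table`): `unit_id`, `class`, `burst_index`,
#'   `half_width_ms`, `n_spikes`.
#' @export
classify_units <- function(s, min_spikes = 100) {
  ids <- names(s$spike_trains)
  bi <- vapply(s$spike_trains, burst_index, numeric(1),
               min_spikes = min_spikes)
  hw <- rep(NA_real_, length(ids))
  if (!is.null(s$unit_meta)) {
    hw <- s$unit_meta$half_width_ms[match(ids, s$unit_meta$unit_id)]
  }
  data.frame(unit_id = ids,
             class = classify_unit(hw, bi),
             burst_index = unname(bi),
             half_width_ms = hw,
             n_spikes = unname(vapply(s$spike_trains, length, integer(1))),
             row.names = NULL)
}
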