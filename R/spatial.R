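#' Occupancy-normalized spatial tuning curve
#'
#' Bins the track into 2 cm bins (95 bins on the default 190 cm track,
#' circular, half-open `[lo, hi)` edges) and computes the movement-filtered
#' firing rate per bin: spikes and occupancy are both restricted to samples
#' with speed at or above `speed_min` and, optionally, to a lap range.
#'
#' @param spikes spike times (s).
#' @param behavior a behavior trace.
#' @param track_length track circumference (cm).
#' @param lap_range optional `c(first, last)` inclusive lap filter.
#' @param speed_min movement filter in cm/s (applied to both numerator and
#'   denominator).
#' @param bin_cm spatial bin width (cm).
#' @return list of class `tuning_curve`: `bin_edges`, `centers` (cm),
#'   `occupancy_s` (time per bin), `p` (occupancy probability, sums to 1),
#'   `rate` (Hz; `NA` for zero-occupancy bins), `mean_rate` (Hz),
#'   `n_spikes`, `track_length`, `bin_cm`.
#' @export
tuning_curve <- function(spikes, behavior, track_length = 190,
                         lap_range = NULL, speed_min = 2, bin_cm = 2) {
  n_bins <- as.integer(round(track_length / bin_cm))
  stopifnot(abs(n_bins * bin_cm - track_length) < 1e-9)
  dt <- stats::median(diff(behavior$time))
  sel <- behavior$speed >= speed_min
  if (!is.null(lap_range)) {
    sel <- sel & behavior$lap >= lap_range[1] & behavior$lap <= lap_range[2]
  }
  bsel <- behavior[sel, , drop = FALSE]
  occ_counts <- tabulate(pmin(floor(bsel$position / bin_cm) + 1, n_bins),
                         nbins = n_bins)
  occupancy <- occ_counts * dt
  stub <- list(behavior = behavior, track_length = track_length)
  keep <- speed_at_time(stub, spikes) >= speed_min
  if (!is.null(lap_range)) {
    lp <- lap_at_time(behavior, spikes)
    keep <- keep & !is.na(lp) & lp >= lap_range[1] & lp <= lap_range[2]
  }
  sp <- spikes[keep]
  pos <- position_at_time(stub, sp)
  cnt <- tabulate(pmin(floor(pos / bin_cm) + 1, n_bins), nbins = n_bins)
  rate <- ifelse(occupancy > 0, cnt / occupancy, NA_real_)
  p <- if (sum(occupancy) > 0) occupancy / sum(occupancy) else
    rep(NA_real_, n_bins)
  mean_rate <- sum(p[occupancy > 0] * rate[occupancy > 0])
  structure(list(bin_edges = seq(0, track_length, by = bin_cm),
                 centers = seq(bin_cm / 2, track_length - bin_cm / 2,
                               by = bin_cm),
                 occupancy_s = occupancy, p = p, rate = rate,
                 mean_rate = mean_rate, n_spikes = length(sp),
                 track_length = track_length, bin_cm = bin_cm),
            class = "tuning_curve")
}

#' Detect place fields on a non-smoothed tuning curve
#'
#' A place field is a continuous (circular, wrap-aware) run of at least
#' `min_bins` bins whose rate exceeds `threshold_frac` of the unit's peak
#' rate; the field limits are the threshold-crossing bins, and multiple
#' disjoint runs yield multiple fields. A curve that is suprathreshold on
#' every occupied bin has no spatial specificity and is rejected (zero
#' fields, `non_specific` attribute set).
#'
#' @param tc a [tuning_curve()].
#' @param threshold_frac field threshold as a fraction of the peak rate.
#' @param min_bins minimal field extent in bins (3 bins = 6 cm).
#' @return data.frame with one row per field: `start_bin`, `end_bin`
#'   (1-based, inclusive; `start_bin > end_bin` marks a wrap across 0 cm),
#'   `n_bins`, `peak_hz`, `center_cm` (rate-weighted circular mean),
#'   `width_cm`. Attribute `non_specific` flags the rejected uniform case.
#' @export
detect_place_fields <- function(tc, threshold_frac = 0.05, min_bins = 3) {
  empty <- data.frame(start_bin = integer(), end_bin = integer(),
                      n_bins = integer(), peak_hz = numeric(),
                      center_cm = numeric(), width_cm = numeric())
  rate <- tc$rate
  occ <- !is.na(rate)
  if (!any(occ) || max(rate[occ]) <= 0) return(empty)
  peak <- max(rate[occ])
  supra <- !is.na(rate) & rate > threshold_frac * peak
  n <- length(rate)
  if (all(supra[occ]) && sum(occ) == n) {
    attr(empty, "non_specific") <- TRUE
    return(empty)
  }
  if (!any(!supra)) {
    attr(empty, "non_specific") <- TRUE
    return(empty)
  }
  # rotate so the sequence starts on a sub-threshold bin, then take runs
  k <- which(!supra)[1]
  ord <- c(k:n, if (k > 1) 1:(k - 1))
  r <- rle(supra[ord])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fields <- lapply(which(r$values & r$lengths >= min_bins), function(j) {
    bins <- ord[starts[j]:ends[j]]
    w <- rate[bins]
    data.frame(start_bin = bins[1], end_bin = bins[length(bins)],
               n_bins = length(bins), peak_hz = max(w),
               center_cm = circ_mean_position(tc$centers[bins], w,
                                              tc$track_length),
               width_cm = length(bins) * tc$bin_cm)
  })
  if (!length(fields)) return(empty)
  out <- do.call(rbind, fields)
  out[order(-out$peak_hz), , drop = FALSE]
}

# bins covered by a (possibly wrapping) field, 1-based
field_bins <- function(field, n_bins) {
  if (field$start_bin <= field$end_bin) {
    field$start_bin:field$end_bin
  } else {
    c(field$start_bin:n_bins, 1:field$end_bin)
  }
}

#' Split-half stability of a tuning curve
#'
#' Divides an epoch's laps into two halves, computes the non-smoothed
#' tuning curve of each half and their Pearson correlation over bins
#' occupied in both halves, with a two-sided correlation t-test. A unit is
#' stable in the epoch iff the correlation is significant at `alpha` and
#' at least `r_min`.
#'
#' @param spikes spike times (s).
#' @param behavior behavior trace.
#' @param track_length cm.
#' @param lap_range inclusive `c(first, last)` laps of the epoch.
#' @param speed_min movement filter (cm/s).
#' @param r_min minimal acceptable correlation.
#' @param alpha significance level of the correlation test.
#' @return list: `R`, `p`, `stable` (FALSE when undefined, e.g. a silent
#'   half).
#' @export
field_stability <- function(spikes, behavior, track_length = 190,
                            lap_range, speed_min = 2, r_min = 0.3,
                            alpha = 0.05) {
  laps <- lap_range[1]:lap_range[2]
  half <- floor(length(laps) / 2)
  if (half < 1) return(list(R = NA_real_, p = NA_real_, stable = FALSE))
  tc1 <- tuning_curve(spikes, behavior, track_length,
                      c(laps[1], laps[half]), speed_min)
  tc2 <- tuning_curve(spikes, behavior, track_length,
                      c(laps[half + 1], laps[length(laps)]), speed_min)
  ok <- !is.na(tc1$rate) & !is.na(tc2$rate)
  if (sum(ok) < 10 || stats::sd(tc1$rate[ok]) == 0 ||
      stats::sd(tc2$rate[ok]) == 0) {
    return(list(R = NA_real_, p = NA_real_, stable = FALSE))
  }
  ct <- stats::cor.test(tc1$rate[ok], tc2$rate[ok])
  list(R = unname(ct$estimate), p = ct$p.value,
       stable = is.finite(ct$estimate) && ct$estimate >= r_min &&
         ct$p.value < alpha)
}

#' Spatial information of a tuning curve (bits/spike)
#'
#' `sum over bins of p_i (F_i / F) log2(F_i / F)` where `p_i` is the
#' occupancy probability, `F_i` the rate in bin i, and `F` the overall mean
#' rate; bins with zero rate contribute zero (the integrand's limit).
#'
#' @param tc a [tuning_curve()], or any list with elements `p`, `rate` and
#'   `mean_rate`.
#' @return bits per spike (non-negative), or `NA` when the mean rate is 0.
#' @export
spatial_information <- function(tc) {
  ok <- !is.na(tc$rate) & !is.na(tc$p)
  f <- tc$rate[ok]
  p <- tc$p[ok]
  F_ <- tc$mean_rate
  if (!is.finite(F_) || F_ <= 0) return(NA_real_)
  pos <- f > 0
  sum(p[pos] * (f[pos] / F_) * log2(f[pos] / F_))
}

#' Pearson correlation between two place maps
#'
#' @param tc_a,tc_b tuning curves on the same bin grid.
#' @return Pearson r over bins occupied in both maps, or `NA` when fewer
#'   than 10 common bins exist.
#' @export
map_correlation <- function(tc_a, tc_b) {
  stopifnot(length(tc_a$rate) == length(tc_b$rate))
  ok <- !is.na(tc_a$rate) & !is.na(tc_b$rate)
  if (sum(ok) < 10) return(NA_real_)
  if (stats::sd(tc_a$rate[ok]) == 0 || stats::sd(tc_b$rate[ok]) == 0) {
    return(NA_real_)
  }
  stats::cor(tc_a$rate[ok], tc_b$rate[ok])
}

#' In-field versus out-of-field stimulus response
#'
#' Splits air-puff onsets by whether the puff's track location falls inside
#' any of the unit's place fields (half-open bin convention: a location on a
#' field's boundary bin counts as in-field) and z-scores the two
#' peri-stimulus histograms separately.
#'
#' @param spikes spike times (s).
#' @param events event log.
#' @param fields data.frame from [detect_place_fields()].
#' @param tc the tuning curve the fields came from (for the bin grid).
#' @param window_s averaging window after onset (s) for the reported mean z.
#' @return list: `z_infield`, `z_outfield` (mean z over `(0, window_s]`;
#'   `NA` when that side has no puffs), `n_infield`, `n_outfield`.
#' @export
infield_outfield_response <- function(spikes, events, fields, tc,
                                      window_s = 1) {
  ap <- events[events$event_type == "air_puff" &
                 !is.na(events$track_location), , drop = FALSE]
  n_bins <- length(tc$rate)
  loc_bin <- pmin(floor(ap$track_location / tc$bin_cm) + 1L, n_bins)
  infield_bins <- unique(unlist(lapply(seq_len(nrow(fields)), function(i) {
    field_bins(fields[i, ], n_bins)
  })))
  infield <- loc_bin %in% infield_bins
  mean_post_z <- function(onsets) {
    if (!length(onsets)) return(NA_real_)
    r <- peri_event_zscore(spikes, onsets)
    if (r$flat_baseline) return(NA_real_)
    mean(r$zscore[r$bin_start >= 0 & r$bin_start < window_s])
  }
  list(z_infield = mean_post_z(ap$onset[infield]),
       z_outfield = mean_post_z(ap$onset[!infield]),
       n_infield = sum(infield), n_outfield = sum(!infield))
}

#' Place-field shift relative to the stimulus location
#'
#' Compares a unit's dominant field before and after the stimulation epochs:
#' circular distances from the field centers to the air-puff location, and a
#' category — `stable` (center moved at most `stable_shift_cm`), `remapped`,
#' `vanished` (field only before) or `emerged` (field only after).
#'
#' @param fields_pre,fields_post field tables from [detect_place_fields()]
#'   for the pre and post no-stimulation epochs (dominant field = highest
#'   peak).
#' @param ap_location air-puff location (cm).
#' @param track_length cm.
#' @param stable_shift_cm maximal center shift still counted stable (2 bins).
#' @return list: `d_pre`, `d_post` (cm, in `[0, track_length/2]`; `NA` for a
#'   missing side), `shift_cm`, `category`.
#' @export
field_shift <- function(fields_pre, fields_post, ap_location,
                        track_length = 190, stable_shift_cm = 4) {
  has_pre <- nrow(fields_pre) > 0
  has_post <- nrow(fields_post) > 0
  c_pre <- if (has_pre) fields_pre$center_cm[1] else NA_real_
  c_post <- if (has_post) fields_post$center_cm[1] else NA_real_
  d_pre <- if (has_pre) circ_track_dist(c_pre, ap_location, track_length)
    else NA_real_
  d_post <- if (has_post) circ_track_dist(c_post, ap_location, track_length)
    else NA_real_
  shift <- if (has_pre && has_post)
    circ_track_dist(c_pre, c_post, track_length) else NA_real_
  category <- if (has_pre && has_post) {
    if (shift <= stable_shift_cm) "stable" else "remapped"
  } else if (has_pre) "vanished" else if (has_post) "emerged" else "absent"
  list(d_pre = d_pre, d_post = d_post, shift_cm = shift, category = category)
}

#' Place-cell flags for all units of a session
#'
#' A pyramidal-style place cell must have at least one place field on its
#' overall no-stimulation tuning curve and a significant, at least
#' `r_min` split-half correlation in every no-stimulation epoch.
#'
#' @param s an `ephys_session`.
#' @param plan optional [split_epochs()] result (computed when NULL).
#' @param speed_min movement filter (cm/s).
#' @param r_min stability threshold.
#' @return named logical vector over units.
#' @export
place_cell_flags <- function(s, plan = NULL, speed_min = 2, r_min = 0.3) {
  if (is.null(plan)) plan <- split_epochs(s$events, s$behavior)
  ns <- plan[plan$label == "no_stim", , drop = FALSE]
  ns <- ns[ns$lap_end - ns$lap_start >= 1, , drop = FALSE]
  out <- logical(length(s$spike_trains))
  names(out) <- names(s$spike_trains)
  for (uid in names(s$spike_trains)) {
    sp <- s$spike_trains[[uid]]
    stable_all <- nrow(ns) > 0
    any_field <- FALSE
    for (i in seq_len(nrow(ns))) {
      st <- field_stability(sp, s$behavior, s$track_length,
                            c(ns$lap_start[i], ns$lap_end[i]),
                            speed_min = speed_min, r_min = r_min)
      if (!isTRUE(st$stable)) { stable_all <- FALSE; break }
    }
    if (stable_all) {
      # fields assessed on the no-stimulation laps only
      ns_laps <- unlist(lapply(seq_len(nrow(ns)),
                               function(i) ns$lap_start[i]:ns$lap_end[i]))
      tc <- tuning_curve_laps(sp, s, ns_laps, speed_min)
      any_field <- nrow(detect_place_fields(tc)) > 0
    }
    out[uid] <- stable_all && any_field
  }
  out
}

#' Tuning curve restricted to an arbitrary lap set
#'
#' @param spikes spike times (s).
#' @param s an `ephys_session`.
#' @param laps integer vector of lap indices to include.
#' @param speed_min movement filter (cm/s).
#' @param bin_cm bin width (cm).
#' @return a [tuning_curve()].
#' @export
tuning_curve_laps <- function(spikes, s, laps, speed_min = 2, bin_cm = 2) {
  b <- s$behavior
  n_bins <- as.integer(round(s$track_length / bin_cm))
  dt <- stats::median(diff(b$time))
  sel <- b$speed >= speed_min & b$lap %in% laps
  occupancy <- tabulate(pmin(floor(b$position[sel] / bin_cm) + 1, n_bins),
                        nbins = n_bins) * dt
  lp <- lap_at_time(b, spikes)
  keep <- speed_at_time(s, spikes) >= speed_min & !is.na(lp) & lp %in% laps
  pos <- position_at_time(s, spikes[keep])
  cnt <- tabulate(pmin(floor(pos / bin_cm) + 1, n_bins), nbins = n_bins)
  rate <- ifelse(occupancy > 0, cnt / occupancy, NA_real_)
  p <- if (sum(occupancy) > 0) occupancy / sum(occupancy) else
    rep(NA_real_, n_bins)
  mean_rate <- sum(p[occupancy > 0] * rate[occupancy > 0])
  structure(list(bin_edges = seq(0, s$track_length, by = bin_cm),
                 centers = seq(bin_cm / 2, s$track_length - bin_cm / 2,
                               by = bin_cm),
                 occupancy_s = occupancy, p = p, rate = rate,
                 mean_rate = mean_rate, n_spikes = sum(keep),
                 track_length = s$track_length, bin_cm = bin_cm),
            class = "tuning_curve")
}
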