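#' Peri-event z-scored response of one unit
#'
#' Builds the trial-averaged peri-stimulus time histogram (PSTH) in 20 ms
#' bins over a [-4, +4] s window around event onsets and z-scores it against
#' the baseline bins in [-4, 0) s (mean and SD taken across baseline bins of
#' the trial-averaged PSTH).
#'
#' @param spikes spike times in seconds.
#' @param onsets event onset times in seconds (each at least `-window[1]` s
#'   after session start).
#' @param bin_s PSTH bin width in seconds.
#' @param window c(pre, post) window in seconds around onsets.
#' @param sd_floor baselines with SD below this (Hz) are treated as flat:
#'   the z-score is undefined and the response class is forced to `none`.
#' @return list of class `peri_event_response`: `bin_start` (s, left edges),
#'   `rate` (trial-averaged Hz), `zscore`, `baseline_mean`, `baseline_sd`
#'   (Hz), `n_trials`, `flat_baseline` flag.
#' @export
peri_event_zscore <- function(spikes, onsets, bin_s = 0.02,
                              window = c(-4, 4), sd_floor = 1e-6) {
  stopifnot(length(onsets) >= 1)
  edges <- seq(window[1], window[2], by = bin_s)
  starts <- edges[-length(edges)]
  rel_all <- unlist(lapply(onsets, function(on) {
    spikes[spikes >= on + window[1] & spikes < on + window[2]] - on
  }))
  counts <- if (length(rel_all)) {
    tabulate(floor((rel_all - window[1]) / bin_s + 1e-9) + 1,
             nbins = length(starts))
  } else numeric(length(starts))
  rate <- counts / (length(onsets) * bin_s)
  base <- starts < -1e-12  # baseline bins lie fully before onset
  bm <- mean(rate[base])
  bs <- stats::sd(rate[base])
  flat <- !is.finite(bs) || bs < sd_floor
  z <- if (flat) rep(NA_real_, length(rate)) else (rate - bm) / bs
  structure(list(bin_start = starts, bin_s = bin_s, rate = rate, zscore = z,
                 baseline_mean = bm, baseline_sd = bs,
                 n_trials = length(onsets), flat_baseline = flat),
            class = "peri_event_response")
}

# first index where `x` holds a run of at least `len` TRUEs; NA if none
first_run_start <- function(x, len) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= len)
  if (!length(hit)) return(NA_integer_)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

# post-stimulus bin selector: bins inside (0, post_window] s
post_bins <- function(resp, post_window = 3) {
  resp$bin_start >= 0 & resp$bin_start < post_window
}

# significant-response window within the post-stimulus bins: anchored on the
# first detection run (z > 2 for >= det_bins, or z < -1 for suppression),
# extended backward through the contiguous z > 1 (z < -1) stretch and
# forward until the z-score returns across 1 (-1) for >= 2 consecutive bins.
# Returns indices into the post-bin vector, or NULL when no run exists.
response_window <- function(resp, direction, det_bins, post_window = 3) {
  z <- resp$zscore[post_bins(resp, post_window)]
  if (direction == "activated") {
    det <- z > 2
    soft <- z > 1
  } else {
    det <- z < -1
    soft <- z < -1
  }
  anchor <- first_run_start(det, det_bins)
  if (is.na(anchor)) return(NULL)
  start <- anchor
  while (start > 1 && isTRUE(soft[start - 1])) start <- start - 1
  soft[is.na(soft)] <- FALSE
  term <- first_run_start(!soft[anchor:length(soft)], 2)
  end <- if (is.na(term)) length(soft) else anchor + term - 2L
  list(start = start, end = end)
}

# does one location's z trace satisfy the activation criterion?
location_activated <- function(resp, z_thresh = 2, min_bins = 3,
                               post_window = 3) {
  if (resp$flat_baseline) return(FALSE)
  zp <- resp$zscore[post_bins(resp, post_window)]
  !is.na(first_run_start(zp > z_thresh, min_bins))
}

# does one location's z trace satisfy the suppression criterion?
location_suppressed <- function(resp, z_thresh = -1, min_bins = 10,
                                post_window = 3) {
  if (resp$flat_baseline) return(FALSE)
  zp <- resp$zscore[post_bins(resp, post_window)]
  !is.na(first_run_start(zp < z_thresh, min_bins))
}

# minimum positive locations required for a consistent response:
# 2 of 2, 2 of 3, 3 of 4 (n - 1 of n beyond that)
required_locations <- function(n_locations) {
  if (n_locations <= 1) return(1L)
  if (n_locations == 2) return(2L)
  as.integer(n_locations - 1)
}

#' Detect stimulus-locked activation across locations
#'
#' A location is positive iff the z-scored PSTH exceeds 2 continuously for
#' at least 50 ms (3 consecutive 20 ms bins) within (0, 3] s after onset;
#' the unit counts as activated iff enough locations are positive (2 of 2,
#' 2 of 3, 3 of 4).
#'
#' @param resp_by_location list of [peri_event_zscore()] results, one per
#'   stimulus location.
#' @param z_thresh activation threshold in z units.
#' @param min_bins minimal run length in bins.
#' @param post_window response search window in seconds after onset.
#' @return list: `activated` flag, `positive_locations` logical vector,
#'   `n_required`, `single_location` flag.
#' @export
detect_activation <- function(resp_by_location, z_thresh = 2, min_bins = 3,
                              post_window = 3) {
  pos <- vapply(resp_by_location, location_activated, logical(1),
                z_thresh = z_thresh, min_bins = min_bins,
                post_window = post_window)
  n_req <- required_locations(length(pos))
  list(activated = sum(pos) >= n_req, positive_locations = pos,
       n_required = n_req, single_location = length(pos) < 2)
}

#' Detect stimulus-locked suppression across locations
#'
#' A location is positive iff the z-scored PSTH drops below -1 continuously
#' for at least `min_bins` 20 ms bins (default 10 bins = 200 ms) within
#' (0, 3] s; the same per-location consistency rule as for activation is
#' applied.
#'
#' @inheritParams detect_activation
#' @param z_thresh suppression threshold in z units.
#' @return list: `suppressed` flag, `positive_locations`, `n_required`,
#'   `single_location`.
#' @export
detect_suppression <- function(resp_by_location, z_thresh = -1,
                               min_bins = 10, post_window = 3) {
  pos <- vapply(resp_by_location, location_suppressed, logical(1),
                z_thresh = z_thresh, min_bins = min_bins,
                post_window = post_window)
  n_req <- required_locations(length(pos))
  list(suppressed = sum(pos) >= n_req, positive_locations = pos,
       n_required = n_req, single_location = length(pos) < 2)
}

#' Response latency from the starting bin's first spikes
#'
#' The starting bin is the first 20 ms bin of the detected response: the
#' contiguous stretch with z above 1 (activation) or below -1 (suppression)
#' that contains the detection run, so an isolated noise bin before the
#' response cannot anchor the latency. For activation the
#' latency is the mean over trials of the first spike time inside that bin
#' relative to onset (trials without a spike in the bin are excluded); for
#' suppression, and as the flagged fallback when no trial has a spike in the
#' starting bin, the bin's start time is used.
#'
#' @param resp pooled [peri_event_zscore()] result.
#' @param spikes the unit's spike times (s).
#' @param onsets all event onsets (s).
#' @param direction `"activated"` or `"suppressed"`.
#' @param post_window search window (s).
#' @return list: `latency_s`, `start_bin_time` (s), `fallback` flag (`TRUE`
#'   when the bin-start fallback was used).
#' @export
response_latency <- function(resp, spikes, onsets,
                             direction = c("activated", "suppressed"),
                             post_window = 3, det_bins = NULL) {
  direction <- match.arg(direction)
  if (is.null(det_bins)) det_bins <- if (direction == "activated") 3L else 10L
  pb <- which(post_bins(resp, post_window))
  win <- response_window(resp, direction, det_bins, post_window)
  if (is.null(win)) return(list(latency_s = NA_real_,
                                start_bin_time = NA_real_,
                                fallback = TRUE))
  t0 <- resp$bin_start[pb[win$start]]
  if (direction == "suppressed") {
    return(list(latency_s = t0, start_bin_time = t0, fallback = FALSE))
  }
  firsts <- vapply(onsets, function(on) {
    sp <- spikes[spikes >= on + t0 & spikes < on + t0 + resp$bin_s]
    if (length(sp)) sp[1] - on else NA_real_
  }, numeric(1))
  firsts <- firsts[!is.na(firsts)]
  if (!length(firsts)) {
    return(list(latency_s = t0, start_bin_time = t0, fallback = TRUE))
  }
  list(latency_s = mean(firsts), start_bin_time = t0, fallback = FALSE)
}

#' Response duration from the starting bin until sustained threshold return
#'
#' Starting at the first bin with z above 1 (activation) or below -1
#' (suppression), the response runs until the z-score first returns across
#' the threshold (|z| below 1) for at least 2 consecutive bins; the duration
#' is the bin span from the starting bin through the last bin before that
#' return.
#'
#' @inheritParams response_latency
#' @return duration in seconds, or `NA` when no starting bin exists.
#' @export
response_duration <- function(resp, direction = c("activated", "suppressed"),
                              post_window = 3, det_bins = NULL) {
  direction <- match.arg(direction)
  if (is.null(det_bins)) det_bins <- if (direction == "activated") 3L else 10L
  win <- response_window(resp, direction, det_bins, post_window)
  if (is.null(win)) return(NA_real_)
  (win$end - win$start + 1) * resp$bin_s
}

#' Full event-response characterization of one unit
#'
#' Runs the z-scoring, per-location activation/suppression detection,
#' latency, duration and magnitude extraction for one unit against one event
#' type, pooling all locations for the response time course.
#'
#' @param spikes spike times (s).
#' @param events an event log (only rows of `event_type` are used).
#' @param event_type which events to analyze.
#' @param post_window response window (s).
#' @param suppression_min_bins minimal suppression run (20 ms bins).
#' @return list of class `event_response`: `class` (`activated`,
#'   `suppressed`, `biphasic`, `none`), `latency_s`, `duration_s`,
#'   `magnitude_z` (mean z over the significant window), `n_locations`,
#'   `n_positive_locations`, `flags`, `pooled` (the pooled
#'   `peri_event_response`), `by_location`.
#' @export
detect_event_response <- function(spikes, events, event_type = "air_puff",
                                  post_window = 3,
                                  suppression_min_bins = 10) {
  ev <- events[events$event_type == event_type, , drop = FALSE]
  if (!nrow(ev)) stop("no events of type ", event_type)
  locs <- unique(ev$track_location)
  by_loc <- lapply(locs, function(l) {
    sel <- if (is.na(l)) is.na(ev$track_location) else
      !is.na(ev$track_location) & ev$track_location == l
    peri_event_zscore(spikes, ev$onset[sel])
  })
  pooled <- peri_event_zscore(spikes, ev$onset)
  flags <- character()
  if (pooled$flat_baseline) flags <- c(flags, "flat-baseline")
  act <- detect_activation(by_loc, post_window = post_window)
  sup <- detect_suppression(by_loc, min_bins = suppression_min_bins,
                            post_window = post_window)
  if (act$single_location) flags <- c(flags, "single-location")
  # the unit's overall (all-trial) response must itself pass the criterion;
  # the per-location rule is a consistency requirement on top of it
  act$activated <- act$activated && location_activated(pooled,
                                                       post_window = post_window)
  sup$suppressed <- sup$suppressed &&
    location_suppressed(pooled, min_bins = suppression_min_bins,
                        post_window = post_window)
  cls <- "none"
  if (act$activated && sup$suppressed) {
    pb <- which(post_bins(pooled, post_window))
    z <- pooled$zscore[pb]
    a0 <- which(z > 1)[1]
    s0 <- which(z < -1)[1]
    cls <- if (!is.na(a0) && (is.na(s0) || a0 < s0)) "biphasic" else "suppressed"
  } else if (act$activated) {
    cls <- "activated"
  } else if (sup$suppressed) {
    cls <- "suppressed"
  }
  latency <- NA_real_
  duration <- NA_real_
  magnitude <- NA_real_
  if (cls != "none") {
    dir <- if (cls == "suppressed") "suppressed" else "activated"
    db <- if (dir == "suppressed") suppression_min_bins else 3L
    lat <- response_latency(pooled, spikes, ev$onset, direction = dir,
                            post_window = post_window, det_bins = db)
    if (lat$fallback) flags <- c(flags, "latency-fallback")
    latency <- lat$latency_s
    duration <- response_duration(pooled, direction = dir,
                                  post_window = post_window, det_bins = db)
    if (!is.na(lat$start_bin_time) && !is.na(duration)) {
      pb <- which(post_bins(pooled, post_window))
      sel <- pooled$bin_start[pb] >= lat$start_bin_time &
        pooled$bin_start[pb] < lat$start_bin_time + duration
      magnitude <- mean(pooled$zscore[pb][sel])
    }
  }
  structure(list(class = cls, latency_s = latency, duration_s = duration,
                 magnitude_z = magnitude, n_locations = length(by_loc),
                 n_positive_locations = sum(act$positive_locations),
                 n_suppressed_locations = sum(sup$positive_locations),
                 flags = flags, pooled = pooled, by_location = by_loc),
            class = "event_response")
}

#' Event responses for every unit of a session
#'
#' @param s an `ephys_session`.
#' @param event_type event type to analyze.
#' @param ... passed to [detect_event_response()].
#' @return data.frame: `unit_id`, `event_type`, `class`, `latency_s`,
#'   `duration_s`, `magnitude_z`, `n_positive_locations`, `n_locations`.
#' @export
event_responses <- function(s, event_type = "air_puff", ...) {
  rows <- lapply(names(s$spike_trains), function(uid) {
    r <- detect_event_response(s$spike_trains[[uid]], s$events,
                               event_type = event_type, ...)
    data.frame(unit_id = uid, event_type = event_type, class = r$class,
               latency_s = r$latency_s, duration_s = r$duration_s,
               magnitude_z = r$magnitude_z,
               n_positive_locations = r$n_positive_locations,
               n_locations = r$n_locations)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Composite response/cell-type nomenclature
#'
#' Combines the response class, cell class and place-cell flag into the
#' standard group labels: `aAP`/`iAP`/`nAP` (activated / inhibited /
#' non-affected by air puff) crossed with `-PC`/`-nPC` for pyramidal cells
#' (place cell / non-place cell) and `-IN` for interneurons; interneurons
#' with a biphasic response are `aiAP-IN`. Unclassified units get `NA` and
#' are excluded from group statistics.
#'
#' @param unit_table output of [classify_units()].
#' @param response_table output of [event_responses()].
#' @param place_flags named logical vector (unit_id -> is place cell), e.g.
#'   from [place_cell_flags()].
#' @return data.frame: `unit_id`, `class`, `response`, `group`.
#' @export
assign_nomenclature <- function(unit_table, response_table, place_flags) {
  m <- merge(unit_table[, c("unit_id", "class")],
             response_table[, c("unit_id", "class")],
             by = "unit_id", suffixes = c("", "_resp"))
  resp_part <- c(activated = "aAP", suppressed = "iAP", none = "nAP",
                 biphasic = "aiAP")[m$class_resp]
  group <- rep(NA_character_, nrow(m))
  ispyr <- m$class == "pyramidal"
  isint <- m$class == "interneuron"
  pc <- place_flags[m$unit_id]
  pc[is.na(pc)] <- FALSE
  # biphasic pyramidal cells are counted with the activated group
  rp <- ifelse(ispyr & resp_part == "aiAP", "aAP", resp_part)
  group[ispyr] <- paste0(rp[ispyr], ifelse(pc[ispyr], "-PC", "-nPC"))
  group[isint] <- paste0(resp_part[isint], "-IN")
  data.frame(unit_id = m$unit_id, class = m$class, response = m$class_resp,
             group = group)
}

#' Percentage of a count within a total
#'
#' @param count numerator count.
#' @param total denominator count (> 0).
#' @param digits decimal places to round to (default one decimal, the
#'   reporting convention for group fractions).
#' @return percentage, rounded.
#' @export
group_fraction <- function(count, total, digits = 1) {
  stopifnot(total > 0)
  round(100 * count / total, digits)
}

#' Paired comparison of response magnitudes across contexts
#'
#' Joins two per-unit response tables (e.g. spatial disc vs non-spatial
#' sphere contexts) on unit id and returns paired magnitudes and durations
#' with their deltas, ready for standard paired tests.
#'
#' @param resp_a,resp_b response tables from [event_responses()] for the two
#'   contexts.
#' @param labels length-2 character naming the contexts.
#' @return data.frame: `unit_id`, `magnitude_<a>`, `magnitude_<b>`,
#'   `delta_magnitude`, `duration_<a>`, `duration_<b>`, `delta_duration`.
#'   Units absent in either context are excluded (with a warning when the
#'   paired table is empty).
#' @export
context_response_compare <- function(resp_a, resp_b,
                                     labels = c("disc", "sphere")) {
  m <- merge(resp_a[, c("unit_id", "magnitude_z", "duration_s")],
             resp_b[, c("unit_id", "magnitude_z", "duration_s")],
             by = "unit_id", suffixes = paste0("_", labels))
  if (!nrow(m)) warning("no units shared between contexts; empty paired table")
  m$delta_magnitude <- m[[paste0("magnitude_z_", labels[1])]] -
    m[[paste0("magnitude_z_", labels[2])]]
  m$delta_duration <- m[[paste0("duration_s_", labels[1])]] -
    m[[paste0("duration_s_", labels[2])]]
  m
}
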