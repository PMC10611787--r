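#' Session container for one recording
#'
#' A `ephys_session` bundles everything the pipeline consumes for a single
#' recording day: sorted spike trains, the linearized behavior trace, the
#' stimulus/reward event log, an optional pyramidal-layer LFP channel and
#' context intervals (spatial disc vs non-spatial sphere).
#'
#' All times are seconds from session start; positions are cm on the
#' half-open circular interval `[0, track_length)`.
#'
#' @param session_id character scalar identifying the session.
#' @param track_length track circumference in cm (default 190).
#' @param spike_trains named list; one strictly increasing numeric vector of
#'   spike times per unit.
#' @param behavior a behavior trace as returned by [behavior_trace()].
#' @param events an event log as returned by [event_log()].
#' @param lfp optional LFP channel from [lfp_channel()].
#' @param context_intervals optional data.frame with columns `start`, `end`
#'   (s) and `context` (`"disc"` or `"sphere"`), non-overlapping and ordered.
#' @param unit_meta optional data.frame of per-unit metadata (columns
#'   `unit_id`, `half_width_ms`, optionally `peak_channel`), carried for the
#'   classification stage; waveform extraction happens upstream of this
#'   package.
#' @return an object of class `ephys_session`.
#' @export
session <- function(session_id, track_length = 190, spike_trains,
                    behavior, events, lfp = NULL,
                    context_intervals = NULL, unit_meta = NULL) {
  s <- structure(
    list(
      session_id = as.character(session_id),
      track_length = as.numeric(track_length),
      spike_trains = spike_trains,
      behavior = behavior,
      events = events,
      lfp = lfp,
      context_intervals = context_intervals,
      unit_meta = unit_meta
    ),
    class = "ephys_session"
  )
  validate_session(s)
  s
}

#' Uniformly sampled behavior trace
#'
#' @param time numeric vector, uniform sample grid in seconds.
#' @param position cm in `[0, track_length)`; wraps at the track end.
#' @param speed cm/s, non-negative and finite.
#' @param lap integer lap index, non-decreasing, incrementing at wraps.
#' @return data.frame of class `behavior_trace`.
#' @export
behavior_trace <- function(time, position, speed, lap) {
  b <- data.frame(time = time, position = position, speed = speed,
                  lap = as.integer(lap))
  class(b) <- c("behavior_trace", "data.frame")
  b
}

#' Stimulus/reward event log
#'
#' @param event_type character: one of `air_puff`, `reward`, `tail_shock`,
#'   `tone`.
#' @param onset onset time in seconds.
#' @param duration event duration in seconds.
#' @param track_location stimulus location on the track in cm, or `NA` for
#'   events without a track location.
#' @param epoch_index integer grouping consecutive same-location trials.
#' @return data.frame of class `event_log`.
#' @export
event_log <- function(event_type = character(), onset = numeric(),
                      duration = numeric(), track_location = numeric(),
                      epoch_index = integer()) {
  e <- data.frame(event_type = as.character(event_type),
                  onset = as.numeric(onset),
                  duration = as.numeric(duration),
                  track_location = as.numeric(track_location),
                  epoch_index = as.integer(epoch_index))
  class(e) <- c("event_log", "data.frame")
  e
}

#' LFP channel
#'
#' @param samples numeric voltage trace (arbitrary units); the first sample
#'   is at time 0.
#' @param sample_rate sampling rate in Hz. Ripple analysis requires at least
#'   500 Hz.
#' @param channel_depths optional named numeric map channel -> micrometre
#'   offset, used for depth localization.
#' @return list of class `lfp_channel`.
#' @export
lfp_channel <- function(samples, sample_rate, channel_depths = NULL) {
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate),
                 channel_depths = channel_depths),
            class = "lfp_channel")
}

#' Validate a session against its invariants
#'
#' Checks monotone spike trains, spike times inside the session span,
#' behavior-grid uniformity, position wrapping, lap-index consistency, event
#' onsets inside the session, and context-interval ordering. Called by
#' [session()] and [load_session()].
#'
#' @param s an `ephys_session`.
#' @return the session, invisibly; stops with an informative error otherwise.
#' @export
validate_session <- function(s) {
  stopifnot(inherits(s, "ephys_session"))
  if (!is.list(s$spike_trains) || is.null(names(s$spike_trains)) ||
      any(names(s$spike_trains) == "")) {
    stop("spike_trains must be a named list of spike-time vectors")
  }
  dur <- session_duration(s)
  for (uid in names(s$spike_trains)) {
    st <- s$spike_trains[[uid]]
    if (length(st) > 1 && any(diff(st) <= 0)) {
      stop(sprintf("spike train of unit '%s' is not strictly increasing", uid))
    }
    if (length(st) && (min(st) < 0 || max(st) > dur + 1e-9)) {
      stop(sprintf("unit '%s' has spike times outside [0, %g] s", uid, dur))
    }
  }
  b <- s$behavior
  if (!all(c("time", "position", "speed", "lap") %in% names(b))) {
    stop("behavior trace must have columns time, position, speed, lap")
  }
  if (nrow(b) >= 3) {
    dt <- diff(b$time)
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt) + 1e-12) {
      stop("behavior time grid is not uniform")
    }
  }
  if (any(!is.finite(b$speed)) || any(b$speed < 0)) {
    stop("behavior speed must be finite and non-negative")
  }
  if (any(b$position < 0 | b$position >= s$track_length)) {
    stop("behavior position must lie in [0, track_length)")
  }
  if (any(diff(b$lap) < 0)) stop("lap index must be non-decreasing")
  e <- s$events
  if (nrow(e) && (any(e$onset < 0) || any(e$onset > dur + 1e-9))) {
    stop("event onsets must lie within the session")
  }
  ci <- s$context_intervals
  if (!is.null(ci) && nrow(ci) > 1) {
    if (any(diff(ci$start) <= 0) || any(ci$end[-nrow(ci)] > ci$start[-1] + 1e-9)) {
      stop("context intervals must be ordered and non-overlapping")
    }
  }
  invisible(s)
}

#' Session duration in seconds
#'
#' The span covered by the session: the latest of behavior end, LFP end and
#' last spike.
#'
#' @param s an `ephys_session`.
#' @return duration in seconds.
#' @export
session_duration <- function(s) {
  dur <- if (nrow(s$behavior)) max(s$behavior$time) else 0
  if (!is.null(s$lfp)) {
    dur <- max(dur, (length(s$lfp$samples) - 1) / s$lfp$sample_rate)
  }
  sp <- unlist(s$spike_trains, use.names = FALSE)
  if (length(sp)) dur <- max(dur, max(sp))
  dur
}

#' Save a session to disk
#'
#' Sessions are serialized with R's native RDS format: a single portable
#' file, lossless for every numeric field (bit-exact round trips).
#' [export_session_csv()] writes the same content as plain-text tables for
#' use outside R.
#'
#' @param s an `ephys_session`.
#' @param path output file path.
#' @export
save_session <- function(s, path) {
  validate_session(s)
  saveRDS(s, path)
  invisible(path)
}

#' Load a session from disk
#'
#' Reads a file written by [save_session()] and re-validates every
#' invariant, so a corrupted container fails loudly with the offending field
#' named.
#'
#' @param path file path.
#' @return an `ephys_session`.
#' @export
load_session <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such session file: %s", path))
  s <- readRDS(path)
  if (!inherits(s, "ephys_session")) {
    stop("file does not contain an ephys_session")
  }
  required <- c("session_id", "track_length", "spike_trains", "behavior",
                "events")
  missing <- setdiff(required, names(s))
  if (length(missing)) {
    stop(sprintf("session container is missing group(s): %s",
                 paste(missing, collapse = ", ")))
  }
  validate_session(s)
  s
}

#' Export a session as plain-text tables
#'
#' Writes `spikes.csv` (unit_id, time_s), `behavior.csv`, `events.csv`,
#' `meta.json` and, when present, `lfp.csv` into a directory, for use by
#' non-R tools.
#'
#' @param s an `ephys_session`.
#' @param dir output directory (created if needed).
#' @export
export_session_csv <- function(s, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- data.frame(
    unit_id = rep(names(s$spike_trains),
                  vapply(s$spike_trains, length, integer(1))),
    time_s = unlist(s$spike_trains, use.names = FALSE)
  )
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(s$behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  utils::write.csv(s$events, file.path(dir, "events.csv"), row.names = FALSE)
  meta <- list(session_id = s$session_id, track_length = s$track_length,
               duration_s = session_duration(s))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(s$lfp)) {
    utils::write.csv(
      data.frame(sample = s$lfp$samples, sample_rate = s$lfp$sample_rate),
      file.path(dir, "lfp.csv"), row.names = FALSE
    )
  }
  invisible(dir)
}

#' Lap index at given times
#'
#' @param behavior a behavior trace.
#' @param times times in seconds.
#' @return integer lap index of the behavior sample at or immediately before
#'   each time (NA before the first sample).
#' @keywords internal
lap_at_time <- function(behavior, times) {
  idx <- findInterval(times, behavior$time)
  out <- rep(NA_integer_, length(times))
  ok <- idx >= 1
  out[ok] <- behavior$lap[idx[ok]]
  out
}

#' Track position at given times
#'
#' Linear interpolation of the behavior position, wrap-aware (interpolation
#' is done on unwrapped cumulative position).
#'
#' @param s an `ephys_session` (or list with `behavior` and `track_length`).
#' @param times times in seconds.
#' @return positions in cm in `[0, track_length)`.
#' @export
position_at_time <- function(s, times) {
  b <- s$behavior
  L <- s$track_length
  # unwrap: add a lap-worth of track for every wrap crossing
  unwrapped <- b$position + L * (b$lap - b$lap[1])
  p <- stats::approx(b$time, unwrapped, xout = times, rule = 2)$y
  p %% L
}

#' Speed at given times
#'
#' @inheritParams position_at_time
#' @return speeds in cm/s (constant extrapolation outside the trace).
#' @export
speed_at_time <- function(s, times) {
  stats::approx(s$behavior$time, s$behavior$speed, xout = times, rule = 2)$y
}

#' Partition laps into alternating no-stimulation and air-puff blocks
#'
#' A lap belongs to an air-puff block iff at least one air-puff onset falls
#' within it; consecutive laps with the same status form one block, and an
#' air-puff block must be location-contiguous (all its puffs at one track
#' location).
#'
#' @param events an event log.
#' @param behavior a behavior trace.
#' @return data.frame of class `epoch_plan` with columns `label`
#'   (`no_stim`/`air_puff`), `lap_start`, `lap_end` (inclusive) and
#'   `ap_location` (cm, `NA` for no-stim blocks). Lap ranges partition the
#'   session's laps in order.
#' @export
split_epochs <- function(events, behavior) {
  laps <- sort(unique(behavior$lap))
  ap <- events[events$event_type == "air_puff", , drop = FALSE]
  ap_lap <- if (nrow(ap)) lap_at_time(behavior, ap$onset) else integer()
  is_ap_lap <- laps %in% ap_lap
  if (!length(laps)) stop("behavior trace contains no laps")
  run_id <- cumsum(c(TRUE, diff(is_ap_lap) != 0))
  out <- do.call(rbind, lapply(split(seq_along(laps), run_id), function(ix) {
    block_laps <- laps[ix]
    if (is_ap_lap[ix[1]]) {
      locs <- unique(ap$track_location[ap_lap %in% block_laps])
      if (length(locs) != 1) {
        stop("air-puff block spanning laps ", block_laps[1], "-",
             block_laps[length(block_laps)],
             " mixes locations: ", paste(locs, collapse = ", "),
             " (blocks must be location-contiguous)")
      }
      data.frame(label = "air_puff", lap_start = block_laps[1],
                 lap_end = block_laps[length(block_laps)],
                 ap_location = locs)
    } else {
      data.frame(label = "no_stim", lap_start = block_laps[1],
                 lap_end = block_laps[length(block_laps)],
                 ap_location = NA_real_)
    }
  }))
  rownames(out) <- NULL
  class(out) <- c("epoch_plan", "data.frame")
  out
}

#' Time intervals covered by a lap range
#'
#' @param behavior a behavior trace.
#' @param lap_start,lap_end inclusive lap range.
#' @return c(start, end) in seconds: the span of behavior samples whose lap
#'   index falls in the range.
#' @keywords internal
lap_range_interval <- function(behavior, lap_start, lap_end) {
  sel <- behavior$lap >= lap_start & behavior$lap <= lap_end
  if (!any(sel)) return(c(NA_real_, NA_real_))
  range(behavior$time[sel])
}

#' @export
print.ephys_session <- function(x, ...) {
  cat(sprintf("<ephys_session '%s'>\n", x$session_id))
  cat(sprintf("  track: %g cm circular | duration: %.1f s\n",
              x$track_length, session_duration(x)))
  cat(sprintf("  units: %d | events: %d | LFP: %s\n",
              length(x$spike_trains), nrow(x$events),
              if (is.null(x$lfp)) "none" else
                sprintf("%g Hz, %d samples", x$lfp$sample_rate,
                        length(x$lfp$samples))))
  invisible(x)
}
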