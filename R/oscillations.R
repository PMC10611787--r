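#' Zero-phase Butterworth band-pass filter
#'
#' @param x signal.
#' @param fs sample rate (Hz).
#' @param band c(low, high) in Hz.
#' @param order filter order.
#' @return filtered signal (forward-backward, zero phase lag).
#' @keywords internal
bandpass_filter <- function(x, fs, band, order = 3) {
  ny <- fs / 2
  stopifnot(band[1] > 0, band[2] < ny)
  bf <- signal::butter(order, band / ny, type = "pass")
  signal::filtfilt(bf, x)
}

# FFT analytic signal (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-passed LFP, trough = 0 degrees
#'
#' Band-passes the LFP, takes the analytic (Hilbert) signal, and returns the
#' instantaneous phase under the convention that 0 degrees is the filtered
#' oscillation's trough and 180 degrees its peak.
#'
#' @param lfp an [lfp_channel()].
#' @param band frequency band in Hz (default theta, 5-12 Hz).
#' @param order Butterworth order.
#' @return list: `time` (s), `phase_deg` in `[0, 360)`, `envelope`
#'   (analytic magnitude), `filtered`.
#' @export
lfp_phase_series <- function(lfp, band = c(5, 12), order = 3) {
  xf <- bandpass_filter(lfp$samples, lfp$sample_rate, band, order)
  a <- analytic_signal(xf)
  t <- (seq_along(xf) - 1) / lfp$sample_rate
  phase <- (Arg(a) * 180 / pi + 180) %% 360  # 0 = trough
  list(time = t, phase_deg = phase, envelope = Mod(a), filtered = xf)
}

#' Theta phase at spike times
#'
#' Interpolates the analytic theta signal (real and imaginary parts, so the
#' interpolation is wrap-safe) at the spike times. Spikes outside the LFP
#' span are dropped with a warning.
#'
#' @param lfp an [lfp_channel()].
#' @param spikes spike times (s).
#' @param band theta band (Hz).
#' @return phases in degrees `[0, 360)`, 0 = trough, one per retained spike
#'   (names dropped); attribute `kept` holds the logical retention mask.
#' @export
theta_phase <- function(lfp, spikes, band = c(5, 12)) {
  stopifnot(lfp$sample_rate >= 100)
  xf <- bandpass_filter(lfp$samples, lfp$sample_rate, band)
  a <- analytic_signal(xf)
  t <- (seq_along(xf) - 1) / lfp$sample_rate
  keep <- spikes >= t[1] & spikes <= t[length(t)]
  if (any(!keep)) {
    warning(sum(!keep), " spike(s) outside the LFP span were dropped")
  }
  re <- stats::approx(t, Re(a), xout = spikes[keep])$y
  im <- stats::approx(t, Im(a), xout = spikes[keep])$y
  out <- (atan2(im, re) * 180 / pi + 180) %% 360
  attr(out, "kept") <- keep
  out
}

#' Immobility periods from the behavior trace
#'
#' Contiguous stretches with speed below `speed_max` lasting at least
#' `min_duration_s`.
#'
#' @param behavior a behavior trace.
#' @param speed_max immobility speed threshold (cm/s).
#' @param min_duration_s minimal bout duration (s).
#' @return data.frame: `start`, `end` (s).
#' @export
immobility_periods <- function(behavior, speed_max = 2,
                               min_duration_s = 0.5) {
  slow <- behavior$speed < speed_max
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start = behavior$time[starts[keep]],
                    end = behavior$time[ends[keep]])
  out[out$end - out$start >= min_duration_s, , drop = FALSE]
}

#' Sustained-running periods from the behavior trace
#'
#' Contiguous stretches with speed at or above `speed_min` lasting at least
#' `min_duration_s` (the movement criterion used for decoding).
#'
#' @inheritParams immobility_periods
#' @param speed_min running speed threshold (cm/s).
#' @return data.frame: `start`, `end` (s).
#' @export
running_periods <- function(behavior, speed_min = 2, min_duration_s = 0.5) {
  fast <- behavior$speed >= speed_min
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(start = behavior$time[starts[keep]],
                    end = behavior$time[ends[keep]])
  out[out$end - out$start >= min_duration_s, , drop = FALSE]
}

#' Detect sharp-wave ripples
#'
#' Band-passes the LFP (120-250 Hz), takes the Hilbert envelope, and detects
#' immobility-restricted events: contiguous stretches with envelope above
#' mean + 1 SD whose peak exceeds mean + 3 SD and which last at least 20 ms,
#' fully inside an immobility period. Mean and SD are computed over the
#' immobility-restricted envelope, so detection is invariant to overall
#' amplitude scaling.
#'
#' @param lfp an [lfp_channel()] (sample rate at least 500 Hz).
#' @param behavior a behavior trace.
#' @param band ripple band (Hz).
#' @param low_sd,peak_sd envelope thresholds in SD units.
#' @param min_duration_s minimal event length (s).
#' @param speed_max,immobility_min_s immobility definition.
#' @return data.frame of class `ripple_events`: `start`, `peak`, `stop` (s),
#'   `peak_magnitude` (SD units above the mean).
#' @export
detect_ripples <- function(lfp, behavior, band = c(120, 250), low_sd = 1,
                           peak_sd = 3, min_duration_s = 0.020,
                           speed_max = 2, immobility_min_s = 0.5) {
  stopifnot(lfp$sample_rate >= 500)
  if (length(lfp$samples) < lfp$sample_rate) {
    stop("LFP shorter than 1 s; cannot detect ripples")
  }
  xf <- bandpass_filter(lfp$samples, lfp$sample_rate, band)
  env <- Mod(analytic_signal(xf))
  t <- (seq_along(env) - 1) / lfp$sample_rate
  imm <- immobility_periods(behavior, speed_max, immobility_min_s)
  if (!nrow(imm)) {
    return(data.frame(start = numeric(), peak = numeric(), stop = numeric(),
                      peak_magnitude = numeric()))
  }
  in_imm <- rep(FALSE, length(t))
  for (i in seq_len(nrow(imm))) {
    in_imm <- in_imm | (t >= imm$start[i] & t <= imm$end[i])
  }
  mu <- mean(env[in_imm])
  sd_ <- stats::sd(env[in_imm])
  cand <- env > mu + low_sd * sd_ & in_imm
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    if (t[i1] - t[i0] < min_duration_s) next
    seg <- env[i0:i1]
    if (max(seg) <= mu + peak_sd * sd_) next
    pk <- i0 + which.max(seg) - 1L
    rows[[length(rows) + 1L]] <- data.frame(
      start = t[i0], peak = t[pk], stop = t[i1],
      peak_magnitude = (max(seg) - mu) / sd_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = numeric(), peak = numeric(), stop = numeric(),
               peak_magnitude = numeric())
  rownames(out) <- NULL
  class(out) <- c("ripple_events", "data.frame")
  out
}

#' Ripple participation of a unit
#'
#' @param spikes spike times (s).
#' @param ripples ripple table from [detect_ripples()].
#' @param behavior behavior trace (for the immobility spike count).
#' @param speed_max,immobility_min_s immobility definition.
#' @return list: `participation` (fraction of ripples containing at least
#'   one spike), `ripple_quiet_spike_ratio` (spikes inside ripples / spikes
#'   during immobility), both `NA` with 0 ripples.
#' @export
ripple_participation <- function(spikes, ripples, behavior, speed_max = 2,
                                 immobility_min_s = 0.5) {
  if (!nrow(ripples)) {
    return(list(participation = NA_real_,
                ripple_quiet_spike_ratio = NA_real_))
  }
  in_rip <- vapply(seq_len(nrow(ripples)), function(i) {
    sum(spikes >= ripples$start[i] & spikes <= ripples$stop[i])
  }, numeric(1))
  imm <- immobility_periods(behavior, speed_max, immobility_min_s)
  n_imm <- 0
  for (i in seq_len(nrow(imm))) {
    n_imm <- n_imm + sum(spikes >= imm$start[i] & spikes <= imm$end[i])
  }
  list(participation = mean(in_rip > 0),
       ripple_quiet_spike_ratio = if (n_imm > 0) sum(in_rip) / n_imm
         else NA_real_)
}

#' Circular phase preference of a unit
#'
#' @param phases_deg spike phases in degrees.
#' @param min_spikes minimal spike count for a defined preference.
#' @return list: `mean_deg` (circular mean), `circ_var` (1 - resultant
#'   length), `resultant`, `n`; all `NA` below `min_spikes`.
#' @export
phase_preference <- function(phases_deg, min_spikes = 10) {
  if (length(phases_deg) < min_spikes) {
    return(list(mean_deg = NA_real_, circ_var = NA_real_,
                resultant = NA_real_, n = length(phases_deg)))
  }
  list(mean_deg = circ_mean_deg(phases_deg),
       circ_var = circ_var(phases_deg),
       resultant = circ_r(phases_deg), n = length(phases_deg))
}

#' Circular-linear phase-precession fit
#'
#' Fits phase = offset + slope * x by maximizing the mean resultant length
#' R(a) = |mean exp(i(phase - a x))| over a bounded slope range (dense grid
#' plus local refinement), with the offset as the circular mean of the
#' residuals. Significance is assessed by permuting phases against x.
#'
#' @param x linear covariate per spike: position within the field (cm) or
#'   time within the response window (s).
#' @param phases_deg spike theta phases (degrees).
#' @param slope_range c(lo, hi) admissible slope (degrees per unit of x).
#' @param n_grid grid resolution over the slope range.
#' @param n_perm phase permutations for the significance test.
#' @param alpha significance level.
#' @param min_spikes minimal spike count.
#' @param seed seed for the permutation test.
#' @return list of class `phase_precession_fit`: `slope` (deg per unit x),
#'   `offset_deg` (phase at x = 0), `resultant`, `p`, `significant`,
#'   `start_phase_deg`, `stop_phase_deg` (linear model at the extremes of
#'   x), `phase_range_deg` (capped at 360), `n`. NULL fit (all NA) when x is
#'   degenerate or spikes are too few.
#' @export
fit_phase_precession <- function(x, phases_deg, slope_range = c(-30, 30),
                                 n_grid = 241, n_perm = 1000, alpha = 0.05,
                                 min_spikes = 10, seed = 1) {
  null_fit <- list(slope = NA_real_, offset_deg = NA_real_,
                   resultant = NA_real_, p = NA_real_, significant = FALSE,
                   start_phase_deg = NA_real_, stop_phase_deg = NA_real_,
                   phase_range_deg = NA_real_, n = length(x))
  class(null_fit) <- "phase_precession_fit"
  if (length(x) < min_spikes || length(unique(x)) < 2) return(null_fit)
  phi <- phases_deg * pi / 180
  resultant_at <- function(a_deg) {
    r <- phi - a_deg * pi / 180 * x
    sqrt(mean(cos(r))^2 + mean(sin(r))^2)
  }
  grid <- seq(slope_range[1], slope_range[2], length.out = n_grid)
  # resultant over the grid for all spikes at once: n x G complex basis
  M <- exp(-1i * outer(x, grid * pi / 180))
  Rg <- Mod(crossprod(M, exp(1i * phi)))[, 1] / length(x)
  best <- which.max(Rg)
  R_grid <- Rg[best]
  lo <- grid[max(best - 1, 1)]
  hi <- grid[min(best + 1, n_grid)]
  opt <- stats::optimize(resultant_at, c(lo, hi), maximum = TRUE)
  slope <- opt$maximum
  R <- opt$objective
  if (R_grid > R) { slope <- grid[best]; R <- R_grid }
  offset <- circ_mean_deg((phases_deg - slope * x) %% 360)
  # permutation null: max-over-grid statistic, compared against the
  # observed max over the same grid (one complex matrix product)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  P <- vapply(seq_len(n_perm), function(i) exp(1i * sample(phi)),
              complex(length(x)))
  perm_R <- apply(Mod(crossprod(M, P)) / length(x), 2, max)
  p <- (1 + sum(perm_R >= R_grid)) / (n_perm + 1)
  start_phase <- (offset + slope * min(x)) %% 360
  stop_phase <- (offset + slope * max(x)) %% 360
  fit <- list(slope = slope, offset_deg = offset, resultant = R, p = p,
              significant = p < alpha,
              start_phase_deg = start_phase, stop_phase_deg = stop_phase,
              phase_range_deg = min(abs(slope) * (max(x) - min(x)), 360),
              n = length(x))
  class(fit) <- "phase_precession_fit"
  fit
}
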