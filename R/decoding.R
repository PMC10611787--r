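#' Segment theta cycles during sustained running
#'
#' Theta cycles are trough-to-trough intervals of the 5-12 Hz phase
#' (troughs = 0-degree crossings), restricted to periods with speed at or
#' above `speed_min` sustained for at least `min_run_s`; cycles with
#' duration outside the theta band's period range `[1/12, 1/5]` s are
#' discarded.
#'
#' @param lfp an [lfp_channel()].
#' @param behavior behavior trace.
#' @param speed_min running threshold (cm/s).
#' @param min_run_s minimal sustained-running duration (s).
#' @param band theta band (Hz).
#' @return data.frame: `start`, `end` (s), `duration`.
#' @export
segment_theta_cycles <- function(lfp, behavior, speed_min = 2,
                                 min_run_s = 0.5, band = c(5, 12)) {
  ph <- lfp_phase_series(lfp, band)
  # troughs: wrap-around of the phase (drop from near 360 to near 0)
  dphi <- diff(ph$phase_deg)
  trough_ix <- which(dphi < -180) + 1L
  troughs <- ph$time[trough_ix]
  if (length(troughs) < 2) {
    return(data.frame(start = numeric(), end = numeric(),
                      duration = numeric()))
  }
  cyc <- data.frame(start = troughs[-length(troughs)], end = troughs[-1])
  cyc$duration <- cyc$end - cyc$start
  cyc <- cyc[cyc$duration >= 1 / band[2] & cyc$duration <= 1 / band[1], ,
             drop = FALSE]
  runs <- running_periods(behavior, speed_min, min_run_s)
  if (!nrow(runs)) return(cyc[0, ])
  ok <- rep(FALSE, nrow(cyc))
  for (i in seq_len(nrow(runs))) {
    ok <- ok | (cyc$start >= runs$start[i] & cyc$end <= runs$end[i])
  }
  out <- cyc[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Poisson Bayesian position decoding of one spike-count vector
#'
#' Posterior `P(x | n) propto prod_i f_i(x)^{n_i} * exp(-tau * sum_i f_i(x))`
#' over position bins, assuming Poisson spiking and independent units, with
#' a uniform prior over the bins visited in training. Computed in the log
#' domain; a small rate floor regularizes silent bins.
#'
#' @param counts spike-count vector over units.
#' @param rate_maps units x bins matrix of training firing rates (Hz).
#' @param tau decoding window duration (s).
#' @param prior optional prior over bins (default: uniform over bins with a
#'   finite, non-NA column in `rate_maps`).
#' @param rate_floor additive rate regularizer (Hz).
#' @return normalized posterior vector over bins.
#' @export
bayes_decode <- function(counts, rate_maps, tau, prior = NULL,
                         rate_floor = 0.01) {
  stopifnot(length(counts) == nrow(rate_maps))
  f <- rate_maps
  occupied <- colSums(is.na(f)) == 0
  f[is.na(f)] <- 0
  f <- f + rate_floor
  logpost <- as.numeric(crossprod(counts, log(f))) - tau * colSums(f)
  if (is.null(prior)) prior <- as.numeric(occupied)
  logpost <- logpost + log(ifelse(prior > 0, prior, 0))
  logpost[prior <= 0] <- -Inf
  m <- max(logpost)
  post <- exp(logpost - m)
  post / sum(post)
}

#' Decode a set of theta cycles
#'
#' Counts each unit's spikes per cycle and decodes every cycle with
#' [bayes_decode()]; the maximum a posteriori (MAP) bin is the decoded
#' position, compared against the animal's actual position at the cycle
#' midpoint.
#'
#' @param s an `ephys_session`.
#' @param cycles data.frame from [segment_theta_cycles()].
#' @param rate_maps units x bins training rate maps (Hz); rownames must be
#'   unit ids present in the session.
#' @param bin_cm spatial bin width of the maps (cm).
#' @param rate_floor decoder regularizer (Hz).
#' @param keep_posteriors return the full posterior matrix.
#' @return list of class `decoding_result`: `cycles` data.frame (`start`,
#'   `end`, `n_spikes`, `map_cm`, `true_cm`, `error_cm` circular), and
#'   `posteriors` (cycles x bins matrix) when requested.
#' @export
decode_cycles <- function(s, cycles, rate_maps, bin_cm = 2,
                          rate_floor = 0.01, keep_posteriors = FALSE) {
  units <- rownames(rate_maps)
  stopifnot(!is.null(units), all(units %in% names(s$spike_trains)))
  n_bins <- ncol(rate_maps)
  centers <- seq(bin_cm / 2, s$track_length - bin_cm / 2, by = bin_cm)
  stopifnot(length(centers) == n_bins)
  n_cyc <- nrow(cycles)
  counts <- matrix(0L, length(units), n_cyc)
  for (i in seq_along(units)) {
    st <- s$spike_trains[[units[i]]]
    counts[i, ] <- findInterval(cycles$end, st) - findInterval(cycles$start, st)
  }
  f <- rate_maps
  occupied <- colSums(is.na(f)) == 0
  f[is.na(f)] <- 0
  f <- f + rate_floor
  logf <- log(f)
  sumf <- colSums(f)
  LL <- crossprod(counts, logf) - outer(cycles$duration, sumf)
  LL[, !occupied] <- -Inf
  map_bin <- max.col(LL, ties.method = "first")
  mid <- (cycles$start + cycles$end) / 2
  true_cm <- position_at_time(s, mid)
  map_cm <- centers[map_bin]
  res <- data.frame(start = cycles$start, end = cycles$end,
                    duration = cycles$duration,
                    n_spikes = colSums(counts),
                    map_cm = map_cm, true_cm = true_cm,
                    error_cm = circ_track_dist(map_cm, true_cm,
                                               s$track_length))
  out <- list(cycles = res, counts = counts, unit_ids = units,
              bin_centers = centers, track_length = s$track_length)
  if (keep_posteriors) {
    P <- exp(LL - apply(LL, 1, max))
    out$posteriors <- P / rowSums(P)
  }
  class(out) <- "decoding_result"
  out
}

#' Training rate maps for the decoder
#'
#' @param s an `ephys_session`.
#' @param laps training lap set.
#' @param unit_ids units to include.
#' @param speed_min movement filter (cm/s).
#' @param bin_cm bin width (cm).
#' @return units x bins matrix of rates (Hz; NA for unoccupied bins),
#'   rownames = unit ids.
#' @export
rate_maps_from_laps <- function(s, laps, unit_ids = names(s$spike_trains),
                                speed_min = 2, bin_cm = 2) {
  maps <- t(vapply(unit_ids, function(uid) {
    tuning_curve_laps(s$spike_trains[[uid]], s, laps, speed_min, bin_cm)$rate
  }, numeric(as.integer(round(s$track_length / bin_cm)))))
  rownames(maps) <- unit_ids
  maps
}

#' Decoding-error profile along the track
#'
#' Average circular decoding error per 2 cm bin of true position.
#'
#' @param result a [decode_cycles()] result.
#' @param bin_cm bin width (cm).
#' @param min_cycles bins with fewer cycles are reported `NA`.
#' @return data.frame: `center_cm`, `mean_error_cm`, `n_cycles`.
#' @export
decoding_error_profile <- function(result, bin_cm = 2, min_cycles = 3) {
  L <- result$track_length
  n_bins <- as.integer(round(L / bin_cm))
  cyc <- result$cycles
  bin <- pmin(floor(cyc$true_cm / bin_cm) + 1L, n_bins)
  centers <- seq(bin_cm / 2, L - bin_cm / 2, by = bin_cm)
  mean_err <- rep(NA_real_, n_bins)
  n_cyc <- tabulate(bin, nbins = n_bins)
  agg <- tapply(cyc$error_cm, factor(bin, levels = seq_len(n_bins)), mean)
  ok <- n_cyc >= min_cycles
  mean_err[ok] <- agg[ok]
  data.frame(center_cm = centers, mean_error_cm = mean_err,
             n_cycles = n_cyc)
}

#' Reward-zone decoded probability with a Monte-Carlo null
#'
#' For each 2 cm bin of the animal's distance past the air-puff location,
#' the fraction of theta cycles whose MAP position falls inside the
#' peri-reward zone (reward +/- `zone_cm`). The null band repeats the
#' computation for `n_mc` random control zones per cycle, drawn uniformly
#' over the track but excluding centers within `zone_cm` of the reward and
#' of the cycle's actual position; a bin is significant iff the observed
#' probability exceeds the null's 97.5th percentile.
#'
#' @param result a [decode_cycles()] result.
#' @param reward_location cm.
#' @param ap_location air-puff location (cm) anchoring the distance axis.
#' @param zone_cm zone half-width (20 cm).
#' @param n_mc Monte-Carlo draws (1000).
#' @param seed RNG seed.
#' @param bin_cm distance-bin width (cm).
#' @param min_cycles bins with fewer cycles are dropped.
#' @return data.frame of class `reward_shift_result`: `distance_cm` (bin
#'   center of distance past the puff), `p_reward` (observed), `null_lo`,
#'   `null_hi` (2.5/97.5 percentiles), `significant`, `n_cycles`.
#' @export
reward_zone_probability <- function(result, reward_location, ap_location,
                                    zone_cm = 20, n_mc = 1000, seed = 1,
                                    bin_cm = 2, min_cycles = 3) {
  L <- result$track_length
  if (2 * zone_cm >= L) stop("reward zone covers the whole track")
  cyc <- result$cycles
  n <- nrow(cyc)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  in_zone <- function(x, center) circ_track_dist(x, center, L) <= zone_cm
  obs_hit <- in_zone(cyc$map_cm, reward_location)
  # per-cycle random control centers, rejecting excluded regions
  ctr <- matrix(stats::runif(n_mc * n, 0, L), n_mc, n)
  bad <- in_zone(ctr, reward_location) |
    circ_track_dist(ctr, rep(cyc$true_cm, each = n_mc), L) <= zone_cm
  while (any(bad)) {
    ctr[bad] <- stats::runif(sum(bad), 0, L)
    bad <- in_zone(ctr, reward_location) |
      circ_track_dist(ctr, rep(cyc$true_cm, each = n_mc), L) <= zone_cm
  }
  null_hit <- circ_track_dist(matrix(rep(cyc$map_cm, each = n_mc), n_mc, n),
                              ctr, L) <= zone_cm
  dist_past <- (cyc$true_cm - ap_location) %% L
  n_bins <- as.integer(round(L / bin_cm))
  bin <- pmin(floor(dist_past / bin_cm) + 1L, n_bins)
  fbin <- factor(bin, levels = seq_len(n_bins))
  n_cyc <- tabulate(bin, nbins = n_bins)
  p_obs <- tapply(obs_hit, fbin, mean)
  null_p <- apply(null_hit, 1, function(h) tapply(h, fbin, mean))
  qrow <- function(v, q) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    stats::quantile(v, q, names = FALSE)
  }
  null_lo <- apply(null_p, 1, qrow, q = 0.025)
  null_hi <- apply(null_p, 1, qrow, q = 0.975)
  out <- data.frame(distance_cm = seq(bin_cm / 2, L - bin_cm / 2,
                                      by = bin_cm),
                    p_reward = as.numeric(p_obs),
                    null_lo = null_lo, null_hi = null_hi,
                    n_cycles = n_cyc)
  out$significant <- !is.na(out$p_reward) & out$n_cycles >= min_cycles &
    out$p_reward > out$null_hi
  out <- out[out$n_cycles >= min_cycles, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reward_shift_result", "data.frame")
  out
}

#' Quintile decomposition of tuning curves in reward-coding cycles
#'
#' Selects "reward-coding" theta cycles — cycles within `window_s` after an
#' air-puff onset whose MAP position falls inside the peri-reward zone —
#' ranks pyramidal cells by their mean within-cycle firing rate, splits
#' them into quintiles, and averages the z-score-normalized tuning curves
#' per quintile.
#'
#' @param result a [decode_cycles()] result.
#' @param rate_maps units x bins tuning curves (same registry as the
#'   decoder).
#' @param ap_onsets air-puff onset times (s).
#' @param reward_location cm.
#' @param zone_cm peri-reward half-width (cm).
#' @param window_s post-onset window (s).
#' @return list: `quintile` (named unit assignment 1-5; 5 = most active),
#'   `mean_curves` (5 x bins matrix of averaged z-scored tuning curves),
#'   `n_cycles` (reward-coding cycles used); NULL when no reward-coding
#'   cycles exist.
#' @export
quintile_tuning_decomposition <- function(result, rate_maps, ap_onsets,
                                          reward_location, zone_cm = 20,
                                          window_s = 3) {
  cyc <- result$cycles
  L <- result$track_length
  post <- rep(FALSE, nrow(cyc))
  for (on in ap_onsets) {
    post <- post | (cyc$start > on & cyc$start <= on + window_s)
  }
  coding <- post & circ_track_dist(cyc$map_cm, reward_location, L) <= zone_cm
  if (!any(coding)) return(NULL)
  sel <- which(coding)
  rate_in_cycle <- result$counts[, sel, drop = FALSE] /
    matrix(cyc$duration[sel], nrow(result$counts), length(sel), byrow = TRUE)
  mean_rate <- rowMeans(rate_in_cycle)
  n_units <- length(mean_rate)
  if (n_units < 5) stop("need at least 5 units for quintiles")
  rk <- rank(mean_rate, ties.method = "first")
  quintile <- as.integer(ceiling(rk / n_units * 5))
  names(quintile) <- result$unit_ids
  zmaps <- t(apply(rate_maps, 1, function(r) {
    r[is.na(r)] <- 0
    if (stats::sd(r) == 0) return(rep(0, length(r)))
    (r - mean(r)) / stats::sd(r)
  }))
  mean_curves <- t(vapply(1:5, function(q) {
    colMeans(zmaps[quintile == q, , drop = FALSE])
  }, numeric(ncol(zmaps))))
  rownames(mean_curves) <- paste0("Q", 1:5)
  list(quintile = quintile, mean_curves = mean_curves,
       n_cycles = length(sel))
}
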