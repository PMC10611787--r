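#' Generator configuration for synthetic sessions
#'
#' Returns the default parameters of the synthetic-session generator. The
#' defaults emulate the head-fixed treadmill paradigm the pipeline targets:
#' a 190 cm circular track, no-stimulation blocks of 10 laps alternating
#' with air-puff blocks of 10 trials (one puff per lap) at each of 3 distinct
#' locations, a water reward at a fixed location where the animal pauses
#' (the immobility bouts that carry ripples), spatially tuned theta-modulated
#' Poisson spiking with phase precession, stimulus-locked activation and
#' suppression, pyramidal-to-interneuron spike transmission, and embedded
#' co-activation assemblies.
#'
#' @param ... named overrides of any default listed below.
#' @return a list of class `synth_config`.
#'
#' @section Main parameters:
#' * `track_length` (cm), `run_speed` (cm/s), `reward_location` (cm),
#'   `reward_pause_s`: behavior layout. The animal runs at constant speed and
#'   pauses at the reward each lap.
#' * `n_pyramidal`, `n_interneuron`: unit counts.
#' * `place_cell_frac`, `field_width_fwhm` (cm, full width at half maximum
#'   of the Gaussian bump), `field_peak_hz`: spatial tuning.
#' * `pyr_baseline_hz`, `int_baseline_hz`: lognormal baseline-rate medians.
#' * `theta_freq` (Hz), `theta_mod_depth`, `precession_slope_deg_cm`:
#'   oscillatory modulation; place-cell preferred phase advances linearly
#'   across the field at the given slope.
#' * `no_stim_laps`, `n_ap_locations`, `trials_per_location`,
#'   `ap_locations` (cm or NULL for auto spacing), `ap_duration_s`: epoch
#'   plan (no-stim block, then air-puff/no-stim alternation).
#' * `frac_activated`, `frac_suppressed`, `response_gain_hz` (additive rate
#'   step), `response_latency_s`, `response_duration_s`,
#'   `suppression_factor`, `suppression_latency_s`, `suppression_duration_s`,
#'   `suppressed_baseline_hz`: stimulus coupling.
#' * `n_assemblies`, `assembly_size`, `assembly_rate_hz`,
#'   `assembly_boost_spikes`: embedded co-activation events, aligned to the
#'   25 ms analysis grid.
#' * `n_connections`, `transmission_prob`, `transmission_delay_ms`,
#'   `transmission_jitter_ms`: monosynaptic pyramidal-to-interneuron pairs.
#' * `lfp`, `lfp_rate`, `lfp_noise_sd`, `theta_amp`, `ripple_rate_hz`,
#'   `ripple_freq`, `ripple_duration_s`, `ripple_amp`: surrogate LFP with
#'   theta during running and ripple bursts during immobility.
#' * `post_puff_remap`: NULL or `list(segment_cm=, shift_cm=)` — during
#'   air-puff laps, place fields are evaluated at a shifted position inside
#'   the track segment following the puff location (injects a localized
#'   remap for decoding-error analyses).
#' * `reward_reactivation`: NULL or `list(window_s=, boost_hz=, zone_cm=)` —
#'   place cells with fields within `zone_cm` of the reward receive an
#'   additive rate boost for `window_s` after each puff (injects the
#'   reward-shifted code for reward-zone decoding analyses).
#' @export
synth_config <- function(...) {
  cfg <- list(
    track_length = 190,
    run_speed = 15,
    reward_location = 150,
    reward_pause_s = 2,
    behavior_dt = 0.02,
    n_pyramidal = 40,
    n_interneuron = 8,
    place_cell_frac = 0.5,
    field_width_fwhm = 15,
    field_peak_hz = 12,
    place_baseline_frac = 0.1,
    pyr_baseline_hz = 0.8,
    pyr_baseline_sdlog = 0.4,
    int_baseline_hz = 10,
    int_baseline_sdlog = 0.25,
    theta_freq = 8,
    theta_mod_depth = 0.5,
    precession_slope_deg_cm = -8,
    pyr_burst_prob = 0.3,
    burst_isi_ms = c(4, 8),
    no_stim_laps = 10,
    n_ap_locations = 3,
    trials_per_location = 10,
    ap_locations = NULL,
    ap_duration_s = 0.2,
    frac_activated = 0.15,
    frac_suppressed = 0.10,
    response_gain_hz = 20,
    response_latency_s = 0.10,
    response_duration_s = 0.5,
    suppression_factor = 0.1,
    suppression_latency_s = 0.10,
    suppression_duration_s = 1.0,
    suppressed_baseline_hz = 8,
    n_assemblies = 0,
    assembly_size = 8,
    assembly_rate_hz = 0.2,
    assembly_boost_spikes = 2,
    assembly_bin_s = 0.025,
    n_connections = 0,
    transmission_prob = 0.1,
    transmission_delay_ms = 1.5,
    transmission_jitter_ms = 0.3,
    lfp = TRUE,
    lfp_rate = 1000,
    lfp_noise_sd = 0.3,
    theta_amp = 1,
    ripple_rate_hz = 0.4,
    ripple_freq = 150,
    ripple_duration_s = 0.05,
    ripple_amp = 5,
    post_puff_remap = NULL,
    reward_reactivation = NULL
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("unknown synth_config parameter(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(ov)] <- ov
  structure(cfg, class = c("synth_config", "list"))
}

# Maximally separated air-puff locations (L/n apart, as in the paradigm,
# where the locations span the track), phased to avoid the peri-reward zone.
# Wide separation matters: the per-location consistency rule can only reject
# place-field-locked artifacts if at most one location lies within the
# response window's track span (~3 s of running) upstream of any field.
auto_ap_locations <- function(cfg) {
  n <- cfg$n_ap_locations
  L <- cfg$track_length
  spacing <- L / n
  margin <- min(25, spacing / 2 - 1)
  best <- NULL
  best_d <- -Inf
  for (phase in seq(2, spacing, by = 1)) {
    locs <- (phase + (0:(n - 1)) * spacing) %% L
    if (any(locs < 2)) next  # keep puffs off the lap-boundary wrap point
    d <- min(circ_track_dist(locs, cfg$reward_location, L))
    if (d > best_d) { best_d <- d; best <- locs }
  }
  if (best_d <= margin) {
    warning("air-puff locations could not all clear the peri-reward zone")
  }
  round(sort(best), 1)
}

# Lap-level plan: label / ap location per lap, built from the config.
build_lap_plan <- function(cfg) {
  ap_locs <- cfg$ap_locations
  if (is.null(ap_locs) && cfg$n_ap_locations > 0) ap_locs <- auto_ap_locations(cfg)
  labels <- rep("no_stim", cfg$no_stim_laps)
  locs <- rep(NA_real_, cfg$no_stim_laps)
  for (l in seq_along(ap_locs)) {
    labels <- c(labels, rep("air_puff", cfg$trials_per_location),
                rep("no_stim", cfg$no_stim_laps))
    locs <- c(locs, rep(ap_locs[l], cfg$trials_per_location),
              rep(NA_real_, cfg$no_stim_laps))
  }
  data.frame(lap = seq_along(labels), label = labels, ap_location = locs)
}

# Piecewise-analytic behavior: constant-speed laps with a pause at reward.
build_behavior <- function(cfg, lap_plan) {
  L <- cfg$track_length
  v <- cfg$run_speed
  dt_r1 <- cfg$reward_location / v
  pause <- cfg$reward_pause_s
  lap_dur <- L / v + pause
  n_laps <- nrow(lap_plan)
  lap_start <- (seq_len(n_laps) - 1) * lap_dur
  t <- seq(0, n_laps * lap_dur - cfg$behavior_dt, by = cfg$behavior_dt)
  lap <- pmin(findInterval(t, lap_start), n_laps)
  tau <- t - lap_start[lap]
  pos <- numeric(length(t))
  spd <- numeric(length(t))
  pre <- tau < dt_r1
  mid <- tau >= dt_r1 & tau < dt_r1 + pause
  post <- tau >= dt_r1 + pause
  pos[pre] <- v * tau[pre]
  spd[pre] <- v
  pos[mid] <- cfg$reward_location
  spd[mid] <- 0
  pos[post] <- v * (tau[post] - pause)
  spd[post] <- v
  behavior_trace(time = t, position = pos %% L, speed = spd, lap = lap)
}

# Event log (air puffs + rewards) consistent with the behavior trace.
build_events <- function(cfg, lap_plan) {
  v <- cfg$run_speed
  L <- cfg$track_length
  pause <- cfg$reward_pause_s
  lap_dur <- L / v + pause
  lap_start <- (lap_plan$lap - 1) * lap_dur
  rew <- data.frame(event_type = "reward",
                    onset = lap_start + cfg$reward_location / v,
                    duration = 0.05,
                    track_location = cfg$reward_location,
                    epoch_index = 0L)
  ap_rows <- lap_plan[lap_plan$label == "air_puff", , drop = FALSE]
  ev <- rew
  if (nrow(ap_rows)) {
    epoch <- cumsum(c(TRUE, diff(ap_rows$lap) > 1 |
                        diff(ap_rows$ap_location) != 0))
    ap <- data.frame(event_type = "air_puff",
                     onset = (ap_rows$lap - 1) * lap_dur +
                       ap_rows$ap_location / v +
                       ifelse(ap_rows$ap_location > cfg$reward_location,
                              pause, 0),
                     duration = cfg$ap_duration_s,
                     track_location = ap_rows$ap_location,
                     epoch_index = as.integer(epoch))
    ev <- rbind(ev, ap)
  }
  ev <- ev[order(ev$onset), ]
  rownames(ev) <- NULL
  class(ev) <- c("event_log", "data.frame")
  ev
}

# Draw per-unit ground truth (classes, tuning, responses) from the config.
draw_unit_truth <- function(cfg) {
  n_pyr <- cfg$n_pyramidal
  n_int <- cfg$n_interneuron
  n <- n_pyr + n_int
  unit_id <- sprintf("u%03d", seq_len(n))
  cls <- c(rep("pyramidal", n_pyr), rep("interneuron", n_int))
  baseline <- c(
    stats::rlnorm(n_pyr, log(cfg$pyr_baseline_hz), cfg$pyr_baseline_sdlog),
    stats::rlnorm(n_int, log(cfg$int_baseline_hz), cfg$int_baseline_sdlog)
  )
  is_place <- c(stats::runif(n_pyr) < cfg$place_cell_frac, rep(FALSE, n_int))
  center <- ifelse(is_place, stats::runif(n, 0, cfg$track_length), NA_real_)
  width <- ifelse(is_place, cfg$field_width_fwhm, NA_real_)
  peak <- ifelse(is_place, cfg$field_peak_hz, NA_real_)
  slope <- ifelse(is_place, cfg$precession_slope_deg_cm, NA_real_)
  # stimulus coupling: pyramidal cells only (interneurons inherit drive
  # through their monosynaptic inputs)
  response <- rep("none", n)
  pyr_ix <- seq_len(n_pyr)
  n_act <- round(cfg$frac_activated * n_pyr)
  n_sup <- round(cfg$frac_suppressed * n_pyr)
  pick <- sample(pyr_ix, min(n_act + n_sup, n_pyr))
  if (n_act > 0) response[pick[seq_len(n_act)]] <- "activated"
  if (n_sup > 0 && length(pick) > n_act) {
    response[pick[(n_act + 1):length(pick)]] <- "suppressed"
  }
  # place cells are close to silent outside their field (out-of-field rate
  # well under the 5%-of-peak field threshold)
  baseline[is_place] <- baseline[is_place] * cfg$place_baseline_frac
  # suppressed units need a measurable baseline for z < -1 to be reachable
  baseline[response == "suppressed"] <- cfg$suppressed_baseline_hz
  resp_latency <- ifelse(response == "activated", cfg$response_latency_s,
                         ifelse(response == "suppressed",
                                cfg$suppression_latency_s, NA_real_))
  resp_duration <- ifelse(response == "activated", cfg$response_duration_s,
                          ifelse(response == "suppressed",
                                 cfg$suppression_duration_s, NA_real_))
  gain <- ifelse(response == "activated", cfg$response_gain_hz, NA_real_)
  # spike-waveform metadata for the classifier (generated, since waveform
  # extraction happens upstream): interneurons narrow, pyramidal wide
  half_width <- ifelse(cls == "interneuron",
                       stats::runif(n, 0.15, 0.28),
                       stats::runif(n, 0.35, 0.6))
  data.frame(unit_id = unit_id, class = cls, baseline_hz = baseline,
             is_place = is_place, field_center_cm = center,
             field_width_fwhm_cm = width, field_peak_hz = peak,
             precession_slope_deg_cm = slope, response = response,
             response_latency_s = resp_latency,
             response_duration_s = resp_duration,
             response_gain_hz = gain,
             half_width_ms = half_width,
             stringsAsFactors = FALSE)
}

# Instantaneous rate of one unit at arbitrary times. `env` carries the
# interpolated behavior (pos, spd, lap, theta phase) at those times.
unit_rate_at <- function(u, env, cfg, ap_onsets, lap_plan) {
  L <- cfg$track_length
  rate <- rep(u$baseline_hz, length(env$t))
  running <- env$spd > 2
  if (isTRUE(u$is_place)) {
    sd_cm <- u$field_width_fwhm_cm / (2 * sqrt(2 * log(2)))
    pos_eval <- env$pos
    rm <- cfg$post_puff_remap
    if (!is.null(rm)) {
      ap_loc <- env$lap_ap_location
      in_seg <- !is.na(ap_loc) &
        ((env$pos - ap_loc) %% L) < rm$segment_cm
      pos_eval[in_seg] <- (env$pos[in_seg] + rm$shift_cm) %% L
    }
    d <- circ_track_dist(pos_eval, u$field_center_cm, L)
    bump <- u$field_peak_hz * exp(-d^2 / (2 * sd_cm^2))
    rate <- rate + ifelse(running, bump, 0)
  }
  # theta modulation (running only), with phase precession inside the field
  m <- cfg$theta_mod_depth
  if (m > 0) {
    pref <- rep(180, length(env$t))  # default preference away from trough
    if (isTRUE(u$is_place)) {
      sd_cm <- u$field_width_fwhm_cm / (2 * sqrt(2 * log(2)))
      half_extent <- sd_cm * sqrt(2 * log(20))  # 5%-of-peak extent
      dx <- circ_track_diff(env$pos, u$field_center_cm, L)
      infield <- abs(dx) <= half_extent
      pref[infield] <- 180 + u$precession_slope_deg_cm * (dx[infield] + half_extent)
    }
    mod <- 1 + m * cos((env$theta_deg - pref) * pi / 180)
    rate <- rate * ifelse(running, mod, 1)
  }
  # stimulus coupling
  if (u$response == "activated" && length(ap_onsets)) {
    on <- outer(env$t, ap_onsets + u$response_latency_s, ">=") &
      outer(env$t, ap_onsets + u$response_latency_s + u$response_duration_s, "<")
    rate <- rate + u$response_gain_hz * (rowSums(on) > 0)
  }
  if (u$response == "suppressed" && length(ap_onsets)) {
    on <- outer(env$t, ap_onsets + u$response_latency_s, ">=") &
      outer(env$t, ap_onsets + u$response_latency_s + u$response_duration_s, "<")
    rate <- ifelse(rowSums(on) > 0, rate * cfg$suppression_factor, rate)
  }
  rr <- cfg$reward_reactivation
  if (!is.null(rr) && isTRUE(u$is_place) && length(ap_onsets) &&
      circ_track_dist(u$field_center_cm, cfg$reward_location, L) <= rr$zone_cm) {
    on <- outer(env$t, ap_onsets, ">") &
      outer(env$t, ap_onsets + rr$window_s, "<=")
    rate <- rate + rr$boost_hz * (rowSums(on) > 0)
  }
  pmax(rate, 0)
}

# Conservative upper bound on a unit's instantaneous rate, for thinning.
unit_rate_max <- function(u, cfg) {
  r <- u$baseline_hz
  if (isTRUE(u$is_place)) r <- r + u$field_peak_hz
  if (u$response == "activated") r <- r + u$response_gain_hz
  rr <- cfg$reward_reactivation
  if (!is.null(rr)) r <- r + rr$boost_hz
  r * (1 + cfg$theta_mod_depth) + 1e-9
}

# Generator-internal theta phase (deg, 0 = trough): advances at theta_freq
# during running, frozen during immobility.
theta_phase_fun <- function(behavior, cfg) {
  run <- behavior$speed > 2
  dphi <- ifelse(run, 360 * cfg$theta_freq * cfg$behavior_dt, 0)
  phi <- cumsum(c(0, dphi[-length(dphi)]))  # unwrapped: interpolation-safe
  function(times) {
    stats::approx(behavior$time, phi, xout = times, rule = 2)$y %% 360
  }
}

#' Generate a synthetic session with ground truth
#'
#' Draws a full session (spikes, behavior, events, LFP) from the generative
#' model described in [synth_config()], deterministic given `seed`. Spikes
#' are an inhomogeneous Poisson process (thinning) with rate
#' baseline + circular Gaussian place field x theta modulation +
#' stimulus-response kernel; designated interneurons receive transmitted
#' spikes 1-3 ms after their presynaptic pyramidal cells' spikes; assembly
#' members receive synchronized extra spikes in shared 25 ms windows; the
#' LFP contains theta during running and ripple bursts during immobility.
#'
#' @param config a [synth_config()] list.
#' @param seed integer seed; the same (config, seed) always yields an
#'   identical session.
#' @return `list(session =` [session()] object`, truth = )` ground-truth list
#'   with elements `units` (per-unit data.frame), `assemblies` (member id
#'   list), `assembly_events` (event-time list), `connections` (data.frame
#'   pre/post/prob/delay), `ripples` (true burst peak times),
#'   `reward_modulated` (unit ids), `lap_plan` and `ap_locations`.
#' @export
generate_session <- function(config = synth_config(), seed = 1) {
  cfg <- config
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  lap_plan <- build_lap_plan(cfg)
  behavior <- build_behavior(cfg, lap_plan)
  events <- build_events(cfg, lap_plan)
  duration <- max(behavior$time) + cfg$behavior_dt
  units <- draw_unit_truth(cfg)

  if (cfg$n_assemblies > 0 &&
      cfg$n_assemblies * cfg$assembly_size > cfg$n_pyramidal) {
    stop("assembly members exceed the pyramidal population: ",
         "n_assemblies * assembly_size must be <= n_pyramidal")
  }

  ap_onsets <- events$onset[events$event_type == "air_puff"]
  theta_at <- theta_phase_fun(behavior, cfg)
  sess_stub <- list(behavior = behavior, track_length = cfg$track_length)

  spike_trains <- vector("list", nrow(units))
  names(spike_trains) <- units$unit_id
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    rmax <- unit_rate_max(u, cfg)
    n_cand <- stats::rpois(1, rmax * duration)
    tc <- sort(stats::runif(n_cand, 0, duration))
    if (length(tc)) {
      env <- list(t = tc,
                  pos = position_at_time(sess_stub, tc),
                  spd = speed_at_time(sess_stub, tc),
                  theta_deg = theta_at(tc),
                  lap_ap_location = lap_plan$ap_location[
                    pmin(lap_at_time(behavior, tc), nrow(lap_plan))])
      r <- unit_rate_at(u, env, cfg, ap_onsets, lap_plan)
      keep <- stats::runif(length(tc)) < r / rmax
      st <- tc[keep]
      # complex-spike bursts: pyramidal cells emit a short-ISI doublet with
      # probability pyr_burst_prob (drives the burst index used by the
      # classifier)
      if (u$class == "pyramidal" && cfg$pyr_burst_prob > 0 && length(st)) {
        b <- st[stats::runif(length(st)) < cfg$pyr_burst_prob]
        if (length(b)) {
          extra <- b + stats::runif(length(b), cfg$burst_isi_ms[1],
                                    cfg$burst_isi_ms[2]) / 1000
          st <- sort(c(st, extra[extra < duration]))
        }
      }
      spike_trains[[i]] <- st
    } else {
      spike_trains[[i]] <- numeric()
    }
  }

  # embedded assemblies: shared activation events aligned to the 25 ms grid
  assemblies <- list()
  assembly_events <- list()
  if (cfg$n_assemblies > 0) {
    pyr_ids <- units$unit_id[units$class == "pyramidal"]
    avail <- sample(pyr_ids)
    for (a in seq_len(cfg$n_assemblies)) {
      members <- sort(avail[((a - 1) * cfg$assembly_size + 1):(a * cfg$assembly_size)])
      n_ev <- stats::rpois(1, cfg$assembly_rate_hz * duration)
      ev <- sort(cfg$assembly_bin_s *
                   floor(stats::runif(n_ev, 0, duration / cfg$assembly_bin_s)))
      ev <- unique(ev[ev + cfg$assembly_bin_s < duration])
      for (mid in members) {
        n_extra <- stats::rpois(length(ev), cfg$assembly_boost_spikes)
        extra <- rep(ev, n_extra) +
          stats::runif(sum(n_extra), 0, cfg$assembly_bin_s)
        spike_trains[[mid]] <- sort(c(spike_trains[[mid]], extra))
      }
      assemblies[[a]] <- members
      assembly_events[[a]] <- ev
    }
  }

  # monosynaptic pyramidal -> interneuron spike transmission
  connections <- data.frame(pre = character(), post = character(),
                            prob = numeric(), delay_ms = numeric())
  if (cfg$n_connections > 0) {
    pyr_ids <- units$unit_id[units$class == "pyramidal"]
    int_ids <- units$unit_id[units$class == "interneuron"]
    if (!length(int_ids)) stop("connections requested but no interneurons")
    pre <- sample(pyr_ids, cfg$n_connections, replace = FALSE)
    post <- sample(int_ids, cfg$n_connections, replace = TRUE)
    connections <- data.frame(pre = pre, post = post,
                              prob = cfg$transmission_prob,
                              delay_ms = cfg$transmission_delay_ms)
    for (k in seq_len(nrow(connections))) {
      pre_sp <- spike_trains[[connections$pre[k]]]
      hit <- pre_sp[stats::runif(length(pre_sp)) < connections$prob[k]]
      if (length(hit)) {
        d <- stats::rnorm(length(hit), cfg$transmission_delay_ms,
                          cfg$transmission_jitter_ms) / 1000
        d <- pmin(pmax(d, 0.001), 0.003)
        tr <- hit + d
        tr <- tr[tr < duration]
        spike_trains[[connections$post[k]]] <-
          sort(c(spike_trains[[connections$post[k]]], tr))
      }
    }
  }

  spike_trains <- lapply(spike_trains, function(st) unique(sort(st)))

  # surrogate LFP: theta while running, noise + ripple bursts while immobile
  lfp <- NULL
  true_ripples <- numeric()
  if (isTRUE(cfg$lfp)) {
    fs <- cfg$lfp_rate
    tl <- seq(0, duration - 1 / fs, by = 1 / fs)
    x <- stats::rnorm(length(tl), 0, cfg$lfp_noise_sd)
    run_l <- speed_at_time(sess_stub, tl) > 2
    phase_l <- theta_at(tl)  # deg, 0 = trough
    x <- x + ifelse(run_l, -cfg$theta_amp * cos(phase_l * pi / 180), 0)
    # immobility bouts for ripple placement
    imm <- !run_l
    r <- rle(imm)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (b in which(r$values & r$lengths / fs >= 0.6)) {
      t0 <- tl[starts[b]] + 0.1
      t1 <- tl[ends[b]] - 0.1
      if (t1 <= t0) next
      n_rip <- stats::rpois(1, cfg$ripple_rate_hz * (t1 - t0))
      if (n_rip == 0) next
      centers <- sort(stats::runif(n_rip, t0, t1))
      for (ctr in centers) {
        sigma <- cfg$ripple_duration_s / 4
        sel <- which(abs(tl - ctr) < 4 * sigma)
        x[sel] <- x[sel] + cfg$ripple_amp *
          exp(-(tl[sel] - ctr)^2 / (2 * sigma^2)) *
          sin(2 * pi * cfg$ripple_freq * (tl[sel] - ctr))
        true_ripples <- c(true_ripples, ctr)
      }
    }
    lfp <- lfp_channel(x, fs)
  }

  ap_locs <- unique(lap_plan$ap_location[!is.na(lap_plan$ap_location)])
  s <- session(
    session_id = sprintf("synth-seed%d", seed),
    track_length = cfg$track_length,
    spike_trains = spike_trains,
    behavior = behavior,
    events = events,
    lfp = lfp,
    context_intervals = data.frame(start = 0, end = duration,
                                   context = "disc"),
    unit_meta = data.frame(unit_id = units$unit_id,
                           half_width_ms = units$half_width_ms)
  )
  rr <- cfg$reward_reactivation
  reward_mod <- character()
  if (!is.null(rr)) {
    reward_mod <- units$unit_id[
      units$is_place &
        circ_track_dist(units$field_center_cm, cfg$reward_location,
                        cfg$track_length) <= rr$zone_cm]
  }
  truth <- list(units = units, assemblies = assemblies,
                assembly_events = assembly_events,
                connections = connections,
                ripples = true_ripples,
                reward_modulated = reward_mod,
                lap_plan = lap_plan, ap_locations = ap_locs,
                config = cfg)
  list(session = s, truth = truth)
}

#' Generate a population of independent homogeneous Poisson units
#'
#' The null model for detector calibration: no behavior correlation, no
#' stimulus coupling, no co-activation. The behavior trace is constant-speed
#' running around the track so occupancy-based operations remain usable.
#'
#' @param n_units number of units.
#' @param rate firing rate in Hz (recycled per unit).
#' @param duration session duration in seconds.
#' @param seed integer seed.
#' @return an `ephys_session`.
#' @export
generate_null_population <- function(n_units, rate, duration, seed = 1) {
  stopifnot(n_units >= 1, duration > 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  rate <- rep_len(rate, n_units)
  trains <- lapply(seq_len(n_units), function(i) {
    n <- stats::rpois(1, rate[i] * duration)
    unique(sort(stats::runif(n, 0, duration)))
  })
  names(trains) <- sprintf("u%03d", seq_len(n_units))
  dt <- 0.02
  t <- seq(0, duration - dt, by = dt)
  v <- 15
  pos <- (v * t) %% 190
  lap <- 1L + as.integer(floor(v * t / 190))
  behavior <- behavior_trace(t, pos, rep(v, length(t)), lap)
  session(session_id = sprintf("null-seed%d", seed), track_length = 190,
          spike_trains = trains, behavior = behavior, events = event_log())
}

#' Analytic expected tuning curve of a generated unit
#'
#' The generator's own rate map: expected running-state firing rate per 2 cm
#' bin (theta modulation averages to 1 over phase), used as the ground-truth
#' rate map in recovery and decoding tests.
#'
#' @param unit_row one row of `truth$units`.
#' @param config the generating [synth_config()].
#' @param bin_cm spatial bin width in cm.
#' @return numeric vector of expected rates (Hz), one per bin.
#' @export
true_rate_map <- function(unit_row, config, bin_cm = 2) {
  L <- config$track_length
  centers <- seq(bin_cm / 2, L - bin_cm / 2, by = bin_cm)
  r <- rep(unit_row$baseline_hz, length(centers))
  if (isTRUE(unit_row$is_place)) {
    sd_cm <- unit_row$field_width_fwhm_cm / (2 * sqrt(2 * log(2)))
    d <- circ_track_dist(centers, unit_row$field_center_cm, L)
    r <- r + unit_row$field_peak_hz * exp(-d^2 / (2 * sd_cm^2))
  }
  if (unit_row$class == "pyramidal") r <- r * (1 + config$pyr_burst_prob)
  r
}
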