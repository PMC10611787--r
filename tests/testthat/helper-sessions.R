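# Shared fixtures, generated once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, make(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# standard mid-size session: place cells, responses, connections, assemblies
std_session <- function() {
  fixture("std", function() {
    generate_session(
      synth_config(n_pyramidal = 30, n_interneuron = 6, n_connections = 5,
                   n_assemblies = 2, assembly_size = 6),
      seed = 11)
  })
}

# small fast session without LFP
small_session <- function() {
  fixture("small", function() {
    generate_session(
      synth_config(n_pyramidal = 12, n_interneuron = 3, no_stim_laps = 5,
                   n_ap_locations = 2, trials_per_location = 6, lfp = FALSE),
      seed = 4)
  })
}

# hand-built minimal session: 2 units, simple behavior
toy_session <- function() {
  dt <- 0.02
  t <- seq(0, 60 - dt, by = dt)
  v <- 15
  pos <- (v * t) %% 190
  lap <- 1L + as.integer(floor(v * t / 190))
  behavior <- behavior_trace(t, pos, rep(v, length(t)), lap)
  session(
    session_id = "toy", track_length = 190,
    spike_trains = list(a = c(1, 2.5, 10, 30), b = seq(0.5, 59, by = 0.5)),
    behavior = behavior, events = event_log()
  )
}

# synthetic peri-event response object with a prescribed post-onset z trace
fake_response <- function(z_post, bin_s = 0.02, window = c(-4, 4)) {
  starts <- seq(window[1], window[2] - bin_s, by = bin_s)
  z <- numeric(length(starts))
  post <- which(starts >= 0)
  z[post[seq_along(z_post)]] <- z_post
  structure(list(bin_start = starts, bin_s = bin_s,
                 rate = z + 2, zscore = z, baseline_mean = 2,
                 baseline_sd = 1, n_trials = 10, flat_baseline = FALSE),
            class = "peri_event_response")
}
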