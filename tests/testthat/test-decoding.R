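test_that("theta cycles are trough-to-trough and gated by sustained running", {
  fs <- 1000
  dur <- 60
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  lfp <- lfp_channel(-cos(2 * pi * 8 * t) + rnorm(length(t), 0, 0.05), fs)
  bt <- seq(0, dur - 0.02, by = 0.02)
  behavior <- behavior_trace(bt, (15 * bt) %% 190, rep(15, length(bt)),
                             1L + as.integer(floor(15 * bt / 190)))
  cyc <- segment_theta_cycles(lfp, behavior)
  expect_gt(nrow(cyc), 400)
  expect_lt(max(abs(cyc$duration - 0.125)), 0.01)
  # all-immobile session: no cycles
  beh0 <- behavior_trace(bt, rep(10, length(bt)), rep(0, length(bt)), 1L)
  expect_identical(nrow(segment_theta_cycles(lfp, beh0)), 0L)
  # speed crossing mid-session keeps only cycles inside qualifying runs
  spd <- ifelse(bt < 30, 15, 0)
  beh_half <- behavior_trace(bt, (cumsum(spd) * 0.02) %% 190, spd,
                             1L + as.integer(floor(cumsum(spd) * 0.02 / 190)))
  cyc_half <- segment_theta_cycles(lfp, beh_half)
  expect_true(all(cyc_half$end <= 30 + 0.02))
  expect_gt(nrow(cyc_half), 200)
})

test_that("Bayesian decoding honors one-hot and uniform rate maps", {
  # one unit, one-hot rate map, 3 spikes: MAP at its field bin
  maps <- matrix(0.0, 1, 95)
  maps[1, 40] <- 10
  post <- bayes_decode(3, maps, tau = 0.125)
  expect_identical(which.max(post), 40L)
  expect_equal(sum(post), 1, tolerance = 1e-9)
  # all units uniform: posterior uniform
  maps_u <- matrix(2, 5, 95)
  post_u <- bayes_decode(c(1, 0, 2, 1, 0), maps_u, tau = 0.125)
  expect_lt(diff(range(post_u)), 1e-12)
})

test_that("log-domain decoder equals the direct-product oracle", {
  set.seed(51)
  worst <- 0
  for (i in 1:20) {
    n_units <- 8
    n_bins <- 20
    maps <- matrix(rexp(n_units * n_bins, 1 / 3), n_units, n_bins)
    counts <- rpois(n_units, 1)
    tau <- 0.125
    post <- bayes_decode(counts, maps, tau)
    f <- maps + 0.01
    direct <- apply(f, 2, function(fx) prod(fx^counts) * exp(-tau * sum(fx)))
    direct <- direct / sum(direct)
    worst <- max(worst, max(abs(post - direct)))
  }
  expect_lt(worst, 1e-8)
})

test_that("decoding is equivariant under circular rotation of maps", {
  set.seed(52)
  maps <- matrix(rexp(10 * 95, 1 / 3), 10, 95)
  counts <- rpois(10, 2)
  post <- bayes_decode(counts, maps, 0.125)
  shift <- 17
  maps_rot <- maps[, c((95 - shift + 1):95, 1:(95 - shift))]
  post_rot <- bayes_decode(counts, maps_rot, 0.125)
  expect_equal(post_rot, post[c((95 - shift + 1):95, 1:(95 - shift))],
               tolerance = 1e-10)
})

test_that("decoding error shrinks with population size and training data", {
  g <- fixture("dec40", function() {
    generate_session(
      synth_config(n_pyramidal = 40, n_interneuron = 0, place_cell_frac = 1,
                   frac_activated = 0, frac_suppressed = 0,
                   n_ap_locations = 0, no_stim_laps = 12), seed = 3)
  })
  s <- g$session
  maps_true <- t(vapply(seq_len(nrow(g$truth$units)), function(i)
    true_rate_map(g$truth$units[i, ], g$truth$config), numeric(95)))
  rownames(maps_true) <- g$truth$units$unit_id
  cyc <- segment_theta_cycles(s$lfp, s$behavior)
  dec40 <- decode_cycles(s, cyc, maps_true)
  expect_lte(median(dec40$cycles$error_cm), 4)
  # subsampling the population degrades the decoder
  dec10 <- decode_cycles(s, cyc, maps_true[1:10, ])
  expect_gt(median(dec10$cycles$error_cm), median(dec40$cycles$error_cm))
  # error profile covers the track
  prof <- decoding_error_profile(dec40)
  expect_identical(nrow(prof), 95L)
  expect_gt(sum(!is.na(prof$mean_error_cm)), 80)
})

test_that("shuffled rate maps decode at chance level", {
  g <- fixture("dec40", function() {
    generate_session(
      synth_config(n_pyramidal = 40, n_interneuron = 0, place_cell_frac = 1,
                   frac_activated = 0, frac_suppressed = 0,
                   n_ap_locations = 0, no_stim_laps = 12), seed = 3)
  })
  s <- g$session
  maps_true <- t(vapply(seq_len(nrow(g$truth$units)), function(i)
    true_rate_map(g$truth$units[i, ], g$truth$config), numeric(95)))
  rownames(maps_true) <- g$truth$units$unit_id
  set.seed(53)
  maps_shuf <- maps_true[, sample(95)]
  cyc <- segment_theta_cycles(s$lfp, s$behavior)
  dec <- decode_cycles(s, cyc[1:200, ], maps_shuf)
  # chance mean circular error is track_length/4
  expect_gt(mean(dec$cycles$error_cm), 190 / 4 * 0.6)
})

test_that("quintile partition sizes differ by at most one", {
  g <- fixture("dec40", function() {
    generate_session(
      synth_config(n_pyramidal = 40, n_interneuron = 0, place_cell_frac = 1,
                   frac_activated = 0, frac_suppressed = 0,
                   n_ap_locations = 0, no_stim_laps = 12), seed = 3)
  })
  s <- g$session
  maps_true <- t(vapply(seq_len(nrow(g$truth$units)), function(i)
    true_rate_map(g$truth$units[i, ], g$truth$config), numeric(95)))
  rownames(maps_true) <- g$truth$units$unit_id
  cyc <- segment_theta_cycles(s$lfp, s$behavior)
  dec <- decode_cycles(s, cyc, maps_true)
  # treat every cycle as eligible: fake onsets covering the session, zone
  # centered on the whole track is not allowed, so use the true reward zone
  q <- quintile_tuning_decomposition(dec, maps_true,
                                     ap_onsets = seq(10, 150, by = 10),
                                     reward_location = 150, zone_cm = 95 / 2)
  expect_true(!is.null(q))
  expect_lte(diff(range(table(q$quintile))), 1)
  expect_identical(nrow(q$mean_curves), 5L)
})
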