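test_that("a uniform-rate runner has a flat tuning curve", {
  s <- generate_null_population(1, 3, 1200, seed = 9)
  tc <- tuning_curve(s$spike_trains[[1]], s$behavior)
  expect_true(all(abs(tc$rate - 3) < 1.5))        # sampling error per bin
  expect_equal(tc$mean_rate, 3, tolerance = 0.1)
  expect_equal(sum(tc$p), 1, tolerance = 1e-9)
  expect_lt(spatial_information(tc), 0.1)
  # zero spikes -> all-zero curve, no fields
  tc0 <- tuning_curve(numeric(0), s$behavior)
  expect_true(all(tc0$rate[!is.na(tc0$rate)] == 0))
  expect_identical(nrow(detect_place_fields(tc0)), 0L)
})

test_that("spatial information matches its closed-form cases", {
  # uniform rate: zero bits regardless of occupancy
  tc_uniform <- list(p = c(0.1, 0.2, 0.3, 0.4), rate = rep(4, 4),
                     mean_rate = 4)
  expect_identical(spatial_information(tc_uniform), 0)
  # 4 equally occupied bins, rates (4,0,0,0): 2 bits
  tc_onehot <- list(p = rep(0.25, 4), rate = c(4, 0, 0, 0), mean_rate = 1)
  expect_identical(spatial_information(tc_onehot), 2)
  # undefined for a silent unit
  expect_true(is.na(spatial_information(list(p = rep(0.25, 4),
                                             rate = rep(0, 4),
                                             mean_rate = 0))))
})

test_that("spatial information equals a brute-force oracle on random curves", {
  set.seed(13)
  worst <- 0
  for (i in 1:200) {
    n <- sample(10:95, 1)
    p <- runif(n); p <- p / sum(p)
    rate <- rpois(n, 3) * runif(n)
    F_ <- sum(p * rate)
    if (F_ == 0) next
    oracle <- 0
    for (j in seq_len(n)) {
      if (rate[j] > 0) {
        oracle <- oracle + p[j] * (rate[j] / F_) * log2(rate[j] / F_)
      }
    }
    si <- spatial_information(list(p = p, rate = rate, mean_rate = F_))
    worst <- max(worst, abs(si - oracle))
    expect_gte(si, -1e-12)
  }
  expect_lt(worst, 1e-12)
})

test_that("place-field detection follows the 5%-of-peak, 3-bin rule", {
  mk_tc <- function(rate) {
    n <- length(rate)
    structure(list(rate = rate, p = rep(1 / n, n),
                   occupancy_s = rep(1, n), mean_rate = mean(rate),
                   centers = seq(1, 2 * n - 1, by = 2), bin_cm = 2,
                   track_length = 2 * n),
              class = "tuning_curve")
  }
  # one 2-bin suprathreshold run -> no field
  r <- rep(0.01, 95); r[40:41] <- 10
  expect_identical(nrow(detect_place_fields(mk_tc(r))), 0L)
  # a 10-bin bump -> one field spanning the threshold crossings
  r2 <- rep(0.01, 95); r2[41:50] <- c(1, 3, 6, 9, 10, 10, 9, 6, 3, 1)
  f2 <- detect_place_fields(mk_tc(r2))
  expect_identical(nrow(f2), 1L)
  expect_identical(f2$start_bin, 41L)
  expect_identical(f2$end_bin, 50L)
  # bump straddling the wrap -> one field with start_bin > end_bin
  r3 <- rep(0.01, 95); r3[c(93:95, 1:3)] <- c(2, 6, 10, 10, 6, 2)
  f3 <- detect_place_fields(mk_tc(r3))
  expect_identical(nrow(f3), 1L)
  expect_gt(f3$start_bin, f3$end_bin)
  expect_identical(f3$start_bin, 93L)
  expect_identical(f3$end_bin, 3L)
  # two disjoint bumps -> two fields
  r4 <- rep(0.01, 95); r4[10:14] <- 8; r4[60:66] <- 5
  expect_identical(nrow(detect_place_fields(mk_tc(r4))), 2L)
  # uniform suprathreshold curve is rejected as non-specific
  f5 <- detect_place_fields(mk_tc(rep(5, 95)))
  expect_identical(nrow(f5), 0L)
  expect_true(isTRUE(attr(f5, "non_specific")))
})

test_that("spatial operations commute with circular track rotation", {
  g <- std_session()
  s <- g$session
  pc <- g$truth$units[g$truth$units$is_place, ][1, ]
  delta <- 48
  s_rot <- s
  s_rot$behavior$position <- (s$behavior$position + delta) %% s$track_length
  tc <- tuning_curve(s$spike_trains[[pc$unit_id]], s$behavior)
  tc_rot <- tuning_curve(s_rot$spike_trains[[pc$unit_id]], s_rot$behavior)
  f <- detect_place_fields(tc)
  f_rot <- detect_place_fields(tc_rot)
  expect_identical(nrow(f), nrow(f_rot))
  expect_lt(circ_track_dist(f_rot$center_cm[1],
                            (f$center_cm[1] + delta) %% 190, 190), 2.1)
})

test_that("map correlation behaves on self, shifted and remapped curves", {
  g <- std_session()
  s <- g$session
  pc <- g$truth$units[g$truth$units$is_place, ][2, ]
  tc <- tuning_curve(s$spike_trains[[pc$unit_id]], s$behavior)
  expect_equal(map_correlation(tc, tc), 1)
  # half-track circular shift of a single-field cell anticorrelates
  tc_shift <- tc
  tc_shift$rate <- c(tc$rate[48:95], tc$rate[1:47])
  expect_lt(map_correlation(tc, tc_shift), 0)
})

test_that("split-half stability accepts stable fields and rejects noise", {
  g <- std_session()
  s <- g$session
  plan <- split_epochs(s$events, s$behavior)
  ns1 <- plan[plan$label == "no_stim", ][1, ]
  pcs <- g$truth$units[g$truth$units$is_place &
                         g$truth$units$response == "none", ]
  stable <- vapply(pcs$unit_id, function(uid) {
    field_stability(s$spike_trains[[uid]], s$behavior, 190,
                    c(ns1$lap_start, ns1$lap_end))$stable
  }, logical(1))
  expect_gte(mean(stable), 0.9)
  # independent Poisson units are almost never stable
  null_flags <- vapply(1:20, function(seed) {
    sn <- generate_null_population(1, 2, 300, seed = seed)
    isTRUE(field_stability(sn$spike_trains[[1]], sn$behavior, 190,
                           range(sn$behavior$lap))$stable)
  }, logical(1))
  expect_lte(mean(null_flags), 0.1)
})

test_that("place-cell flags recover ground truth", {
  g <- std_session()
  flags <- place_cell_flags(g$session)
  tu <- g$truth$units
  is_pc <- tu$is_place & tu$response != "suppressed"
  sens <- mean(flags[tu$unit_id[is_pc]])
  specificity <- 1 - mean(flags[tu$unit_id[!tu$is_place]])
  expect_gte(sens, 0.9)
  expect_gte(specificity, 0.9)
})

test_that("field shift categorizes stable, vanished and remapped fields", {
  f_pre <- data.frame(start_bin = 10L, end_bin = 20L, n_bins = 11L,
                      peak_hz = 8, center_cm = 30, width_cm = 22)
  f_same <- f_pre
  out <- field_shift(f_pre, f_same, ap_location = 100)
  expect_identical(out$category, "stable")
  expect_identical(out$d_pre, out$d_post)
  empty <- f_pre[0, ]
  expect_identical(field_shift(f_pre, empty, 100)$category, "vanished")
  expect_identical(field_shift(empty, f_pre, 100)$category, "emerged")
  f_moved <- f_pre; f_moved$center_cm <- 60
  out2 <- field_shift(f_pre, f_moved, 100)
  expect_identical(out2$category, "remapped")
  expect_equal(out2$shift_cm, 30)
  expect_true(out$d_pre >= 0 && out$d_pre <= 95)
})

test_that("in-field versus out-of-field responses split by puff location", {
  g <- std_session()
  s <- g$session
  # a non-responsive, non-place unit: both sides near zero
  tu <- g$truth$units
  uid <- tu$unit_id[!tu$is_place & tu$response == "none" &
                      tu$class == "pyramidal"][1]
  tc <- tuning_curve(s$spike_trains[[uid]], s$behavior)
  fake_fields <- data.frame(start_bin = 1L, end_bin = 20L, n_bins = 20L,
                            peak_hz = 1, center_cm = 20, width_cm = 40)
  io <- infield_outfield_response(s$spike_trains[[uid]], s$events,
                                  fake_fields, tc)
  vals <- c(io$z_infield, io$z_outfield)
  expect_true(all(abs(vals[!is.na(vals)]) < 1))
  expect_identical(io$n_infield + io$n_outfield,
                   sum(s$events$event_type == "air_puff"))
})
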