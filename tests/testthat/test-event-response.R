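test_that("peri-event z-scoring matches its definition and is shift-invariant", {
  set.seed(2)
  onsets <- seq(20, 580, by = 20)
  spikes <- unique(sort(runif(1200, 0, 600)))  # ~2 Hz baseline
  r <- peri_event_zscore(spikes, onsets)
  base <- r$bin_start < 0
  expect_equal(mean(r$zscore[base]), 0, tolerance = 1e-10)
  expect_equal(sd(r$zscore[base]), 1, tolerance = 1e-10)
  expect_equal(r$zscore,
               (r$rate - r$baseline_mean) / r$baseline_sd, tolerance = 1e-12)
  # uniform time shift of spikes and onsets leaves the z trace unchanged
  r2 <- peri_event_zscore(spikes + 11.5, onsets + 11.5)
  expect_equal(r2$zscore, r$zscore, tolerance = 1e-12)
})

test_that("silent units are flagged flat-baseline with class none", {
  onsets <- seq(20, 200, by = 20)
  r <- peri_event_zscore(numeric(0), onsets)
  expect_true(r$flat_baseline)
  ev <- event_log("air_puff", onsets, 0.2, 40, 1L)
  resp <- detect_event_response(numeric(0), ev)
  expect_identical(resp$class, "none")
  expect_true("flat-baseline" %in% resp$flags)
})

test_that("activation needs z > 2 for 3 consecutive bins at enough locations", {
  run3 <- fake_response(c(0, 0, 2.5, 2.6, 2.4, 0))   # 60 ms run
  run2 <- fake_response(c(0, 0, 2.5, 2.6, 0, 0))     # 40 ms run only
  flat <- fake_response(rep(0, 10))
  # 60 ms at 3 of 4 locations -> activated
  expect_true(detect_activation(list(run3, run3, run3, flat))$activated)
  # 40 ms runs never count
  expect_false(detect_activation(list(run2, run2, run2, run2))$activated)
  # 1 of 3 positive is not enough; 2 of 3 is
  expect_false(detect_activation(list(run3, flat, flat))$activated)
  expect_true(detect_activation(list(run3, run3, flat))$activated)
  # 2-location sessions require 2 of 2
  expect_true(detect_activation(list(run3, run3))$activated)
  expect_false(detect_activation(list(run3, flat))$activated)
})

test_that("suppression needs a sustained z < -1 drop", {
  drop10 <- fake_response(rep(-1.5, 10))             # 200 ms
  drop4 <- fake_response(rep(-1.5, 4))               # 80 ms: too short
  flat <- fake_response(rep(0, 10))
  expect_true(detect_suppression(list(drop10, drop10, flat))$suppressed)
  expect_false(detect_suppression(list(drop4, drop4, drop4))$suppressed)
  expect_false(detect_suppression(list(drop10, flat, flat))$suppressed)
})

test_that("response window anchors on the detection run", {
  # isolated early z>1 bin must not anchor latency/duration
  z <- c(1.2, 0, 0, 0, 1.5, 2.5, 2.5, 2.5, 2.5, 1.5, 0.5, 0.2)
  r <- fake_response(z)
  expect_equal(response_duration(r, "activated"), 6 * 0.02)
  # 100 ms of z>2 then below 1 -> 0.10 s
  r2 <- fake_response(c(2.5, 2.5, 2.5, 2.5, 2.5, 0.2, 0.1))
  expect_equal(response_duration(r2, "activated"), 0.10)
})

test_that("latency is the mean first-spike time in the starting bin", {
  onsets <- seq(20, 310, by = 10)
  # strong response: 4 spikes per trial at 25, 45, 65, 85 ms; sparse baseline
  set.seed(3)
  baseline <- runif(600, 0, 320)
  spikes <- sort(unique(c(baseline,
                          rep(onsets, each = 4) + c(0.025, 0.045, 0.065, 0.085))))
  ev <- event_log("air_puff", onsets, 0.2, 40, 1L)
  resp <- detect_event_response(spikes, ev)
  expect_identical(resp$class, "activated")
  expect_equal(resp$latency_s, 0.025, tolerance = 0.005)
  # spikes at 5 ms -> starting bin is the first bin, latency 5 ms
  spikes2 <- sort(unique(c(baseline,
                           rep(onsets, each = 4) + c(0.005, 0.02, 0.04, 0.06))))
  resp2 <- detect_event_response(spikes2, ev)
  expect_equal(resp2$latency_s, 0.005, tolerance = 0.005)
})

test_that("injected responses are recovered with correct parameters", {
  g <- std_session()
  s <- g$session
  tu <- g$truth$units
  rt <- event_responses(s)
  m <- merge(rt, tu, by = "unit_id")
  act <- m[m$response == "activated", ]
  sup <- m[m$response == "suppressed", ]
  expect_true(all(act$class.x %in% c("activated", "biphasic")))
  # suppressed place cells are harder (field crossings inflate the baseline
  # SD), so demand recovery of most, and no sign confusion
  expect_gte(mean(sup$class.x == "suppressed"), 0.6)
  expect_false(any(sup$class.x %in% c("activated", "biphasic")))
  # magnitude grows with injected gain (monotone recovery: activated units
  # have far larger magnitudes than unaffected ones)
  none_mag <- abs(m$magnitude_z[m$response == "none"])
  expect_gt(min(act$magnitude_z), max(c(none_mag, 0), na.rm = TRUE))
})

test_that("group fractions reproduce printed percentages", {
  expect_identical(group_fraction(136, 851), 16.0)
  expect_identical(group_fraction(0, 100), 0)
  expect_identical(group_fraction(26, 336), 7.7)
})

test_that("nomenclature composes response, cell type and place flag", {
  units <- data.frame(unit_id = c("a", "b", "c", "d"),
                      class = c("pyramidal", "pyramidal", "interneuron",
                                "unclassified"))
  resp <- data.frame(unit_id = c("a", "b", "c", "d"),
                     class = c("activated", "none", "biphasic", "activated"))
  flags <- c(a = FALSE, b = TRUE, c = FALSE, d = FALSE)
  g <- assign_nomenclature(units, resp, flags)
  expect_identical(g$group[g$unit_id == "a"], "aAP-nPC")
  expect_identical(g$group[g$unit_id == "b"], "nAP-PC")
  expect_identical(g$group[g$unit_id == "c"], "aiAP-IN")
  expect_true(is.na(g$group[g$unit_id == "d"]))
})

test_that("context comparison pairs units and handles disjoint sets", {
  ra <- data.frame(unit_id = c("a", "b"), magnitude_z = c(3, 1),
                   duration_s = c(0.5, 0.2))
  rb <- data.frame(unit_id = c("a", "b"), magnitude_z = c(3, 1),
                   duration_s = c(0.5, 0.2))
  cc <- context_response_compare(ra, rb)
  expect_equal(cc$delta_magnitude, c(0, 0))
  expect_equal(cc$delta_duration, c(0, 0))
  rc <- data.frame(unit_id = c("x"), magnitude_z = 2, duration_s = 1)
  expect_warning(out <- context_response_compare(ra, rc), "no units shared")
  expect_identical(nrow(out), 0L)
})
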