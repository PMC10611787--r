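# build an LFP + behavior pair with prescribed immobility and optional bursts
make_lfp_session <- function(duration = 60, fs = 1000, noise_sd = 0.3,
                             bursts = NULL, seed = 1,
                             imm = data.frame(start = 20, end = 40)) {
  set.seed(seed)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- rnorm(length(t), 0, noise_sd)
  if (!is.null(bursts)) {
    for (i in seq_len(nrow(bursts))) {
      ctr <- bursts$center[i]
      sigma <- bursts$dur[i] / 4
      sel <- which(abs(t - ctr) < 5 * sigma)
      x[sel] <- x[sel] + bursts$amp[i] *
        exp(-(t[sel] - ctr)^2 / (2 * sigma^2)) *
        sin(2 * pi * 150 * (t[sel] - ctr))
    }
  }
  bt <- seq(0, duration - 0.02, by = 0.02)
  spd <- rep(15, length(bt))
  for (i in seq_len(nrow(imm))) {
    spd[bt >= imm$start[i] & bt <= imm$end[i]] <- 0
  }
  pos <- (cumsum(spd) * 0.02) %% 190
  behavior <- behavior_trace(bt, pos, spd, 1L + as.integer(cumsum(
    c(0, diff(pos) < -100))))
  list(lfp = lfp_channel(x, fs), behavior = behavior)
}

test_that("ripple detection finds injected bursts and rejects short ones", {
  ok <- make_lfp_session(bursts = data.frame(center = 30, dur = 0.030,
                                             amp = 3), seed = 2)
  rip <- detect_ripples(ok$lfp, ok$behavior)
  hit <- rip$start < 30 & rip$stop > 30
  expect_identical(sum(hit), 1L)
  expect_gte(rip$peak_magnitude[hit], 5)
  # the same burst during running is ignored (ripples are
  # immobility-restricted)
  run <- make_lfp_session(bursts = data.frame(center = 10, dur = 0.030,
                                              amp = 3), seed = 2)
  rip_run <- detect_ripples(run$lfp, run$behavior)
  expect_false(any(rip_run$start < 10.1 & rip_run$stop > 9.9))
  # events shorter than the minimal duration are discarded: the suprathreshold
  # envelope of the injected burst lasts ~34 ms, so a 50 ms minimum drops it
  rip_min <- detect_ripples(ok$lfp, ok$behavior, min_duration_s = 0.050)
  expect_false(any(rip_min$start < 30 & rip_min$stop > 30))
})

test_that("ripple detection is null-calibrated and scale-invariant", {
  zeros <- vapply(1:10, function(seed) {
    nl <- make_lfp_session(seed = seed + 10)
    nrow(detect_ripples(nl$lfp, nl$behavior))
  }, numeric(1))
  expect_gte(mean(zeros == 0), 0.9)
  # amplitude scaling leaves detections unchanged (thresholds in SD units)
  bb <- make_lfp_session(bursts = data.frame(center = 30, dur = 0.04,
                                             amp = 3), seed = 5)
  r1 <- detect_ripples(bb$lfp, bb$behavior)
  lfp10 <- lfp_channel(bb$lfp$samples * 10, bb$lfp$sample_rate)
  r2 <- detect_ripples(lfp10, bb$behavior)
  expect_equal(r1$start, r2$start)
  expect_equal(r1$peak_magnitude, r2$peak_magnitude, tolerance = 1e-8)
})

test_that("theta phase convention puts troughs at 0 and peaks at 180 degrees", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  lfp <- lfp_channel(-cos(2 * pi * 8 * t), fs)
  troughs <- seq(1 / 8, 9.5, by = 1 / 8)   # x = -cos: trough at cycle start
  ph_tr <- theta_phase(lfp, troughs)
  expect_true(all(pmin(ph_tr, 360 - ph_tr) < 5))
  ph_pk <- theta_phase(lfp, troughs + 1 / 16)
  expect_true(all(abs(ph_pk - 180) < 5))
  expect_warning(theta_phase(lfp, c(5, 100)), "outside the LFP span")
})

test_that("phase preference gives circular mean and variance", {
  p <- phase_preference(rep(90, 20))
  expect_equal(p$mean_deg, 90)
  expect_equal(p$circ_var, 0, tolerance = 1e-12)
  set.seed(31)
  u <- runif(5000, 0, 360)
  expect_lt(phase_preference(u)$resultant, 0.05)
  # von Mises sample around 30 degrees
  vm <- (30 + 180 / pi * atan2(rnorm(500, 0, 0.5), 1 + rnorm(500, 0, 0.1))) %% 360
  expect_lt(abs(circ_diff_deg(phase_preference(vm)$mean_deg, 30)), 10)
  expect_true(is.na(phase_preference(rep(10, 5))$mean_deg))
})

test_that("circular-linear regression recovers noiseless and noisy slopes", {
  set.seed(32)
  x <- runif(200, 0, 30)
  ph <- (-8 * x + 180) %% 360
  f <- fit_phase_precession(x, ph)
  expect_equal(f$slope, -8, tolerance = 0.2)
  expect_lt(abs(circ_diff_deg(f$offset_deg, 180)), 5)
  expect_true(f$significant)
  expect_equal(f$start_phase_deg,
               (f$offset_deg + f$slope * min(x)) %% 360)
  # constant phase: slope 0, resultant 1
  f0 <- fit_phase_precession(x, rep(120, 200))
  expect_equal(f0$slope, 0, tolerance = 1e-6)
  expect_equal(f0$resultant, 1, tolerance = 1e-9)
  # degenerate x: null fit
  fn <- fit_phase_precession(rep(1, 50), runif(50, 0, 360))
  expect_true(is.na(fn$slope))
  # noisy recovery within 10%
  ph_noisy <- (ph + rnorm(200, 0, 40)) %% 360
  fnz <- fit_phase_precession(x, ph_noisy)
  expect_lt(abs(fnz$slope - (-8)) / 8, 0.1)
})

test_that("permutation test is calibrated on shuffled phases", {
  set.seed(33)
  x <- runif(100, 0, 30)
  hits <- vapply(1:20, function(i) {
    ph <- runif(100, 0, 360)
    fit_phase_precession(x, ph, n_perm = 500, seed = i)$significant
  }, logical(1))
  expect_lte(mean(hits), 0.15)
})

test_that("phase operations are equivariant under global phase rotation", {
  set.seed(34)
  x <- runif(150, 0, 25)
  ph <- (-6 * x + 90 + rnorm(150, 0, 20)) %% 360
  f1 <- fit_phase_precession(x, ph)
  f2 <- fit_phase_precession(x, (ph + 40) %% 360)
  expect_equal(f2$slope, f1$slope, tolerance = 0.2)
  expect_lt(abs(circ_diff_deg(f2$offset_deg, f1$offset_deg + 40)), 5)
  expect_equal(f2$phase_range_deg, f1$phase_range_deg, tolerance = 5)
  p1 <- phase_preference(ph)
  p2 <- phase_preference((ph + 40) %% 360)
  expect_lt(abs(circ_diff_deg(p2$mean_deg, p1$mean_deg + 40)), 1e-6)
})

test_that("ripple participation matches closed-form expectations", {
  rip <- data.frame(start = c(10, 20, 30), peak = c(10.02, 20.02, 30.02),
                    stop = c(10.05, 20.05, 30.05), peak_magnitude = 4)
  bt <- seq(0, 40, by = 0.02)
  behavior <- behavior_trace(bt, rep(0, length(bt)), rep(0, length(bt)), 1L)
  # unit firing in every ripple
  sp <- c(10.01, 20.01, 30.01)
  rp <- ripple_participation(sp, rip, behavior)
  expect_equal(rp$participation, 1)
  # silent during immobility
  rp0 <- ripple_participation(numeric(0), rip, behavior)
  expect_equal(rp0$participation, 0)
  # Poisson unit: participation ~ 1 - exp(-r * dbar)
  set.seed(35)
  rip2 <- data.frame(start = seq(5, 395, by = 2))
  rip2$stop <- rip2$start + 0.05
  rip2$peak <- rip2$start + 0.02
  rip2$peak_magnitude <- 4
  bt2 <- seq(0, 400, by = 0.02)
  beh2 <- behavior_trace(bt2, rep(0, length(bt2)), rep(0, length(bt2)), 1L)
  r <- 20
  sp2 <- unique(sort(runif(r * 400, 0, 400)))
  rp2 <- ripple_participation(sp2, rip2, beh2)
  p_exp <- 1 - exp(-r * 0.05)
  se <- sqrt(p_exp * (1 - p_exp) / nrow(rip2))
  expect_lt(abs(rp2$participation - p_exp), 3 * se)
  ratio_exp <- sum(rip2$stop - rip2$start) / 400
  expect_lt(abs(rp2$ripple_quiet_spike_ratio - ratio_exp), 0.01)
})
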