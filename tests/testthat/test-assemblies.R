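test_that("binned z-scored matrix has exact row moments and drops flat units", {
  set.seed(41)
  trains <- list(a = sort(runif(500, 0, 100)),
                 b = sort(runif(800, 0, 100)),
                 flat = numeric(0))
  pm <- bin_and_zscore(trains, 0.025, c(0, 100))
  expect_identical(pm$dropped, "flat")
  expect_lt(max(abs(rowMeans(pm$Z))), 1e-10)
  expect_lt(max(abs(apply(pm$Z, 1, sd) - 1)), 1e-10)
})

test_that("exclusion mask removes exactly the masked bins", {
  trains <- list(a = sort(runif(400, 0, 100)), b = sort(runif(400, 0, 100)))
  excl <- data.frame(start = 20, end = 30)
  pm_full <- bin_and_zscore(trains, 0.025, c(0, 100))
  pm_masked <- bin_and_zscore(trains, 0.025, c(0, 100), exclude = excl)
  removed <- sum(pm_full$bin_centers >= 20 & pm_full$bin_centers <= 30)
  expect_identical(ncol(pm_full$Z) - ncol(pm_masked$Z), removed)
  expect_false(any(pm_masked$bin_centers >= 20 & pm_masked$bin_centers <= 30))
})

test_that("duplicated units force at least one significant component", {
  set.seed(42)
  base <- sort(runif(3000, 0, 600))
  trains <- c(list(dup1 = base, dup2 = base),
              lapply(1:10, function(i) sort(runif(3000, 0, 600))))
  names(trains)[3:12] <- paste0("u", 1:10)
  pm <- bin_and_zscore(trains, 0.025, c(0, 600))
  expect_gte(significant_component_count(pm), 1)
})

test_that("embedded assemblies are counted and their members recovered", {
  cfg <- synth_config(n_pyramidal = 50, n_interneuron = 0,
                      place_cell_frac = 0, theta_mod_depth = 0,
                      pyr_burst_prob = 0, frac_activated = 0,
                      frac_suppressed = 0, n_assemblies = 3,
                      assembly_size = 8, n_ap_locations = 0,
                      no_stim_laps = 45, reward_pause_s = 0.5, lfp = FALSE)
  g <- generate_session(cfg, seed = 14)
  pm <- bin_and_zscore(g$session$spike_trains, 0.025,
                       c(0, session_duration(g$session)))
  k <- as.integer(significant_component_count(pm))
  expect_identical(k, 3L)
  pats <- extract_assemblies(pm, k, seed = 14)
  expect_lt(max(abs(sqrt(colSums(pats$weights^2)) - 1)), 1e-9)
  jac <- vapply(seq_len(k), function(j) {
    max(vapply(g$truth$assemblies, function(m) {
      length(intersect(pats$members[[j]], m)) /
        length(union(pats$members[[j]], m))
    }, numeric(1)))
  }, numeric(1))
  expect_gte(mean(jac), 0.7)
  # disjoint true assemblies give near-orthogonal recovered patterns
  cross <- abs(crossprod(pats$weights))
  diag(cross) <- 0
  expect_lt(max(cross), 0.4)
})

test_that("unit relabeling permutes assembly weights identically", {
  cfg <- synth_config(n_pyramidal = 20, n_interneuron = 0,
                      place_cell_frac = 0, theta_mod_depth = 0,
                      pyr_burst_prob = 0, frac_activated = 0,
                      frac_suppressed = 0, n_assemblies = 1,
                      assembly_size = 5, n_ap_locations = 0,
                      no_stim_laps = 20, reward_pause_s = 0.5, lfp = FALSE)
  g <- generate_session(cfg, seed = 15)
  dur <- session_duration(g$session)
  pm1 <- bin_and_zscore(g$session$spike_trains, 0.025, c(0, dur))
  perm <- rev(seq_along(g$session$spike_trains))
  pm2 <- bin_and_zscore(g$session$spike_trains[perm], 0.025, c(0, dur))
  k <- max(significant_component_count(pm1), 1)
  p1 <- extract_assemblies(pm1, k, seed = 3)
  p2 <- extract_assemblies(pm2, k, seed = 3)
  m <- match(p1$unit_ids, p2$unit_ids)
  agree <- vapply(seq_len(k), function(j) {
    max(abs(crossprod(p2$weights[m, , drop = FALSE], p1$weights[, j])))
  }, numeric(1))
  expect_true(all(agree > 0.99))
})

test_that("reactivation strength follows its algebraic identity", {
  n <- 12
  w <- rep(1 / sqrt(n), n)
  pm <- list(Z = matrix(w, n, 1), bin_centers = 0.0125, bin_s = 0.025)
  rs <- reactivation_strength(w, pm, threshold = 5)
  # z(t) = w exactly: R = 1 - sum(w_i^4) = 1 - 1/n for uniform members
  expect_equal(rs$strength, 1 - sum(w^4), tolerance = 1e-12)
  expect_equal(rs$strength, 1 - 1 / n, tolerance = 1e-12)
  # z orthogonal to w: only the (negative) diagonal term remains
  z_orth <- c(1, -1, rep(0, n - 2)) / sqrt(2)
  pm2 <- list(Z = matrix(z_orth, n, 1), bin_centers = 0.0125, bin_s = 0.025)
  rs2 <- reactivation_strength(w, pm2, threshold = 5)
  expect_equal(rs2$strength, -sum(w^2 * z_orth^2), tolerance = 1e-12)
  expect_error(reactivation_strength(w[-1], pm), "mismatched unit registries")
})

test_that("injected coactivation events are recovered as reactivation peaks", {
  cfg <- synth_config(n_pyramidal = 30, n_interneuron = 0,
                      place_cell_frac = 0, theta_mod_depth = 0,
                      pyr_burst_prob = 0, frac_activated = 0,
                      frac_suppressed = 0, n_assemblies = 1,
                      assembly_size = 8, assembly_boost_spikes = 3,
                      n_ap_locations = 0, no_stim_laps = 30,
                      reward_pause_s = 0.5, lfp = FALSE)
  g <- generate_session(cfg, seed = 16)
  pm <- bin_and_zscore(g$session$spike_trains, 0.025,
                       c(0, session_duration(g$session)))
  k <- max(significant_component_count(pm), 1)
  pats <- extract_assemblies(pm, k, seed = 16)
  rs <- reactivation_strength(pats$weights[, 1], pm)
  ev <- g$truth$assembly_events[[1]] + 0.0125   # event bin centers
  hit <- vapply(ev, function(e) any(abs(rs$events - e) <= 0.026),
                logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("the synthetic air-puff template is unit-norm and equal-weight", {
  reg <- sprintf("u%02d", 1:10)
  w4 <- synthetic_ap_pattern(reg[1:4], reg)
  expect_equal(w4[1:4], rep(0.5, 4))
  expect_equal(sum(w4^2), 1)
  w1 <- synthetic_ap_pattern(reg[7], reg)
  expect_identical(w1[7], 1)
  expect_identical(sum(w1 != 0), 1L)
  expect_error(synthetic_ap_pattern(character(), reg), "no air-puff")
  for (nn in c(2, 5, 9)) {
    expect_equal(sum(synthetic_ap_pattern(reg[1:nn], reg)^2), 1)
  }
})

test_that("template similarity flags identity, not orthogonality", {
  reg <- sprintf("u%02d", 1:30)
  templ <- synthetic_ap_pattern(reg[1:5], reg)
  ts1 <- template_similarity(templ, templ, 1000, seed = 1)
  expect_equal(ts1$similarity, 1)
  expect_true(ts1$significant)
  orth <- numeric(30); orth[10:14] <- 1 / sqrt(5)
  ts0 <- template_similarity(orth, templ, 1000, seed = 1)
  expect_equal(ts0$similarity, 0)
  expect_false(ts0$significant)
})

test_that("context metrics separate immobility-locked reactivation", {
  # construct a population whose assembly co-fires only while immobile
  set.seed(44)
  dur <- 400
  bt <- seq(0, dur - 0.02, by = 0.02)
  spd <- rep(15, length(bt))
  spd[bt %% 40 >= 30] <- 0   # 10 s immobility every 40 s
  pos <- (cumsum(spd) * 0.02) %% 190
  behavior <- behavior_trace(bt, pos, spd,
                             1L + as.integer(cumsum(c(0, diff(pos) < -100))))
  imm_start <- seq(30, dur - 10, by = 40)
  ev <- as.vector(vapply(imm_start, function(s0)
    s0 + sort(runif(8, 0.5, 9.5)), numeric(8)))
  ev <- 0.025 * floor(ev / 0.025)
  members <- lapply(1:6, function(i)
    sort(unique(c(runif(400, 0, dur), rep(ev, each = 2) +
                    runif(2 * length(ev), 0, 0.025)))))
  others <- lapply(1:14, function(i) sort(unique(runif(400, 0, dur))))
  trains <- c(members, others)
  names(trains) <- sprintf("u%02d", seq_along(trains))
  pm <- bin_and_zscore(trains, 0.025, c(0, dur))
  w <- numeric(20); w[1:6] <- 1 / sqrt(6)
  cm <- assembly_context_metrics(w, pm, behavior)
  expect_gt(cm$immobility_running_ratio, 3)
})
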