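#' Binned, z-scored population activity matrix
#'
#' Counts each unit's spikes in 25 ms bins over an interval, optionally
#' removes excluded time spans (e.g. air-puff laps) before normalization,
#' and z-scores each unit's count series. Units with zero variance are
#' dropped (recorded in the `dropped` attribute).
#'
#' @param spike_trains named list of spike-time vectors (s).
#' @param bin_s bin width (s).
#' @param interval c(start, end) window (s).
#' @param exclude optional data.frame with `start`/`end` columns; bins whose
#'   centers fall inside any excluded span are removed before z-scoring.
#' @return list of class `population_matrix`: `Z` (units x bins, row mean 0
#'   and SD 1), `unit_ids`, `bin_centers` (s), `bin_s`, `dropped` (unit ids
#'   removed for zero variance).
#' @export
bin_and_zscore <- function(spike_trains, bin_s = 0.025, interval,
                           exclude = NULL) {
  edges <- seq(interval[1], interval[2], by = bin_s)
  n_bins <- length(edges) - 1L
  stopifnot(n_bins >= 100)
  centers <- edges[-length(edges)] + bin_s / 2
  keep_bin <- rep(TRUE, n_bins)
  if (!is.null(exclude) && nrow(exclude)) {
    for (i in seq_len(nrow(exclude))) {
      keep_bin <- keep_bin &
        !(centers >= exclude$start[i] & centers <= exclude$end[i])
    }
  }
  counts <- t(vapply(spike_trains, function(st) {
    sp <- st[st >= interval[1] & st < interval[2]]
    tabulate(floor((sp - interval[1]) / bin_s) + 1L, nbins = n_bins)
  }, integer(n_bins)))
  counts <- counts[, keep_bin, drop = FALSE]
  mu <- rowMeans(counts)
  sd_ <- apply(counts, 1, stats::sd)
  ok <- sd_ > 0
  Z <- (counts[ok, , drop = FALSE] - mu[ok]) / sd_[ok]
  structure(list(Z = Z, unit_ids = names(spike_trains)[ok],
                 bin_centers = centers[keep_bin], bin_s = bin_s,
                 dropped = names(spike_trains)[!ok]),
            class = "population_matrix")
}

#' Number of significant principal components (Marcenko-Pastur)
#'
#' Eigenvalues of the unit-unit correlation matrix exceeding the
#' Marcenko-Pastur upper edge — the largest eigenvalue expected from an
#' uncorrelated population of the same shape — count as significant
#' co-activation structure. Because the asymptotic edge
#' `(1 + sqrt(n_units / n_bins))^2` is exceeded by a genuinely uncorrelated
#' population's largest eigenvalue in a non-negligible fraction of
#' finite-size sessions (Tracy-Widom edge fluctuations), the default
#' threshold adds the finite-sample Tracy-Widom correction at the
#' `tw_quantile` level; set `tw_quantile = NULL` for the raw asymptotic
#' bound.
#'
#' @param pm a [bin_and_zscore()] result.
#' @param tw_quantile upper-tail Tracy-Widom quantile for the finite-sample
#'   edge (0.99 by default; NULL for the plain asymptotic bound).
#' @return integer count of significant components; the eigenvalues and the
#'   bound are attached as attributes `eigenvalues` and `mp_bound`.
#' @export
significant_component_count <- function(pm, tw_quantile = 0.99) {
  n <- nrow(pm$Z)
  B <- ncol(pm$Z)
  if (B <= n) stop("need more time bins than units for the Marcenko-Pastur bound")
  C <- stats::cor(t(pm$Z))
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (is.null(tw_quantile)) {
    bound <- (1 + sqrt(n / B))^2
  } else {
    # Johnstone's largest-eigenvalue law for white Wishart matrices
    mu <- (sqrt(B - 1) + sqrt(n))^2 / B
    sig <- (sqrt(B - 1) + sqrt(n)) *
      (1 / sqrt(B - 1) + 1 / sqrt(n))^(1 / 3) / B
    tw_q <- c("0.95" = 0.9793, "0.99" = 2.0234, "0.999" = 3.2724)
    key <- as.character(tw_quantile)
    if (!key %in% names(tw_q)) {
      stop("tw_quantile must be one of 0.95, 0.99, 0.999 (or NULL)")
    }
    bound <- mu + sig * tw_q[[key]]
  }
  out <- sum(ev > bound)
  attr(out, "eigenvalues") <- ev
  attr(out, "mp_bound") <- bound
  out
}

# symmetric fixed-point ICA (cube nonlinearity) on whitened k x B data;
# returns the orthonormal unmixing matrix W (k x k)
fastica_symmetric <- function(X, seed = 1, max_iter = 500, tol = 1e-8) {
  k <- nrow(X)
  B <- ncol(X)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  for (attempt in seq_len(5)) {
    set.seed(seed + attempt - 1L)
    W <- matrix(stats::rnorm(k * k), k, k)
    sym_decorrelate <- function(W) {
      e <- eigen(W %*% t(W), symmetric = TRUE)
      solve_sqrt <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                                       k, k) %*% t(e$vectors)
      solve_sqrt %*% W
    }
    W <- sym_decorrelate(W)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      U <- W %*% X
      W_new <- (U^3) %*% t(X) / B - 3 * W
      W_new <- sym_decorrelate(W_new)
      delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
      W <- W_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (converged) return(W)
  }
  stop("ICA did not converge after 5 seeded restarts")
}

#' Extract assembly patterns by PCA/ICA
#'
#' Projects the z-scored population matrix onto its `k` significant
#' principal components, whitens, and runs a seeded fixed-point ICA; the
#' independent components are back-projected to unit space, normalized to
#' unit Euclidean norm, and sign-aligned so each pattern's largest-magnitude
#' weight is positive.
#'
#' @param pm a [bin_and_zscore()] result.
#' @param k number of components, from [significant_component_count()].
#' @param seed ICA initialization seed (results are deterministic given the
#'   seed).
#' @param member_sd member threshold: units whose weight exceeds
#'   mean + `member_sd` * SD of the pattern's weights.
#' @return list of class `assembly_patterns`: `weights` (units x k matrix,
#'   unit-norm columns), `unit_ids`, `members` (list of unit-id vectors),
#'   `k`.
#' @export
extract_assemblies <- function(pm, k, seed = 1, member_sd = 2) {
  stopifnot(k >= 1, k <= nrow(pm$Z))
  B <- ncol(pm$Z)
  C <- stats::cor(t(pm$Z))
  e <- eigen(C, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  lam <- e$values[seq_len(k)]
  Y <- t(V) %*% pm$Z                       # k x B projection
  X <- Y / apply(Y, 1, stats::sd)          # whiten empirically
  W <- fastica_symmetric(X, seed = seed)
  w_unit <- V %*% (sqrt(lam) * t(W))       # back-project mixing columns
  w_unit <- sweep(w_unit, 2, sqrt(colSums(w_unit^2)), "/")
  for (j in seq_len(k)) {
    i_max <- which.max(abs(w_unit[, j]))
    if (w_unit[i_max, j] < 0) w_unit[, j] <- -w_unit[, j]
  }
  members <- lapply(seq_len(k), function(j) {
    w <- w_unit[, j]
    pm$unit_ids[w > mean(w) + member_sd * stats::sd(w)]
  })
  structure(list(weights = w_unit, unit_ids = pm$unit_ids,
                 members = members, k = k),
            class = "assembly_patterns")
}

#' Assembly reactivation strength over time
#'
#' Quadratic-form projection of the instantaneous z-scored population vector
#' onto a pattern: `R(t) = z(t)' P z(t)` with `P = w w'` and the diagonal
#' zeroed, so a single unit's firing cannot trigger a reactivation.
#' Reactivation events are local maxima of `R(t)` above `threshold`.
#'
#' @param weights unit-norm pattern vector (same unit registry as `pm`).
#' @param pm a [bin_and_zscore()] result.
#' @param threshold event threshold on the raw strength (5).
#' @return list: `strength` (per bin), `bin_centers`, `events` (bin-center
#'   times of suprathreshold local maxima).
#' @export
reactivation_strength <- function(weights, pm, threshold = 5) {
  if (length(weights) != nrow(pm$Z)) {
    stop("pattern and population matrix have mismatched unit registries")
  }
  proj <- as.numeric(crossprod(weights, pm$Z))   # w' z(t)
  diag_term <- as.numeric(crossprod(weights^2, pm$Z^2))
  strength <- proj^2 - diag_term
  n <- length(strength)
  is_peak <- strength > threshold &
    strength >= c(-Inf, strength[-n]) &
    strength >= c(strength[-1], -Inf)
  list(strength = strength, bin_centers = pm$bin_centers,
       events = pm$bin_centers[is_peak])
}

#' Synthetic air-puff pattern from the activated pyramidal set
#'
#' Template with equal weights `1/sqrt(n)` on the air-puff-activated
#' pyramidal cells and zero elsewhere (unit Euclidean norm).
#'
#' @param aap_ids unit ids of the activated pyramidal cells.
#' @param unit_ids full unit registry (order defines the vector).
#' @return numeric template vector over `unit_ids`.
#' @export
synthetic_ap_pattern <- function(aap_ids, unit_ids) {
  aap_ids <- intersect(aap_ids, unit_ids)
  if (!length(aap_ids)) stop("no air-puff-activated units in the registry")
  w <- numeric(length(unit_ids))
  w[unit_ids %in% aap_ids] <- 1 / sqrt(length(aap_ids))
  w
}

#' Similarity of an assembly pattern to the synthetic air-puff template
#'
#' Similarity index = |inner product| of the two unit-norm vectors. The
#' null distribution is built by permuting the pattern's weight entries
#' across units `n_shuffles` times; the similarity is significant iff it
#' exceeds the null's 99th percentile.
#'
#' @param pattern unit-norm assembly weight vector.
#' @param template unit-norm template (same registry).
#' @param n_shuffles permutations (1000).
#' @param seed permutation seed.
#' @param percentile significance percentile of the null (0.99).
#' @return list: `similarity`, `threshold` (null percentile), `significant`.
#' @export
template_similarity <- function(pattern, template, n_shuffles = 1000,
                                seed = 1, percentile = 0.99) {
  stopifnot(length(pattern) == length(template))
  if (sum(template != 0) < 3) {
    warning("fewer than 3 nonzero template entries; permutation null is weak")
  }
  s <- abs(sum(pattern * template))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)
  null <- vapply(seq_len(n_shuffles), function(i) {
    abs(sum(sample(pattern) * template))
  }, numeric(1))
  thr <- stats::quantile(null, percentile, names = FALSE)
  list(similarity = s, threshold = thr, significant = s > thr)
}

#' Context metrics of an assembly pattern
#'
#' Mean reactivation strength per epoch block, the immobility/running
#' strength ratio, and the ripple-triggered average strength around ripple
#' peaks.
#'
#' @param weights pattern vector (registry of `pm`).
#' @param pm a [bin_and_zscore()] result.
#' @param behavior behavior trace (for bin speeds).
#' @param ripples ripple table from [detect_ripples()] (may be empty).
#' @param plan optional epoch plan from [split_epochs()]; per-epoch means
#'   are skipped when NULL.
#' @param speed_min running/immobility split (cm/s).
#' @param lag_s half-window of the ripple-triggered average (s).
#' @return list: `by_epoch` (data.frame label/lap range/mean strength or
#'   NULL), `immobility_running_ratio`, `ripple_triggered` (data.frame
#'   `lag_s`, `mean_strength`; NULL without ripples).
#' @export
assembly_context_metrics <- function(weights, pm, behavior, ripples = NULL,
                                     plan = NULL, speed_min = 2,
                                     lag_s = 0.5) {
  rs <- reactivation_strength(weights, pm)
  spd <- stats::approx(behavior$time, behavior$speed,
                       xout = pm$bin_centers, rule = 2)$y
  imm <- spd < speed_min
  ratio <- if (any(imm) && any(!imm)) {
    mean(rs$strength[imm]) / mean(rs$strength[!imm])
  } else NA_real_
  by_epoch <- NULL
  if (!is.null(plan)) {
    lapb <- lap_at_time(behavior, pm$bin_centers)
    by_epoch <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i) {
      sel <- !is.na(lapb) & lapb >= plan$lap_start[i] &
        lapb <= plan$lap_end[i]
      data.frame(label = plan$label[i], lap_start = plan$lap_start[i],
                 lap_end = plan$lap_end[i],
                 mean_strength = if (any(sel)) mean(rs$strength[sel])
                   else NA_real_)
    }))
  }
  ripple_triggered <- NULL
  if (!is.null(ripples) && nrow(ripples)) {
    n_lag <- round(lag_s / pm$bin_s)
    lags <- (-n_lag:n_lag) * pm$bin_s
    acc <- matrix(NA_real_, nrow(ripples), length(lags))
    for (i in seq_len(nrow(ripples))) {
      ctr <- findInterval(ripples$peak[i], rs$bin_centers + pm$bin_s / 2) + 1L
      ix <- ctr + (-n_lag:n_lag)
      ok <- ix >= 1 & ix <= length(rs$strength)
      acc[i, ok] <- rs$strength[ix[ok]]
    }
    ripple_triggered <- data.frame(lag_s = lags,
                                   mean_strength = colMeans(acc, na.rm = TRUE))
  }
  list(by_epoch = by_epoch, immobility_running_ratio = ratio,
       ripple_triggered = ripple_triggered)
}
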