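#' Spike-train cross-correlogram
#'
#' Counts of postsynaptic spike lags relative to every presynaptic spike,
#' binned at `bin_ms` over +/- `window_ms`. Lag bin `b` (center, ms) covers
#' `(b - bin/2, b + bin/2]`, so the "0-3 ms" monosynaptic window corresponds
#' to bins 1, 2 and 3 at 1 ms binning and the zero-lag bin is its own bin.
#'
#' @param pre,post spike-time vectors (s), sorted increasing.
#' @param window_ms half-window (ms).
#' @param bin_ms bin width (ms).
#' @param drop_zero_self drop exact zero lags (used for autocorrelograms,
#'   where each spike pairs with itself).
#' @return data.frame: `lag_ms` (bin centers from -window to +window),
#'   `count`.
#' @export
cross_correlogram <- function(pre, post, window_ms = 50, bin_ms = 1,
                              drop_zero_self = FALSE) {
  stopifnot(length(pre) >= 1, length(post) >= 1)
  centers <- seq(-window_ms, window_ms, by = bin_ms)
  w <- (window_ms + bin_ms / 2) / 1000
  # sliding-window pair enumeration on the sorted trains
  lo <- findInterval(pre - w, post) + 1L
  hi <- findInterval(pre + w, post)
  n_pairs <- pmax(hi - lo + 1L, 0L)
  total <- sum(n_pairs)
  counts <- integer(length(centers))
  if (total > 0) {
    keep <- n_pairs > 0
    idx <- sequence(n_pairs[keep]) + rep(lo[keep] - 1L, n_pairs[keep])
    lags_ms <- (post[idx] - rep(pre[keep], n_pairs[keep])) * 1000
    if (drop_zero_self) lags_ms <- lags_ms[lags_ms != 0]
    # bin b covers (b - bin/2, b + bin/2]: use ceiling on shifted lags
    bix <- as.integer(ceiling((lags_ms - bin_ms / 2) / bin_ms - 1e-9)) +
      as.integer(window_ms / bin_ms) + 1L
    bix <- bix[bix >= 1 & bix <= length(centers)]
    counts <- tabulate(bix, nbins = length(centers))
  }
  data.frame(lag_ms = centers, count = counts)
}

#' Hollow-Gaussian predictor of a cross-correlogram
#'
#' Convolves the raw CCG with a Gaussian kernel whose central bin weight is
#' reduced by `hollow_fraction` (then renormalized to unit sum), producing
#' the slow co-modulation expectation against which sharp monosynaptic peaks
#' are tested. Near the edges the truncated kernel is renormalized so that a
#' flat CCG maps to itself exactly.
#'
#' @param ccg_counts raw CCG counts (vector over lag bins).
#' @param sd_ms kernel standard deviation in ms.
#' @param hollow_fraction fraction removed from the central bin (0.6).
#' @param bin_ms bin width (ms).
#' @return numeric vector of expected counts, same length as the input.
#' @export
hollow_gaussian_predictor <- function(ccg_counts, sd_ms = 10,
                                      hollow_fraction = 0.6, bin_ms = 1) {
  n <- length(ccg_counts)
  half <- min(as.integer(ceiling(5 * sd_ms / bin_ms)), n - 1L)
  lags <- (-half:half) * bin_ms
  k <- stats::dnorm(lags, 0, sd_ms)
  k[half + 1L] <- k[half + 1L] * (1 - hollow_fraction)
  k <- k / sum(k)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    ok <- j >= 1 & j <= n
    out[i] <- sum(k[ok] * ccg_counts[j[ok]]) / sum(k[ok])
  }
  out
}

#' Test a pyramidal-to-interneuron pair for a monosynaptic connection
#'
#' The pair is connected iff the global CCG peak falls in the (0, 3] ms lag
#' window (bins 1-3 at 1 ms binning; the zero-lag bin is excluded, which
#' removes common-drive artifacts) and the probability of a count at least
#' as large under a Poisson with the predictor's mean at that bin is below
#' `alpha`.
#'
#' @param ccg data.frame from [cross_correlogram()].
#' @param predictor expected counts from [hollow_gaussian_predictor()].
#' @param alpha significance threshold (0.001).
#' @param max_lag_ms upper edge of the monosynaptic lag window (ms).
#' @return list: `connected`, `peak_lag_ms`, `peak_count`, `peak_p`.
#' @export
test_connection <- function(ccg, predictor, alpha = 0.001, max_lag_ms = 3) {
  stopifnot(length(predictor) == nrow(ccg))
  peak_ix <- which.max(ccg$count)
  peak_lag <- ccg$lag_ms[peak_ix]
  obs <- ccg$count[peak_ix]
  mu <- predictor[peak_ix]
  p <- if (mu <= 0) {
    if (obs > 0) 0 else 1
  } else {
    stats::ppois(obs - 1, mu, lower.tail = FALSE)
  }
  in_window <- peak_lag > 0 & peak_lag <= max_lag_ms
  list(connected = in_window && obs > 0 && p < alpha,
       peak_lag_ms = peak_lag, peak_count = obs, peak_p = p)
}

#' Monosynaptic connection scan over pyramidal-to-interneuron pairs
#'
#' @param s an `ephys_session`.
#' @param unit_table [classify_units()] output (or any data.frame with
#'   `unit_id` and `class`).
#' @param window_ms,sd_ms,hollow_fraction,alpha,max_lag_ms see
#'   [cross_correlogram()], [hollow_gaussian_predictor()],
#'   [test_connection()].
#' @param min_spikes pairs where either train has fewer spikes are skipped.
#' @return data.frame (`edges`): `pre_id`, `post_id`, `peak_lag_ms`,
#'   `peak_p`, `connected`, `n_pre`, `n_post`.
#' @export
detect_connections <- function(s, unit_table, window_ms = 50, sd_ms = 10,
                               hollow_fraction = 0.6, alpha = 0.001,
                               max_lag_ms = 3, min_spikes = 50) {
  pyr <- unit_table$unit_id[unit_table$class == "pyramidal"]
  int <- unit_table$unit_id[unit_table$class == "interneuron"]
  rows <- list()
  for (a in pyr) {
    pre_sp <- s$spike_trains[[a]]
    if (length(pre_sp) < min_spikes) next
    for (b in int) {
      post_sp <- s$spike_trains[[b]]
      if (length(post_sp) < min_spikes) next
      ccg <- cross_correlogram(pre_sp, post_sp, window_ms = window_ms)
      pred <- hollow_gaussian_predictor(ccg$count, sd_ms = sd_ms,
                                        hollow_fraction = hollow_fraction)
      tst <- test_connection(ccg, pred, alpha = alpha,
                             max_lag_ms = max_lag_ms)
      rows[[length(rows) + 1L]] <- data.frame(
        pre_id = a, post_id = b, peak_lag_ms = tst$peak_lag_ms,
        peak_p = tst$peak_p, connected = tst$connected,
        n_pre = length(pre_sp), n_post = length(post_sp))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pre_id = character(), post_id = character(),
               peak_lag_ms = numeric(), peak_p = numeric(),
               connected = logical(), n_pre = integer(), n_post = integer())
  rownames(out) <- NULL
  out
}

#' Postsynaptic out-degree per presynaptic group
#'
#' Counts the distinct connected interneuron partners of each presynaptic
#' pyramidal cell (duplicate edges collapse) and summarizes the counts by
#' response group, e.g. air-puff-activated versus non-affected pyramidal
#' cells.
#'
#' @param edges edge table from [detect_connections()] (only rows with
#'   `connected` are used) or any data.frame with `pre_id`/`post_id`.
#' @param groups named character vector mapping unit_id to group label.
#' @return data.frame: `unit_id`, `group`, `out_degree` (one row for every
#'   unit in `groups`, zero for units with no targets).
#' @export
out_degree_by_group <- function(edges, groups) {
  if ("connected" %in% names(edges)) {
    edges <- edges[edges$connected, , drop = FALSE]
  }
  deg <- vapply(names(groups), function(uid) {
    length(unique(edges$post_id[edges$pre_id == uid]))
  }, integer(1))
  data.frame(unit_id = names(groups), group = unname(groups),
             out_degree = unname(deg))
}
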