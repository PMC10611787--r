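#' Pipeline configuration
#'
#' Every numeric constant of the analysis in one flat list, with the
#' package's defaults: 20 ms PSTH bins over [-4, 4] s, activation at z > 2
#' for 3 consecutive bins and suppression at z < -1 for 10 bins within
#' (0, 3] s, 2 cm spatial bins with a 2 cm/s movement filter, 5%-of-peak
#' place fields of at least 3 bins with split-half stability R >= 0.3,
#' 1 ms/±50 ms cross-correlograms with a 10 ms hollow-Gaussian predictor
#' (hollow fraction 0.6) and Poisson peak test at p < 0.001 in (0, 3] ms,
#' 120-250 Hz ripples at mean + 1/3 SD for >= 20 ms during immobility,
#' 5-12 Hz theta, 25 ms assembly bins with the Marcenko-Pastur component
#' bound and reactivation threshold 5, 1000-shuffle template similarity at
#' the 99th percentile, and a Poisson decoder with 0.01 Hz rate floor,
#' ±20 cm reward zone and 1000 Monte-Carlo control zones.
#'
#' @param ... named overrides.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    psth_bin_s = 0.02,
    psth_window = c(-4, 4),
    activation_z = 2,
    activation_min_bins = 3,
    suppression_z = -1,
    suppression_min_bins = 10,
    post_window_s = 3,
    speed_min = 2,
    tuning_bin_cm = 2,
    field_threshold = 0.05,
    field_min_bins = 3,
    stability_r = 0.3,
    stability_alpha = 0.05,
    ccg_window_ms = 50,
    ccg_sd_ms = 10,
    hollow_fraction = 0.6,
    connection_alpha = 0.001,
    connection_max_lag_ms = 3,
    theta_band = c(5, 12),
    ripple_band = c(120, 250),
    ripple_low_sd = 1,
    ripple_peak_sd = 3,
    ripple_min_s = 0.020,
    immobility_min_s = 0.5,
    assembly_bin_s = 0.025,
    reactivation_threshold = 5,
    template_shuffles = 1000,
    decode_rate_floor = 0.01,
    reward_zone_cm = 20,
    mc_draws = 1000,
    seed = 1,
    run_connectivity = TRUE,
    run_oscillations = TRUE,
    run_assemblies = TRUE,
    run_decoding = TRUE
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("unknown pipeline_config parameter(s): ",
         paste(unknown, collapse = ", "))
  }
  cfg[names(ov)] <- ov
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full analysis pipeline on a session
#'
#' Stages run in dependency order: unit classification, epoch splitting,
#' event responses, place-cell analysis, nomenclature, connectivity,
#' ripples, assemblies (with the synthetic air-puff template test), and
#' theta-cycle decoding of the first no-stimulation epoch (second half
#' decoded from maps trained on the first half). Every stage writes a CSV
#' artifact into `out_dir` plus a `summary.json`; identical inputs, config
#' and seed give identical outputs.
#'
#' @param s an `ephys_session`.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @return list with elements `units`, `plan`, `responses`, `place_flags`,
#'   `groups`, `edges`, `ripples`, `assemblies`, `decoding`, `summary`.
#' @export
run_pipeline <- function(s, config = pipeline_config(), out_dir = NULL) {
  cfg <- config
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(out_dir) && !is.null(df)) {
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
  }

  units <- classify_units(s)
  emit(units, "units.csv")
  plan <- split_epochs(s$events, s$behavior)
  emit(plan, "epochs.csv")

  has_ap <- any(s$events$event_type == "air_puff")
  responses <- NULL
  if (has_ap) {
    responses <- event_responses(s, "air_puff",
                                 post_window = cfg$post_window_s,
                                 suppression_min_bins = cfg$suppression_min_bins)
    emit(responses, "responses.csv")
  }

  place_flags <- place_cell_flags(s, plan, cfg$speed_min, cfg$stability_r)
  field_rows <- lapply(names(s$spike_trains), function(uid) {
    tc <- tuning_curve(s$spike_trains[[uid]], s$behavior, s$track_length,
                       speed_min = cfg$speed_min)
    flds <- detect_place_fields(tc, cfg$field_threshold, cfg$field_min_bins)
    si <- spatial_information(tc)
    if (!nrow(flds)) {
      return(data.frame(unit_id = uid, start_cm = NA_real_, end_cm = NA_real_,
                        peak_hz = NA_real_, center_cm = NA_real_,
                        spatial_info_bits = si,
                        place_cell = unname(place_flags[uid])))
    }
    data.frame(unit_id = uid,
               start_cm = (flds$start_bin - 1) * tc$bin_cm,
               end_cm = flds$end_bin * tc$bin_cm,
               peak_hz = flds$peak_hz, center_cm = flds$center_cm,
               spatial_info_bits = si,
               place_cell = unname(place_flags[uid]))
  })
  fields <- do.call(rbind, field_rows)
  emit(fields, "fields.csv")

  groups <- NULL
  if (has_ap && !is.null(responses)) {
    groups <- assign_nomenclature(units, responses, place_flags)
    emit(groups, "groups.csv")
  }

  edges <- NULL
  if (isTRUE(cfg$run_connectivity) &&
      any(units$class == "pyramidal") && any(units$class == "interneuron")) {
    edges <- detect_connections(s, units, window_ms = cfg$ccg_window_ms,
                                sd_ms = cfg$ccg_sd_ms,
                                hollow_fraction = cfg$hollow_fraction,
                                alpha = cfg$connection_alpha,
                                max_lag_ms = cfg$connection_max_lag_ms)
    emit(edges, "edges.csv")
  }

  ripples <- NULL
  if (isTRUE(cfg$run_oscillations) && !is.null(s$lfp) &&
      s$lfp$sample_rate >= 500) {
    ripples <- detect_ripples(s$lfp, s$behavior, cfg$ripple_band,
                              cfg$ripple_low_sd, cfg$ripple_peak_sd,
                              cfg$ripple_min_s, cfg$speed_min,
                              cfg$immobility_min_s)
    emit(ripples, "ripples.csv")
  }

  assemblies <- NULL
  if (isTRUE(cfg$run_assemblies)) {
    pyr_ids <- units$unit_id[units$class == "pyramidal"]
    if (length(pyr_ids) >= 5) {
      pm <- bin_and_zscore(s$spike_trains[pyr_ids], cfg$assembly_bin_s,
                           c(0, session_duration(s)))
      if (ncol(pm$Z) > nrow(pm$Z)) {
        k <- significant_component_count(pm)
        if (k >= 1) {
          pats <- extract_assemblies(pm, k, seed = cfg$seed)
          sim <- rep(NA_real_, k)
          sig <- rep(NA, k)
          if (!is.null(groups)) {
            aap <- groups$unit_id[!is.na(groups$group) &
                                    groups$group %in% c("aAP-PC", "aAP-nPC")]
            if (length(aap)) {
              templ <- synthetic_ap_pattern(aap, pats$unit_ids)
              for (j in seq_len(k)) {
                ts_ <- template_similarity(pats$weights[, j], templ,
                                           cfg$template_shuffles,
                                           seed = cfg$seed)
                sim[j] <- ts_$similarity
                sig[j] <- ts_$significant
              }
            }
          }
          assemblies <- list(
            patterns = pats,
            table = data.frame(pattern = seq_len(k),
                               n_members = lengths(pats$members),
                               similarity_to_ap = sim,
                               ap_significant = sig))
          emit(assemblies$table, "assemblies.csv")
        }
      }
    }
  }

  decoding <- NULL
  if (isTRUE(cfg$run_decoding) && !is.null(s$lfp)) {
    ns <- plan[plan$label == "no_stim", , drop = FALSE]
    if (nrow(ns) >= 1 && ns$lap_end[1] - ns$lap_start[1] >= 3) {
      laps <- ns$lap_start[1]:ns$lap_end[1]
      half <- floor(length(laps) / 2)
      train <- laps[1:half]
      test <- laps[(half + 1):length(laps)]
      maps <- rate_maps_from_laps(s, train, speed_min = cfg$speed_min,
                                  bin_cm = cfg$tuning_bin_cm)
      cyc <- segment_theta_cycles(s$lfp, s$behavior, cfg$speed_min,
                                  cfg$immobility_min_s, cfg$theta_band)
      ti <- lap_range_interval(s$behavior, test[1], test[length(test)])
      cyc <- cyc[cyc$start >= ti[1] & cyc$end <= ti[2], , drop = FALSE]
      if (nrow(cyc) >= 10) {
        dec <- decode_cycles(s, cyc, maps, cfg$tuning_bin_cm,
                             cfg$decode_rate_floor)
        decoding <- list(result = dec,
                         median_error_cm = stats::median(dec$cycles$error_cm),
                         profile = decoding_error_profile(dec))
        emit(dec$cycles, "decode_cycles.csv")
      }
    }
  }

  summary <- list(
    session_id = s$session_id,
    n_units = nrow(units),
    n_pyramidal = sum(units$class == "pyramidal"),
    n_interneuron = sum(units$class == "interneuron"),
    n_place_cells = sum(place_flags),
    n_activated = if (!is.null(responses))
      sum(responses$class %in% c("activated", "biphasic")) else NA,
    n_suppressed = if (!is.null(responses))
      sum(responses$class == "suppressed") else NA,
    n_edges = if (!is.null(edges)) sum(edges$connected) else NA,
    n_ripples = if (!is.null(ripples)) nrow(ripples) else NA,
    n_assemblies = if (!is.null(assemblies)) nrow(assemblies$table) else 0L,
    median_decoding_error_cm = if (!is.null(decoding))
      decoding$median_error_cm else NA,
    seed = cfg$seed
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  list(units = units, plan = plan, responses = responses,
       place_flags = place_flags, fields = fields, groups = groups,
       edges = edges, ripples = ripples, assemblies = assemblies,
       decoding = decoding, summary = summary)
}
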