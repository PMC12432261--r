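# End-to-end pipeline: simulate -> condition -> rank montages -> saccade
# deflections -> gaze-angle models, as one deterministic, config-driven run
# writing plain-CSV/JSON artifacts plus a manifest.

#' Default pipeline configuration
#'
#' The schema-complete configuration list consumed by [run_pipeline()].
#' A single global seed fans out to per-participant sub-seeds through a
#' fixed counter scheme, so adding participants never perturbs existing
#' ones.
#'
#' @param participants number of simulated participants.
#' @param cycles task repetitions per participant.
#' @param seed global integer seed.
#' @return a named list (the config schema with defaults filled in).
#' @export
default_pipeline_config <- function(participants = 2, cycles = 1, seed = 1) {
  list(
    participants = participants,
    cycles = cycles,
    seed = seed,
    pursuit = list(amplitudes_deg = c(5, 10, 15),
                   frequencies_hz = c(0.5, 1),
                   axes = c("horizontal", "vertical")),
    saccade = list(angles_deg = seq(2.5, 15, by = 2.5),
                   directions = c("left", "right", "up", "down")),
    noise = list(white_uV = 2, drift_uV_per_sqrt_s = 3, line_50hz_uV = 5,
                 camera_noise_deg = 0.3, camera_dropout_prob = 0.02,
                 camera_latency_s = 0.1),
    deflection_mode = "flank",
    cv_scheme = "loo"
  )
}

#' Validate a pipeline configuration
#'
#' Checks the config against the schema and errors listing every offending
#' key.
#'
#' @param config a config list (see [default_pipeline_config()]).
#' @return the config, invisibly, if valid.
#' @export
validate_pipeline_config <- function(config) {
  bad <- character()
  chk <- function(cond, key) if (!isTRUE(cond)) bad <<- c(bad, key)
  chk(is.numeric(config$participants) && config$participants >= 1, "participants")
  chk(is.numeric(config$cycles) && config$cycles >= 1, "cycles")
  chk(is.numeric(config$seed) && config$seed == round(config$seed), "seed")
  chk(all(config$pursuit$amplitudes_deg > 0), "pursuit.amplitudes_deg")
  chk(all(config$pursuit$frequencies_hz > 0), "pursuit.frequencies_hz")
  chk(all(config$pursuit$axes %in% c("horizontal", "vertical")), "pursuit.axes")
  chk(all(config$saccade$angles_deg > 0), "saccade.angles_deg")
  chk(all(config$saccade$directions %in% c("left", "right", "up", "down")),
      "saccade.directions")
  chk(is.numeric(config$noise$white_uV) && config$noise$white_uV >= 0,
      "noise.white_uV")
  chk(is.numeric(config$noise$drift_uV_per_sqrt_s) &&
        config$noise$drift_uV_per_sqrt_s >= 0, "noise.drift_uV_per_sqrt_s")
  chk(is.numeric(config$noise$line_50hz_uV) && config$noise$line_50hz_uV >= 0,
      "noise.line_50hz_uV")
  chk(is.numeric(config$noise$camera_noise_deg) &&
        config$noise$camera_noise_deg >= 0, "noise.camera_noise_deg")
  chk(is.numeric(config$noise$camera_dropout_prob) &&
        config$noise$camera_dropout_prob >= 0 &&
        config$noise$camera_dropout_prob < 1, "noise.camera_dropout_prob")
  chk(is.numeric(config$noise$camera_latency_s) &&
        config$noise$camera_latency_s >= 0 &&
        config$noise$camera_latency_s <= 0.5, "noise.camera_latency_s")
  chk(config$deflection_mode %in% c("flank", "span", "window"),
      "deflection_mode")
  chk(config$cv_scheme %in% c("loo", "pooled"), "cv_scheme")
  if (length(bad)) {
    stop("invalid pipeline config key(s): ", paste(bad, collapse = ", "))
  }
  invisible(config)
}

#' @rdname default_pipeline_config
#' @param path JSON file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_pipeline_config()
  for (key in names(base)) if (is.null(cfg[[key]])) cfg[[key]] <- base[[key]]
  validate_pipeline_config(cfg)
  cfg
}

#' Deterministic per-participant sub-seed
#'
#' @param seed global seed.
#' @param i participant index (1-based).
#' @return an integer seed below 2^31.
#' @export
participant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i) * 9973) %% 2147483647L)
}

synth_config_from <- function(config, rng_seed) {
  synth_config(noise_white_uV = config$noise$white_uV,
               drift_random_walk_uV_per_sqrt_s = config$noise$drift_uV_per_sqrt_s,
               line_50hz_uV = config$noise$line_50hz_uV,
               camera_noise_deg = config$noise$camera_noise_deg,
               camera_dropout_prob = config$noise$camera_dropout_prob,
               camera_latency_s = config$noise$camera_latency_s,
               rng_seed = rng_seed)
}

#' Run the full analysis pipeline
#'
#' Simulates the configured cohort (pursuit and saccade sessions per
#' participant), ranks the candidate montages against gold-standard EOG and
#' camera gaze, runs the montage statistics (Friedman, then pairwise
#' Wilcoxon when p < 0.05), computes saccade deflection records with the
#' best-ranked pairs, fits the three gaze-angle models (best pair, all
#' pairs, gold standard) with the configured cross-validation, and writes
#' every result as CSV plus a JSON manifest. Identical configurations give
#' byte-identical artifacts.
#'
#' @param config a config list (see [default_pipeline_config()]) or the
#'   path of a config JSON file.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the key results and artifact paths.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- default_electrode_layout()

  sessions <- lapply(seq_len(config$participants), function(i) {
    seed_i <- participant_seed(config$seed, i)
    pursuit <- simulate_session(
      pursuit_schedule(config$pursuit$amplitudes_deg,
                       config$pursuit$frequencies_hz,
                       config$pursuit$axes, cycles = config$cycles,
                       seed = seed_i),
      layout, synth_config_from(config, seed_i))
    saccade <- simulate_session(
      saccade_schedule(config$saccade$angles_deg, config$saccade$directions,
                       cycles = config$cycles),
      layout, synth_config_from(config, participant_seed(seed_i, 7919)))
    pursuit$recording <- bandpass_recording(pursuit$recording)
    saccade$recording <- bandpass_recording(saccade$recording)
    list(id = i, pursuit = pursuit, saccade = saccade)
  })

  # --- montage ranking -----------------------------------------------------
  orientations <- intersect(c("horizontal", "vertical"), config$pursuit$axes)
  rankings <- list()
  stats_rows <- list()
  for (orient in orientations) {
    candidates <- default_montages(orient)
    for (ref in c("gold", "camera")) {
      r_all <- NULL
      per_participant <- list()
      for (s in sessions) {
        trials <- pursuit_trials(s$pursuit$recording, s$pursuit$camera,
                                 s$pursuit$schedule, orient)
        rk <- rank_montages(trials, candidates, reference = ref)
        per_participant[[length(per_participant) + 1]] <-
          vapply(rownames(rk)[order(rownames(rk))], function(lab) rk[lab, "mean_r"],
                 numeric(1))
        r_all <- rbind(r_all, attr(rk, "r_matrix"))
      }
      combined <- rank_montages_combined(r_all, candidates, orient, ref)
      key <- paste(orient, ref, sep = "_")
      rankings[[key]] <- combined
      write_results_table(
        cbind(montage = rownames(combined), combined),
        file.path(out_dir, paste0("ranking_", key, ".csv")))
      # participant-level Fisher means are the observations for the tests
      pp <- do.call(rbind, per_participant)
      if (nrow(pp) >= 2) {
        ft <- friedman_across_montages(pp)
        stats_rows[[length(stats_rows) + 1]] <- data.frame(
          orientation = orient, reference = ref, test = "friedman",
          statistic = ft$statistic, p_value = ft$p_value, n = ft$n)
        if (ft$p_value < 0.05) {
          pw <- pairwise_wilcoxon(pp)
          idx <- which(upper.tri(pw), arr.ind = TRUE)
          stats_rows[[length(stats_rows) + 1]] <- data.frame(
            orientation = orient, reference = ref,
            test = paste0("wilcoxon:", rownames(pw)[idx[, 1]], "|",
                          colnames(pw)[idx[, 2]]),
            statistic = NA_real_, p_value = pw[idx], n = nrow(pp))
        }
      }
    }
  }
  if (length(stats_rows)) {
    write_results_table(do.call(rbind, stats_rows),
                        file.path(out_dir, "montage_stats.csv"))
  }

  best_h <- rownames(rankings[["horizontal_gold"]])[1]
  best_v <- if ("vertical_gold" %in% names(rankings)) {
    rownames(rankings[["vertical_gold"]])[1]
  } else NULL

  # --- saccade analysis ----------------------------------------------------
  montages <- c(default_montages("horizontal"),
                if ("vertical" %in% orientations) default_montages("vertical"))
  records <- do.call(rbind, lapply(sessions, function(s) {
    ep <- extract_epochs(s$saccade$recording, s$saccade$schedule,
                         participant_id = s$id)
    saccade_deflections(ep, montages, mode = config$deflection_mode,
                        camera = s$saccade$camera)
  }))
  write_results_table(records, file.path(out_dir, "saccade_deflections.csv"))

  defl_stats <- deflection_summary(records, best_h, best_v)
  write_results_table(defl_stats, file.path(out_dir, "deflection_summary.csv"))

  # --- gaze-angle prediction (horizontal only) -----------------------------
  horiz <- records[records$axis == "horizontal" & records$valid &
                     is.finite(records$angle_change_deg), , drop = FALSE]
  feature_sets <- list(
    best_pair = best_h,
    all_pairs = vapply(montages, montage_label, character(1)),
    gold_standard = "gold"
  )
  mae_tables <- list()
  preds <- list()
  for (nm in names(feature_sets)) {
    pr <- cv_predict_angles(horiz, feature_sets[[nm]], scheme = config$cv_scheme)
    preds[[nm]] <- pr
    mae <- evaluate_mae(pr, horiz$angle_change_deg, horiz$direction,
                        horiz$amplitude_deg)
    mae_tables[[nm]] <- mae
    write_results_table(mae, file.path(out_dir, paste0("mae_", nm, ".csv")))
  }
  ba <- bland_altman(preds$best_pair, preds$gold_standard)
  write_results_table(
    data.frame(mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
               loa_low = ba$loa_low, loa_high = ba$loa_high),
    file.path(out_dir, "bland_altman_best_vs_gold.csv"))

  manifest <- list(
    package = "eareog",
    version = as.character(utils::packageVersion("eareog")),
    seed = config$seed,
    config = config,
    best_horizontal_montage = best_h,
    best_vertical_montage = best_v,
    artifacts = sort(list.files(out_dir, pattern = "\\.csv$"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(rankings = rankings, records = records,
                 mae = mae_tables, bland_altman = ba,
                 best_horizontal = best_h, best_vertical = best_v,
                 out_dir = out_dir))
}

# combine per-trial correlation matrices from several participants into one
# ranking table
rank_montages_combined <- function(r_matrix, candidates, orientation, reference) {
  labels <- vapply(candidates, montage_label, character(1))
  res <- data.frame(
    channel_a = vapply(candidates, function(p) p$channel_a, character(1)),
    channel_b = vapply(candidates, function(p) p$channel_b, character(1)),
    orientation = orientation,
    reference = reference,
    n_trials = colSums(!is.na(r_matrix)),
    mean_r = vapply(seq_along(labels), function(j) {
      r <- r_matrix[!is.na(r_matrix[, j]), j]
      if (length(r) == 0) NA_real_ else fisher_mean(r)
    }, numeric(1)),
    row.names = labels
  )
  res[order(-abs(res$mean_r)), ]
}

# per-direction/per-angle mean deflections and ear-vs-gold correlations
deflection_summary <- function(records, best_h, best_v = NULL) {
  rows <- list()
  for (d in unique(records$direction)) {
    axis <- if (d %in% c("left", "right")) "horizontal" else "vertical"
    pair_col <- if (axis == "horizontal") best_h else best_v
    if (is.null(pair_col)) next
    sub <- records[records$direction == d & records$valid, , drop = FALSE]
    if (nrow(sub) == 0) next
    ang <- sort(unique(sub$amplitude_deg))
    # absolute per-angle mean deflections: the montage's polarity convention
    # must not decide the sign of the agreement
    ear <- vapply(ang, function(a) abs(mean(sub[[pair_col]][sub$amplitude_deg == a])),
                  numeric(1))
    gold <- vapply(ang, function(a) abs(mean(sub$gold[sub$amplitude_deg == a])),
                   numeric(1))
    ct <- if (length(ang) >= 3) {
      deflection_amplitude_correlation(ear, gold)
    } else NULL
    rows[[length(rows) + 1]] <- data.frame(
      direction = d, montage = pair_col,
      n_angles = length(ang), n_saccades = nrow(sub),
      r_ear_gold = if (is.null(ct)) NA_real_ else ct$statistic,
      p_value = if (is.null(ct)) NA_real_ else ct$p_value,
      reliable = axis == "horizontal")
  }
  do.call(rbind, rows)
}
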