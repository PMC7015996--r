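#' Canonical hemodynamic profiles for simulated corpora
#'
#' Two carotid flow profiles spanning the range seen in healthy dogs: a
#' low-resistance profile (PSV 120, EDV 45 cm/s, broad systolic pulse,
#' pulsatility index near 1) and a high-resistance profile (PSV 160, EDV
#' 15 cm/s, sharp systolic pulse, pulsatility index near 4).
#'
#' @return Named list of profile parameter lists (`psv`, `edv`,
#'   `heart_rate`, `systole_frac`, `decay_frac`).
#' @export
doppler_profiles <- function() {
  list(
    low_resistance = list(psv = 120, edv = 45, heart_rate = 110,
                          systole_frac = 0.30, decay_frac = 0.20),
    high_resistance = list(psv = 160, edv = 15, heart_rate = 130,
                           systole_frac = 0.10, decay_frac = 0.08)
  )
}

#' Simulate a corpus of Doppler recordings from multiple subjects
#'
#' Subjects are assigned to the given hemodynamic profiles in round-robin
#' order; each subject receives a small random perturbation of the profile
#' (velocities by ~3%, heart rate by a few beats/min), and each of its
#' recordings is synthesized with its own derived seed. Alternate recordings
#' of a subject are labelled left/right vessel side.
#'
#' @param n_subjects Number of subjects.
#' @param recordings_per_subject Recordings per subject.
#' @param duration Recording length, s (at least 8 cycles must fit).
#' @param seed Root seed; everything is derived from it.
#' @param profiles List of profiles as in [doppler_profiles()].
#' @param noise_floor,spectral_bandwidth,doppler_scale Passed to
#'   [simulation_config()].
#' @return List with `signals` (list of [audio_signal()] with ground-truth
#'   waveforms attached), `configs` (their [simulation_config()]s) and
#'   `manifest` (data frame: recording_id, subject_id, vessel_side, profile,
#'   psv, edv, heart_rate).
#' @export
simulate_corpus <- function(n_subjects = 10L, recordings_per_subject = 4L,
                            duration = 4, seed = 1L,
                            profiles = doppler_profiles(),
                            noise_floor = 0.01, spectral_bandwidth = 200,
                            doppler_scale = 20) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  recordings_per_subject <- check_count(recordings_per_subject,
                                        "recordings_per_subject")
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  signals <- list(); configs <- list(); rows <- list()
  rec_seed <- seed %% 100000L
  for (s in seq_len(n_subjects)) {
    prof_name <- names(profiles)[(s - 1L) %% length(profiles) + 1L]
    prof <- profiles[[prof_name]]
    psv <- prof$psv * stats::rnorm(1, 1, 0.03)
    edv <- min(prof$edv * stats::rnorm(1, 1, 0.03), 0.9 * psv)
    hr <- prof$heart_rate + stats::rnorm(1, 0, 3)
    hr <- max(hr, 8 * 60 / duration)  # keep >= 8 cycles in the recording
    subject_id <- sprintf("dog%02d", s)
    for (r in seq_len(recordings_per_subject)) {
      rec_seed <- rec_seed + 7919L
      side <- c("left", "right")[(r - 1L) %% 2L + 1L]
      cfg <- simulation_config(
        heart_rate = hr, psv = psv, edv = edv, duration = duration,
        doppler_scale = doppler_scale,
        spectral_bandwidth = spectral_bandwidth, noise_floor = noise_floor,
        systole_frac = prof$systole_frac, decay_frac = prof$decay_frac,
        seed = rec_seed, subject_id = subject_id,
        recording_id = sprintf("%s_%s_%d", subject_id, side, r))
      sig <- synthesize_doppler_audio(cfg)
      sig$vessel_side <- side
      signals[[cfg$recording_id]] <- sig
      configs[[cfg$recording_id]] <- cfg
      rows[[cfg$recording_id]] <- data.frame(
        recording_id = cfg$recording_id, subject_id = subject_id,
        vessel_side = side, profile = prof_name,
        psv = psv, edv = edv, heart_rate = hr, stringsAsFactors = FALSE)
    }
  }
  list(signals = signals, configs = configs,
       manifest = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Pipeline configuration
#'
#' Collects every tunable of the fingerprinting pipeline with its default,
#' validated against the stage preconditions. A YAML or JSON file with a
#' subset of these fields can be loaded via `config_file`; explicitly passed
#' arguments override file values.
#'
#' @param n_freq,bin_size,first_bin,last_bin,n_peaks Spectral stage
#'   parameters; see [compute_periodogram()] through
#'   [find_prominent_peaks()].
#' @param n_components,dist_pcs,n_each Similarity stage parameters; see
#'   [fit_pca()], [score_distances()], [select_pairs()].
#' @param mu0 Chance-level mean for the panel t-test.
#' @param n_subjects,recordings_per_subject,duration Simulated-corpus shape
#'   (used when no input directory is given).
#' @param seed Root seed for all randomness.
#' @param config_file Optional YAML/JSON file with defaults.
#' @return Validated named list of class `"run_config"`.
#' @export
run_config <- function(n_freq = 100000L, bin_size = 80L, first_bin = 10L,
                       last_bin = 200L, n_peaks = 10L, n_components = 4L,
                       dist_pcs = 2L, n_each = 5L, mu0 = 2.5,
                       n_subjects = 10L, recordings_per_subject = 4L,
                       duration = 4, seed = 1L, config_file = NULL) {
  cfg <- list(n_freq = n_freq, bin_size = bin_size, first_bin = first_bin,
              last_bin = last_bin, n_peaks = n_peaks,
              n_components = n_components, dist_pcs = dist_pcs,
              n_each = n_each, mu0 = mu0, n_subjects = n_subjects,
              recordings_per_subject = recordings_per_subject,
              duration = duration, seed = seed)
  if (!is.null(config_file)) {
    from_file <- if (grepl("\\.json$", config_file, ignore.case = TRUE))
      jsonlite::read_json(config_file, simplifyVector = TRUE)
    else yaml::read_yaml(config_file)
    unknown <- setdiff(names(from_file), names(cfg))
    if (length(unknown))
      stop_("unknown config field(s): %s", paste(unknown, collapse = ", "),
            class = "validation_error")
    passed <- names(match.call())[-1]
    for (f in setdiff(names(from_file), passed)) cfg[[f]] <- from_file[[f]]
  }
  for (f in c("n_freq", "bin_size", "first_bin", "last_bin", "n_peaks",
              "n_components", "dist_pcs", "n_each", "n_subjects",
              "recordings_per_subject"))
    cfg[[f]] <- check_count(cfg[[f]], f)
  check_number(cfg$mu0, "mu0", class = "validation_error")
  check_number(cfg$duration, "duration", lower = 0, strict_lower = TRUE,
               class = "validation_error")
  if (cfg$first_bin > cfg$last_bin)
    stop_("first_bin must not exceed last_bin", class = "validation_error")
  if (cfg$dist_pcs > cfg$n_components)
    stop_("dist_pcs must not exceed n_components", class = "validation_error")
  structure(cfg, class = "run_config")
}

log_stage <- function(fmt, ...) message(sprintf(paste0("[dopplerprint] ", fmt), ...))

#' Run the full fingerprinting pipeline
#'
#' Chains the two data streams end to end: obtain recordings (read from
#' `input_dir` with a metadata sidecar, or simulate a corpus), fingerprint
#' every recording, index the collection by PCA (with venetian-blinds PRESS),
#' compute score distances, select similar/dissimilar cross-subject pairs,
#' and — when ground-truth or supplied velocity waveforms are available —
#' compute time-domain hemodynamic indices, run the comparison PCA and rank
#' the selected pairs under both distance tables. Writes all artifacts to
#' `output_dir` and logs each stage.
#'
#' @param output_dir Directory for artifacts (created if needed):
#'   `fingerprints.csv`/`.json`, `pca_scores.csv`, `pca_loadings.csv`,
#'   `explained_variance.csv`, `press.csv`, `pairs.json`, `ranking.csv`,
#'   `indices.csv`, `report.json`.
#' @param config A [run_config()].
#' @param input_dir Optional directory of WAV/AIFF recordings; if `NULL`, a
#'   corpus is simulated according to `config`.
#' @param metadata_csv Optional sidecar CSV (see [read_metadata()]) for
#'   `input_dir`.
#' @param ratings_csv Optional listener-panel ratings CSV; when given, panel
#'   statistics are added to the report.
#' @return Invisibly, a list with the in-memory artifacts: `collection`,
#'   `pca`, `press`, `distances`, `pairs`, `indices`, `ranking`, `report`.
#' @export
run_pipeline <- function(output_dir, config = run_config(), input_dir = NULL,
                         metadata_csv = NULL, ratings_csv = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  truths <- NULL; heart_rates <- NULL
  if (is.null(input_dir)) {
    log_stage("simulating corpus: %d subjects x %d recordings, %g s, seed %d",
              config$n_subjects, config$recordings_per_subject,
              config$duration, config$seed)
    corpus <- simulate_corpus(config$n_subjects,
                              config$recordings_per_subject,
                              duration = config$duration, seed = config$seed)
    signals <- corpus$signals
    truths <- lapply(signals, attr, "truth")
    heart_rates <- vapply(corpus$configs, `[[`, numeric(1), "heart_rate")
    utils::write.csv(corpus$manifest, file.path(output_dir, "manifest.csv"),
                     row.names = FALSE)
  } else {
    meta <- if (!is.null(metadata_csv)) read_metadata(metadata_csv) else {
      paths <- list.files(input_dir, pattern = "\\.(wav|aiff?)$",
                          ignore.case = TRUE, full.names = TRUE)
      data.frame(recording_id = sub("\\.[^.]+$", "", basename(paths)),
                 subject_id = sub("\\.[^.]+$", "", basename(paths)),
                 vessel_side = "unknown", path = paths,
                 stringsAsFactors = FALSE)
    }
    log_stage("reading %d recordings from %s", nrow(meta), input_dir)
    signals <- lapply(seq_len(nrow(meta)), function(i)
      read_audio(meta$path[i], recording_id = meta$recording_id[i],
                 subject_id = meta$subject_id[i],
                 vessel_side = meta$vessel_side[i]))
    names(signals) <- meta$recording_id
  }

  log_stage("fingerprinting: %d-point periodogram, bin size %d, band %d-%d (%d bins), %d peaks",
            config$n_freq, config$bin_size, config$first_bin, config$last_bin,
            config$last_bin - config$first_bin + 1L, config$n_peaks)
  matrices <- lapply(signals, fingerprint_audio, n_freq = config$n_freq,
                     bin_size = config$bin_size, first_bin = config$first_bin,
                     last_bin = config$last_bin, n_peaks = config$n_peaks)
  collection <- build_fingerprints(unname(matrices))
  write_fingerprints(collection, file.path(output_dir, "fingerprints.csv"),
                     file.path(output_dir, "fingerprints.json"))

  log_stage("indexing: PCA with %d components", config$n_components)
  pca <- fit_pca(collection$fingerprints, n_components = config$n_components)
  n <- nrow(collection$fingerprints)
  press <- tryCatch(
    venetian_blinds_press(collection$fingerprints, config$n_components,
                          n_splits = min(10L, n)),
    error = function(e) { log_stage("PRESS skipped: %s", conditionMessage(e)); NULL })
  utils::write.csv(data.frame(recording_id = rownames(pca$scores), pca$scores),
                   file.path(output_dir, "pca_scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(feature = rownames(pca$loadings), pca$loadings),
                   file.path(output_dir, "pca_loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(pca$explained_all),
                              explained_fraction = pca$explained_all),
                   file.path(output_dir, "explained_variance.csv"),
                   row.names = FALSE)
  if (!is.null(press))
    utils::write.csv(data.frame(k = seq_along(press), press = press),
                     file.path(output_dir, "press.csv"), row.names = FALSE)

  log_stage("pair selection: distances on %d PCs, %d pairs each",
            config$dist_pcs, config$n_each)
  distances <- score_distances(pca, n_pcs_for_distance = config$dist_pcs)
  subjects <- stats::setNames(collection$subject_ids, collection$recording_ids)
  pairs <- select_pairs(distances, subjects, n_each = config$n_each)
  jsonlite::write_json(list(similar = pairs$similar,
                            dissimilar = pairs$dissimilar,
                            distance_pcs = config$dist_pcs),
                       file.path(output_dir, "pairs.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  indices <- NULL; ranking <- NULL
  if (!is.null(truths)) {
    log_stage("time-domain branch: hemodynamic indices from ground-truth waveforms")
    indices <- do.call(rbind, lapply(names(truths), function(id) {
      ix <- compute_indices(truths[[id]], heart_rate = heart_rates[[id]],
                            subject_id = subjects[[id]],
                            vessel_side = signals[[id]]$vessel_side)
      cbind(recording_id = id, ix)
    }))
    utils::write.csv(indices, file.path(output_dir, "indices.csv"),
                     row.names = FALSE)
    td <- as.matrix(indices[, c("psv", "edv", "pi", "ri")])
    rownames(td) <- indices$recording_id
    td_pca <- fit_pca(td, n_components = min(config$n_components,
                                             ncol(td), nrow(td) - 1L))
    td_dist <- score_distances(td_pca,
                               n_pcs_for_distance = min(config$dist_pcs,
                                                        td_pca$n_components))
    ranking <- rank_pairs(pairs, distances, td_dist)
    utils::write.csv(ranking$ranking, file.path(output_dir, "ranking.csv"),
                     row.names = FALSE)
    log_stage("rank correlation (fingerprint vs time-domain): %.3f",
              ranking$spearman)
  }

  report <- list(
    n_recordings = n,
    n_band_bins = config$last_bin - config$first_bin + 1L,
    n_peak_values = 4L * config$n_peaks,
    n_fingerprint_features = 5L,
    explained_variance_fraction = pca$explained_variance_fraction,
    spearman_fingerprint_vs_time = if (!is.null(ranking)) ranking$spearman else NULL
  )
  if (!is.null(ratings_csv)) {
    log_stage("panel statistics from %s", ratings_csv)
    ratings <- read_ratings(ratings_csv)
    summ <- agreement_summary(ratings)
    tt <- one_sample_ttest(rater_scores(ratings), mu0 = config$mu0)
    kap <- tryCatch(fleiss_kappa(ratings), error = function(e) NULL)
    report$panel <- c(summ, list(t = tt$t, p = tt$p,
                                 kappa = if (!is.null(kap)) kap$kappa else NA))
  }
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done: artifacts in %s", output_dir)
  invisible(list(collection = collection, pca = pca, press = press,
                 distances = distances, pairs = pairs, indices = indices,
                 ranking = ranking, report = report))
}

#' Write a small synthetic test corpus to disk
#'
#' Generates up to ten short recordings (WAV plus ground-truth waveform
#' CSVs), a metadata sidecar, and a synthetic listener-panel ratings CSV
#' with the default score distribution of [synthetic_panel_ratings()].
#'
#' @param dir Output directory (created if needed).
#' @param seed Root seed.
#' @param n_recordings Number of recordings (max 10).
#' @param duration Recording length, s (max 5).
#' @return Invisibly, the manifest data frame (with a `path` column).
#' @export
make_fixtures <- function(dir, seed = 1L, n_recordings = 10L, duration = 4) {
  n_recordings <- check_count(n_recordings, "n_recordings")
  if (n_recordings > 10L || duration > 5)
    stop_("fixtures are capped at 10 recordings of 5 s", class = "validation_error")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- simulate_corpus(n_subjects = ceiling(n_recordings / 2),
                            recordings_per_subject = 2L,
                            duration = duration, seed = seed)
  manifest <- corpus$manifest[seq_len(n_recordings), , drop = FALSE]
  manifest$path <- paste0(manifest$recording_id, ".wav")
  for (i in seq_len(n_recordings)) {
    id <- manifest$recording_id[i]
    write_audio(corpus$signals[[id]], file.path(dir, manifest$path[i]))
    write_waveform(attr(corpus$signals[[id]], "truth"),
                   file.path(dir, paste0(id, "_truth.csv")))
  }
  utils::write.csv(manifest[, c("recording_id", "subject_id", "vessel_side",
                                "path")],
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  ratings <- synthetic_panel_ratings(seed = seed)
  long <- data.frame(rater_id = rep(rownames(ratings), ncol(ratings)),
                     set_id = rep(colnames(ratings), each = nrow(ratings)),
                     agrees = as.integer(ratings))
  utils::write.csv(long, file.path(dir, "ratings.csv"), row.names = FALSE)
  invisible(manifest)
}
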