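#' End-to-end reading-task experiment
#'
#' Partition each labelled recording into non-overlapping fixed-length
#' samples, featurize, build balanced train/test tables, and run the
#' three-family / three-feature-set model grid. When `out_dir` is given,
#' all artifacts (feature table, train/test tables, suite CSV + JSON,
#' resolved config, provenance with per-stage counts) are written there.
#'
#' @param recordings list of `list(wave = waveform, label = "HC"|"PD")`.
#' @param seed integer seed driving the split and the cross-validation.
#' @param cepstral a [cepstral_config].
#' @param sample_len_s partition length in seconds (default 1.0).
#' @param split optional [split_spec]; by default 80/20 of the smaller
#'   class, balanced.
#' @param cv optional [cv_config] (default 5x5 folds from `seed`).
#' @param out_dir optional output directory.
#' @return List: `features`, `tables`, `suite`, `audit`, `provenance`.
#' @export
run_reading <- function(recordings, seed, cepstral = cepstral_config(),
                        sample_len_s = 1.0, split = NULL, cv = NULL,
                        out_dir = NULL) {
  if (length(recordings) == 0L) stop("empty recording manifest")
  features <- featurize_cohort(recordings, cepstral, sample_len_s)
  if (is.null(split)) {
    m <- min(table(features$label))
    per_te <- max(1L, floor(m * 0.2))
    split <- split_spec(2L * (m - per_te), 2L * per_te, seed = seed)
  }
  if (is.null(cv)) cv <- cv_config(seed = seed)
  tables <- build_tables(features, split)
  suite <- run_model_suite(tables$train, tables$test, cv)
  audit <- audit_table(tables$train, tables$test)
  provenance <- list(
    package_version = as.character(utils::packageVersion("pdvoice")),
    task = "reading", seed = seed,
    cepstral = cepstral[!vapply(cepstral, is.null, logical(1))],
    sample_len_s = sample_len_s,
    split = unclass(split), cv = unclass(cv),
    counts = list(recordings = length(recordings),
                  samples_featurized = nrow(features),
                  train_rows = nrow(tables$train),
                  test_rows = nrow(tables$test)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(features, file.path(out_dir, "features.csv"))
    write_feature_table(tables$train, file.path(out_dir, "train.csv"))
    write_feature_table(tables$test, file.path(out_dir, "test.csv"))
    write_suite(suite, file.path(out_dir, "suite.csv"),
                file.path(out_dir, "suite.json"))
    write_config(provenance$cepstral, file.path(out_dir, "cepstral_config.txt"))
    jsonlite::write_json(c(provenance, list(audit = list(
      class_counts = as.list(audit$class_counts),
      n_subjects = audit$n_subjects,
      subject_overlap = audit$subject_overlap))),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  }
  list(features = features, tables = tables, suite = suite, audit = audit,
       provenance = provenance)
}

#' End-to-end conversation-task experiment
#'
#' Each two-party call is diarized; the subject's cluster (by default the
#' one with the greatest total speaking time, overridable per entry) is
#' extracted and every merged same-speaker segment becomes one audio
#' sample. Samples are featurized, balanced tables built, the model grid
#' run, and the per-coefficient group panel computed on the extracted
#' feature rows.
#'
#' @param conversations list of `list(wave = waveform,
#'   label = "HC"|"PD", subject_cluster = optional integer override)`.
#' @param seed integer seed.
#' @param diarization a [diarization_config].
#' @param cepstral a [cepstral_config].
#' @param split optional [split_spec] (default 80/20 balanced).
#' @param cv optional [cv_config].
#' @param panel_variant,panel_correction options of [coefficient_panel].
#' @param out_dir optional output directory (also receives one RTTM and
#'   one extracted-subject WAV per conversation).
#' @return List: `features`, `tables`, `suite`, `panel`, `diarizations`,
#'   `provenance`.
#' @export
run_conversation <- function(conversations, seed,
                             diarization = diarization_config(),
                             cepstral = cepstral_config(), split = NULL,
                             cv = NULL, panel_variant = "student",
                             panel_correction = "none", out_dir = NULL) {
  if (length(conversations) == 0L) stop("empty conversation manifest")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  diars <- list()
  rows <- list()
  for (i in seq_along(conversations)) {
    conv <- conversations[[i]]
    d <- tryCatch(diarize(conv$wave, diarization), error = function(e) e)
    if (inherits(d, "error")) {
      warning("skipping ", conv$wave$source_id, ": ", conditionMessage(d))
      next
    }
    cl <- if (!is.null(conv$subject_cluster)) conv$subject_cluster
          else dominant_cluster(d)
    seg <- d$segments[d$segments$cluster == cl, , drop = FALSE]
    min_len <- cepstral$frame_len_s * 3
    vecs <- list()
    for (s in seq_len(nrow(seg))) {
      if (seg$end[s] - seg$start[s] < min_len) next
      a <- round(seg$start[s] * conv$wave$rate) + 1L
      b <- min(length(conv$wave$samples), round(seg$end[s] * conv$wave$rate))
      piece <- waveform(conv$wave$samples[a:b], conv$wave$rate,
                        conv$wave$source_id)
      v <- featurize_sample(piece, cepstral, label = conv$label)
      df <- as.data.frame(as.list(v))
      names(df) <- names(v)
      df$label <- conv$label
      df$source_id <- conv$wave$source_id
      df$chunk_index <- s
      vecs[[length(vecs) + 1L]] <- df
    }
    rows[[length(rows) + 1L]] <- do.call(rbind, vecs)
    diars[[conv$wave$source_id]] <- d
    if (!is.null(out_dir)) {
      write_rttm(d$segments, file.path(out_dir, paste0(conv$wave$source_id, ".rttm")),
                 file_id = conv$wave$source_id)
      write_wav(extract_speaker_audio(conv$wave, d, cl),
                file.path(out_dir, sprintf("%s_spk%d.wav", conv$wave$source_id, cl)))
    }
  }
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  if (is.null(split)) {
    m <- min(table(features$label))
    per_te <- max(1L, floor(m * 0.2))
    split <- split_spec(2L * (m - per_te), 2L * per_te, seed = seed)
  }
  if (is.null(cv)) cv <- cv_config(seed = seed)
  tables <- build_tables(features, split)
  suite <- run_model_suite(tables$train, tables$test, cv)
  panel <- coefficient_panel(features[features$label == "HC", ],
                             features[features$label == "PD", ],
                             variant = panel_variant,
                             correction = panel_correction)
  provenance <- list(
    package_version = as.character(utils::packageVersion("pdvoice")),
    task = "conversation", seed = seed,
    diarization = list(window_s = diarization$window_s,
                       hop_s = diarization$hop_s,
                       n_speakers = diarization$n_speakers,
                       include_noise_cluster = diarization$include_noise_cluster,
                       smoothing_width = diarization$smoothing_width,
                       seed = diarization$seed),
    split = unclass(split), cv = unclass(cv),
    counts = list(conversations = length(conversations),
                  diarized = length(diars),
                  samples_featurized = nrow(features),
                  train_rows = nrow(tables$train),
                  test_rows = nrow(tables$test)))
  if (!is.null(out_dir)) {
    write_feature_table(features, file.path(out_dir, "features.csv"))
    write_suite(suite, file.path(out_dir, "suite.csv"),
                file.path(out_dir, "suite.json"))
    utils::write.csv(panel, file.path(out_dir, "panel.csv"), row.names = FALSE)
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(features = features, tables = tables, suite = suite, panel = panel,
       diarizations = diars, provenance = provenance)
}
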