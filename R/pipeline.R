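# End-to-end pipeline and command-line entry points.

#' Run the full pipeline
#'
#' generate -> telemetry -> preprocess -> featurize -> train ->
#' evaluate, persisting every intermediate: WAV recordings plus CSV
#' manifest, an HDF5 feature store, and JSON/Markdown evaluation
#' reports. Identical configurations produce identical artifacts.
#'
#' @param config A [default_pipeline_config()].
#' @param verbose Print stage progress.
#' @return The `evaluation_report`, invisibly; artifacts under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  tel <- telemetry_config(
    supply_voltage = config$telemetry$supply_voltage,
    reference_resistance = config$telemetry$reference_resistance,
    adc_bits = config$telemetry$adc_bits,
    sampling_rate = config$telemetry$sampling_rate,
    adpcm_bits_per_sample = config$telemetry$adpcm_bits_per_sample)

  if (config$synthgen$n_subjects < 2L && config$evaluation$scheme == "loso")
    stop("leave-one-subject-out evaluation requires at least 2 subjects; ",
         "got n_subjects = ", config$synthgen$n_subjects)

  say("[generate] %d subjects x 6 emotions x 5 sentences x %d reps",
      config$synthgen$n_subjects, config$synthgen$reps_per_cell)
  corpus <- generate_corpus(config$synthgen$n_subjects,
                            config$synthgen$reps_per_cell,
                            master_seed = config$master_seed,
                            telemetry = tel,
                            apply_adpcm = config$telemetry$apply_adpcm)
  manifest <- corpus$manifest
  if (isTRUE(config$synthgen$write_wavs)) {
    wav_dir <- file.path(out, "wav")
    dir.create(wav_dir, showWarnings = FALSE)
    manifest$path <- file.path("wav", paste0(manifest$recording_id, ".wav"))
    for (i in seq_along(corpus$recordings))
      write_wav(corpus$recordings[[i]], file.path(out, manifest$path[i]))
    say("[generate] wrote %d WAV files", nrow(manifest))
  }
  write_manifest(manifest, file.path(out, "manifest.csv"))

  say("[featurize] extracting %d feature matrices", nrow(manifest))
  pp <- preprocess_config(
    preemphasis_alpha = config$preprocess$preemphasis_alpha,
    n_frames = config$preprocess$n_frames,
    frame_length_samples = config$preprocess$frame_length_samples)
  features <- lapply(corpus$recordings, function(rec) {
    tryCatch(extract_features(rec, pp), error = function(e)
      stop("featurize failed for recording ", rec$seed, ": ",
           conditionMessage(e)))
  })
  names(features) <- manifest$recording_id
  write_feature_store(features, manifest, file.path(out, "features.h5"))

  desc <- lapply(corpus$recordings, prosodic_descriptors,
                 with_delta_mfcc = FALSE)
  desc_df <- cbind(manifest[, MANIFEST_COLUMNS],
                   do.call(rbind, lapply(desc, function(d)
                     as.data.frame(d[c("speech_rate", "pause_rate",
                                       "mean_norm_amplitude",
                                       "peak_to_peak_norm", "energy_mean",
                                       "energy_sd")]))))
  utils::write.csv(desc_df, file.path(out, "descriptors.csv"),
                   row.names = FALSE)

  say("[evaluate] %s", config$evaluation$scheme)
  rcfg <- config$recognizer
  if (!inherits(rcfg, "recognizer_config"))
    rcfg <- do.call(recognizer_config, rcfg)
  report <- run_loso(features, manifest, rcfg,
                     seed = config$master_seed, verbose = verbose)
  write_evaluation_report(report, file.path(out, "report.json"))
  write_evaluation_report(report, file.path(out, "report.md"))

  run_info <- list(package_version = as.character(utils::packageVersion("throatspeech")),
                   master_seed = config$master_seed,
                   n_recordings = nrow(manifest),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(run_info, file.path(out, "run_info.json"),
                       auto_unbox = TRUE)
  say("[done] emotion %.3f +/- %.3f, text %.3f +/- %.3f",
      report$emotion_accuracy_mean, report$emotion_accuracy_sd,
      report$text_accuracy_mean, report$text_accuracy_sd)
  invisible(report)
}

#' Command-line interface
#'
#' Umbrella dispatcher used by the `inst/cli/throatspeech` script:
#' subcommands `generate`, `telemetry`, `featurize`, `evaluate`,
#' `pipeline`.
#'
#' @param args Character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)` by default).
#' @return Exit status, invisibly.
#' @export
throatspeech_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: throatspeech <command> [options]",
    "  generate  --subjects N --reps N --seed N --out DIR",
    "  telemetry --roundtrip IN.wav OUT.wav",
    "  featurize --manifest DIR/manifest.csv --out FEATURES.h5",
    "  evaluate  --features FEATURES.h5 --seed N --out REPORT.json",
    "  pipeline  [--config CONFIG.yaml] [--seed N] [--out DIR]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; rest <- args[-1]
  opt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (!length(i)) return(default)
    rest[i[1] + 1L]
  }
  switch(cmd,
    generate = {
      out <- opt("--out", "throat_out")
      dir.create(file.path(out, "wav"), showWarnings = FALSE, recursive = TRUE)
      corpus <- generate_corpus(
        as.integer(opt("--subjects", "4")),
        as.integer(opt("--reps", "10")),
        as.integer(opt("--seed", "1")))
      manifest <- corpus$manifest
      manifest$path <- file.path("wav", paste0(manifest$recording_id, ".wav"))
      for (i in seq_along(corpus$recordings))
        write_wav(corpus$recordings[[i]], file.path(out, manifest$path[i]))
      write_manifest(manifest, file.path(out, "manifest.csv"))
      message(nrow(manifest), " recordings written to ", out)
    },
    telemetry = {
      stopifnot(identical(rest[1], "--roundtrip"))
      rec <- read_wav(rest[2])
      rec$samples <- adpcm_roundtrip(rec$samples)
      write_wav(rec, rest[3])
      message("round-tripped ", rest[2], " -> ", rest[3])
    },
    featurize = {
      man_path <- opt("--manifest")
      manifest <- read_manifest(man_path)
      base <- dirname(man_path)
      features <- lapply(seq_len(nrow(manifest)), function(i) {
        rec <- read_wav(file.path(base, manifest$path[i]),
                        metadata = as.list(manifest[i, ]))
        extract_features(rec)
      })
      names(features) <- manifest$recording_id
      write_feature_store(features, manifest, opt("--out", "features.h5"))
      message(length(features), " feature matrices written")
    },
    evaluate = {
      store <- read_feature_store(opt("--features", "features.h5"))
      report <- run_loso(store$features, store$manifest,
                         seed = as.integer(opt("--seed", "1")))
      write_evaluation_report(report, opt("--out", "report.json"))
      message(sprintf("emotion %.3f, text %.3f",
                      report$emotion_accuracy_mean,
                      report$text_accuracy_mean))
    },
    pipeline = {
      cfg_path <- opt("--config")
      config <- if (is.null(cfg_path)) default_pipeline_config()
                else read_pipeline_config(cfg_path)
      seed <- opt("--seed"); if (!is.null(seed))
        config$master_seed <- as.integer(seed)
      outdir <- opt("--out"); if (!is.null(outdir))
        config$out_dir <- outdir
      run_pipeline(config)
    },
    { message("unknown command: ", cmd, "\n", usage); return(invisible(1L)) }
  )
  invisible(0L)
}
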