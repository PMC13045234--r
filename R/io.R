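# Readers/writers: WAV signals, CSV manifests, HDF5 feature store,
# YAML configuration.

MANIFEST_COLUMNS <- c("recording_id", "subject_id", "emotion",
                      "sentence_id", "repetition", "seed")

#' Write a recording as 16-bit PCM WAV
#'
#' Mono, sampled at the recording's rate; 12-bit ADC codes are mapped
#' linearly onto the 16-bit sample range (`(code - 2048) * 16`).
#'
#' @param rec A `throat_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "throat_recording"))
  pcm <- as.integer((rec$samples - 2048L) * 16L)
  n <- length(pcm)
  fs <- as.integer(rec$sampling_rate)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")    # PCM
  writeBin(1L, con, size = 2, endian = "little")    # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")    # block align
  writeBin(16L, con, size = 2, endian = "little")   # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM WAV written by [write_wav()]
#'
#' Supports mono 16-bit PCM. Samples are mapped back to 12-bit ADC
#' codes.
#'
#' @param path WAV file path.
#' @param metadata Optional named list merged into the recording
#'   (subject_id, emotion, sentence_id, repetition, seed).
#' @return A `throat_recording`.
#' @export
read_wav <- function(path, metadata = list()) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAV file: ", path)
  fs <- NULL; bits <- NULL; channels <- NULL; pcm <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0 || nchar(tag) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (tag == "fmt ") {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      channels <- fmt[2]
      fs <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "integer", size = 4, endian = "little"))
      invisible(readBin(con, "integer", size = 2, endian = "little"))
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16) invisible(readBin(con, "raw", n = size - 16L))
    } else if (tag == "data") {
      pcm <- readBin(con, "integer", n = size %/% 2L, size = 2,
                     signed = TRUE, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
  if (is.null(pcm)) stop("no data chunk found in ", path)
  if (channels != 1L || bits != 16L)
    stop("only mono 16-bit WAV is supported")
  codes <- pmin(pmax(as.integer(round(pcm / 16)) + 2048L, 0L), 4095L)
  rec <- list(samples = codes, sampling_rate = fs,
              subject_id = metadata$subject_id %||% NA_integer_,
              emotion = metadata$emotion %||% NA_character_,
              sentence_id = metadata$sentence_id %||% NA_integer_,
              repetition = metadata$repetition %||% NA_integer_,
              seed = metadata$seed %||% NA_integer_,
              duration = length(codes) / fs)
  structure(rec, class = "throat_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a corpus manifest as CSV
#'
#' @param manifest Data frame with at least the columns
#'   `recording_id, subject_id, emotion, sentence_id, repetition, seed`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a corpus manifest from CSV
#'
#' Unknown columns are preserved; missing required columns and
#' duplicate recording ids are rejected.
#'
#' @param path CSV path.
#' @return The manifest data frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
  m
}

validate_manifest <- function(m) {
  stopifnot(is.data.frame(m))
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(m))
  if (length(missing_cols))
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(m$recording_id))
    stop("manifest contains duplicate recording_id: ",
         m$recording_id[duplicated(m$recording_id)][1])
  invisible(m)
}

#' Write feature matrices to an HDF5 store
#'
#' One dataset per recording under `/features/<recording_id>` (40 x 128,
#' 32-bit float) plus the label table under `/labels`.
#'
#' @param features Named list of `feature_matrix` objects (names =
#'   recording ids).
#' @param manifest The corpus manifest.
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_feature_store <- function(features, manifest, path) {
  validate_manifest(manifest)
  stopifnot(setequal(names(features), manifest$recording_id))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "features")
  for (id in names(features)) {
    v <- features[[id]]
    vals <- if (inherits(v, "feature_matrix")) v$values else v
    rhdf5::h5createDataset(path, paste0("features/", id),
                           dims = dim(vals), H5type = "H5T_IEEE_F32LE")
    rhdf5::h5write(vals, path, paste0("features/", id))
  }
  rhdf5::h5write(manifest, path, "labels")
  rhdf5::h5closeAll()
  invisible(path)
}

#' Read a feature store written by [write_feature_store()]
#'
#' @param path `.h5` path.
#' @return List with `features` (named list of 40 x 128 matrices) and
#'   `manifest`.
#' @export
read_feature_store <- function(path) {
  manifest <- rhdf5::h5read(path, "labels")
  # rhdf5 returns 1-d arrays for compound fields; flatten to vectors
  manifest <- as.data.frame(lapply(manifest, as.vector),
                            stringsAsFactors = FALSE)
  ids <- manifest$recording_id
  features <- lapply(ids, function(id) {
    rhdf5::h5read(path, paste0("features/", id))
  })
  names(features) <- ids
  rhdf5::h5closeAll()
  validate_manifest(manifest)
  list(features = features, manifest = manifest)
}

#' Default pipeline configuration
#'
#' Nested configuration for every stage, serializable to YAML and back
#' without loss.
#'
#' @param master_seed Master seed for corpus generation and training.
#' @param out_dir Output directory for pipeline artifacts.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(master_seed = 1L, out_dir = "throat_out") {
  structure(list(
    master_seed = as.integer(master_seed),
    out_dir = out_dir,
    synthgen = list(n_subjects = 4L, reps_per_cell = 10L,
                    write_wavs = TRUE),
    telemetry = list(supply_voltage = 3.3, reference_resistance = 1e4,
                     adc_bits = 12L, sampling_rate = 4000L,
                     adpcm_bits_per_sample = 4L, apply_adpcm = TRUE),
    preprocess = list(preemphasis_alpha = 0.98, n_frames = 128L,
                      frame_length_samples = 128L),
    features = list(n_mfcc = 13L, n_mel_filters = 40L, n_fft = 256L),
    recognizer = recognizer_config(),
    evaluation = list(scheme = "loso", val_fraction = 0.2)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values found in the file override the defaults section-wise.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  merge_into <- function(base, extra) {
    for (nm in names(extra)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(extra[[nm]]))
        merge_into(base[[nm]], extra[[nm]]) else extra[[nm]]
    }
    base
  }
  structure(merge_into(unclass(cfg), user), class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
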