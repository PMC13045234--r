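# Feature extraction: 40 x 128 MFCC stack, mel spectrograms, prosodic
# descriptors.

FEATURE_ROWS <- 40L
N_MFCC <- 13L
N_MEL_FILTERS <- 40L
LOG_FLOOR <- 1e-10

mel_scale <- function(f) 2595 * log10(1 + f / 700)
mel_inv <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filterbank
#'
#' `n_filters` triangular filters with centres equally spaced on the mel
#' scale between `fmin` and `fmax` (capped at Nyquist).
#'
#' @param n_filters Number of filters.
#' @param n_fft FFT length.
#' @param sampling_rate Samples per second.
#' @param fmin,fmax Band edges in Hz.
#' @return `n_filters x (n_fft/2 + 1)` weight matrix.
#' @export
mel_filterbank <- function(n_filters = N_MEL_FILTERS, n_fft = 256L,
                           sampling_rate = 4000L, fmin = 0,
                           fmax = sampling_rate / 2) {
  fmax <- min(fmax, sampling_rate / 2)
  n_bins <- n_fft %/% 2L + 1L
  freqs <- (seq_len(n_bins) - 1) * sampling_rate / n_fft
  edges <- mel_inv(seq(mel_scale(fmin), mel_scale(fmax),
                       length.out = n_filters + 2L))
  fb <- matrix(0, n_filters, n_bins)
  for (i in seq_len(n_filters)) {
    lo <- edges[i]; mid <- edges[i + 1]; hi <- edges[i + 2]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[i, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# DCT-II matrix (orthonormal), rows = coefficients 0..(k-1)
dct_matrix <- function(k, n) {
  m <- outer(0:(k - 1), 0:(n - 1), function(p, q) {
    cos(pi * p * (2 * q + 1) / (2 * n))
  })
  m <- m * sqrt(2 / n)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

# Delta features by +/-2-frame linear regression, edge frames replicated.
delta_features <- function(m, window = 2L) {
  nfr <- ncol(m)
  denom <- 2 * sum((seq_len(window))^2)
  idx <- function(i) pmin(pmax(i, 1L), nfr)
  d <- matrix(0, nrow(m), nfr)
  for (w in seq_len(window)) {
    d <- d + w * (m[, idx(seq_len(nfr) + w), drop = FALSE] -
                    m[, idx(seq_len(nfr) - w), drop = FALSE])
  }
  d / denom
}

# Power spectra of a frame matrix (frames in rows), n_fft-point FFT.
frame_power_spectra <- function(frames, n_fft = 256L) {
  flen <- ncol(frames)
  n_bins <- n_fft %/% 2L + 1L
  padded <- cbind(frames, matrix(0, nrow(frames), n_fft - flen))
  sp <- stats::mvfft(t(padded))[seq_len(n_bins), , drop = FALSE]
  Mod(sp)^2 / n_fft          # bins x frames
}

#' Mel spectrogram of a frame sequence
#'
#' @param frames A `frame_sequence` from [frame_and_window()].
#' @param n_fft FFT length.
#' @param sampling_rate Samples per second.
#' @return An object of class `mel_spectrogram`: list with `values`
#'   (40 x n_frames nonnegative matrix) and `mel_band_edges` (Hz).
#' @export
mel_spectrogram <- function(frames, n_fft = 256L, sampling_rate = 4000L) {
  stopifnot(inherits(frames, "frame_sequence"))
  pw <- frame_power_spectra(frames$frames, n_fft)
  fb <- mel_filterbank(N_MEL_FILTERS, n_fft, sampling_rate)
  vals <- fb %*% pw
  edges <- mel_inv(seq(0, mel_scale(sampling_rate / 2),
                       length.out = N_MEL_FILTERS + 2L))
  structure(list(values = pmax(vals, 0), mel_band_edges = edges),
            class = "mel_spectrogram")
}

#' 40 x 128 MFCC feature stack
#'
#' Per frame: power spectrum, 40-filter mel energies, dB log
#' (floored), DCT-II; coefficients c1..c13 are kept. Rows 14-26 are the
#' +/-2-frame regression deltas, rows 27-39 the delta-deltas, and row 40
#' is the log raw-frame energy. (1-based row indexing.)
#'
#' @param frames A `frame_sequence` with exactly 128 frames.
#' @param n_fft FFT length.
#' @param sampling_rate Samples per second.
#' @return An object of class `feature_matrix`: list with `values`
#'   (40 x 128), and the row layout in `row_layout`.
#' @export
mfcc_stack <- function(frames, n_fft = 256L, sampling_rate = 4000L) {
  stopifnot(inherits(frames, "frame_sequence"))
  nfr <- nrow(frames$frames)
  pw <- frame_power_spectra(frames$frames, n_fft)
  fb <- mel_filterbank(N_MEL_FILTERS, n_fft, sampling_rate)
  mel <- pmax(fb %*% pw, LOG_FLOOR)
  logmel <- 10 * log10(mel)       # dB convention, as in librosa/HTK
  dct <- dct_matrix(N_MFCC + 1L, N_MEL_FILTERS)
  cep <- (dct %*% logmel)[-1L, , drop = FALSE]   # c1..c13
  d1 <- delta_features(cep)
  d2 <- delta_features(d1)
  raw <- if (!is.null(frames$frames_raw)) frames$frames_raw else frames$frames
  loge <- 10 * log10(pmax(rowMeans(raw^2), LOG_FLOOR))
  vals <- rbind(cep, d1, d2, loge)
  rownames(vals) <- c(paste0("c", 1:N_MFCC), paste0("d", 1:N_MFCC),
                      paste0("dd", 1:N_MFCC), "log_energy")
  structure(list(values = vals,
                 row_layout = c(mfcc = 13L, delta = 13L, delta2 = 13L,
                                log_energy = 1L)),
            class = "feature_matrix")
}

#' Full raw-recording-to-features path
#'
#' Normalizes ADC codes, applies pre-emphasis, detects endpoints, frames
#' the voiced span and computes the 40 x 128 stack. Recordings whose
#' voiced span is shorter than one frame fall back to framing the whole
#' trace.
#'
#' @param rec A `throat_recording` (see [synthesize_recording()]).
#' @param config A [preprocess_config()].
#' @return A `feature_matrix`.
#' @export
extract_features <- function(rec, config = preprocess_config()) {
  stopifnot(inherits(rec, "throat_recording"))
  x <- adc_normalize(rec$samples)
  y <- pre_emphasis(x, config$preemphasis_alpha)
  span <- detect_endpoints(y, config, rec$sampling_rate)
  if (span[2] - span[1] < config$frame_length_samples)
    span <- c(0L, length(y))
  fs <- frame_and_window(y, span, config)
  mfcc_stack(fs, sampling_rate = rec$sampling_rate)
}

#' Prosodic descriptors of a recording
#'
#' Measures the quantities used to characterise emotional prosody:
#' speech rate (voiced bursts per minute of recording), pause rate
#' (inter-burst silences of at least `pause_min_ms` per minute), mean
#' absolute normalized amplitude over voiced samples, peak-to-peak
#' normalized amplitude, and the mean/SD of per-frame normalized energy
#' (mean absolute amplitude on the 20 ms detector grid) over voiced
#' frames. `delta_mfcc_mean` is the mean absolute value of the
#' delta-MFCC block of the recording's feature stack.
#'
#' @param rec A `throat_recording`.
#' @param config A [preprocess_config()].
#' @param pause_min_ms Minimum silence length counted as a pause.
#' @param with_delta_mfcc Compute `delta_mfcc_mean` (runs the full
#'   feature path; slightly slower).
#' @return An object of class `prosodic_descriptors` (a named list).
#' @export
prosodic_descriptors <- function(rec, config = preprocess_config(),
                                 pause_min_ms = 200,
                                 with_delta_mfcc = TRUE) {
  stopifnot(inherits(rec, "throat_recording"))
  x <- adc_normalize(rec$samples)
  dur_min <- length(x) / rec$sampling_rate / 60
  segs <- detect_segments(x, config, rec$sampling_rate)
  zero <- structure(list(speech_rate = 0, pause_rate = 0,
                         mean_norm_amplitude = 0, peak_to_peak_norm = 0,
                         energy_mean = 0, energy_sd = 0,
                         delta_mfcc_mean = 0, n_bursts = 0L),
                    class = "prosodic_descriptors")
  if (!nrow(segs)) return(zero)
  n_bursts <- nrow(segs)
  gaps <- if (n_bursts > 1) segs[-1, 1] - segs[-n_bursts, 2] else numeric(0)
  n_pauses <- sum(gaps >= pause_min_ms / 1000 * rec$sampling_rate)
  voiced_idx <- unlist(lapply(seq_len(n_bursts), function(i) {
    (segs[i, 1] + 1L):segs[i, 2]
  }))
  xv <- x[voiced_idx]
  # frame-level energy = mean |x| per detector frame, voiced frames only
  prof <- short_time_profile(x, config, rec$sampling_rate)
  flen <- prof$frame_length
  fr_mid <- prof$start + flen / 2
  voiced_fr <- vapply(fr_mid, function(m) {
    any(m >= segs[, 1] & m < segs[, 2])
  }, logical(1))
  fr_abs <- vapply(which(voiced_fr), function(i) {
    mean(abs(x[(prof$start[i] + 1L):(prof$start[i] + flen)]))
  }, numeric(1))
  dmf <- if (with_delta_mfcc) {
    fm <- extract_features(rec, config)
    mean(abs(fm$values[14:26, ]))
  } else NA_real_
  structure(list(speech_rate = n_bursts / dur_min,
                 pause_rate = n_pauses / dur_min,
                 mean_norm_amplitude = mean(abs(xv)),
                 peak_to_peak_norm = max(x) - min(x),
                 energy_mean = mean(fr_abs),
                 energy_sd = if (length(fr_abs) > 1) stats::sd(fr_abs) else 0,
                 delta_mfcc_mean = dmf,
                 n_bursts = n_bursts),
            class = "prosodic_descriptors")
}
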