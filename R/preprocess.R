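# Preprocessing: pre-emphasis, endpoint detection, framing + windowing.

#' Preprocessing configuration
#'
#' Parameters of the analysis front end. Endpoint detection uses the
#' classical double-threshold short-time energy + zero-crossing-rate
#' scheme with thresholds set relative to an assumed-silent leading
#' prefix. Framing always yields exactly `n_frames` overlapping frames
#' by adapting the hop to the voiced-span length.
#'
#' @param preemphasis_alpha First-order high-pass coefficient.
#' @param n_frames Number of analysis frames (fixed matrix width).
#' @param frame_length_samples Analysis frame length in samples
#'   (32 ms at 4 ksps).
#' @param energy_frame_ms,energy_hop_ms Short-time energy grid for the
#'   detector, milliseconds.
#' @param energy_threshold_high,energy_threshold_low Multiples of the
#'   silence-floor RMS used as the double thresholds.
#' @param zcr_threshold Zero crossings per detector frame above which a
#'   low-energy frame is still treated as speech-like.
#' @param min_voiced_ms Segments shorter than this are discarded.
#' @param min_gap_ms Segments separated by less than this are merged.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(preemphasis_alpha = 0.98,
                              n_frames = 128L,
                              frame_length_samples = 128L,
                              energy_frame_ms = 20,
                              energy_hop_ms = 10,
                              energy_threshold_high = 4,
                              energy_threshold_low = 2,
                              zcr_threshold = 40,
                              min_voiced_ms = 40,
                              min_gap_ms = 40) {
  stopifnot(preemphasis_alpha > 0, preemphasis_alpha < 1,
            n_frames >= 2, frame_length_samples >= 8)
  structure(list(preemphasis_alpha = preemphasis_alpha,
                 n_frames = as.integer(n_frames),
                 frame_length_samples = as.integer(frame_length_samples),
                 energy_frame_ms = energy_frame_ms,
                 energy_hop_ms = energy_hop_ms,
                 energy_threshold_high = energy_threshold_high,
                 energy_threshold_low = energy_threshold_low,
                 zcr_threshold = zcr_threshold,
                 min_voiced_ms = min_voiced_ms,
                 min_gap_ms = min_gap_ms),
            class = "preprocess_config")
}

#' First-order pre-emphasis filter
#'
#' `y[1] = x[1]; y[n] = x[n] - alpha * x[n-1]`. Linear; boosts high
#' frequencies before spectral analysis.
#'
#' @param x Numeric trace.
#' @param alpha Coefficient in (0, 1).
#' @return Filtered trace, same length.
#' @export
pre_emphasis <- function(x, alpha = 0.98) {
  stopifnot(length(x) >= 1, alpha > 0, alpha < 1)
  c(x[1], x[-1] - alpha * x[-length(x)])
}

# Short-time energy (RMS) and zero-crossing counts on the detector grid.
# Returns one row per detector frame with its sample start (0-based).
short_time_profile <- function(x, config, sampling_rate = 4000L) {
  flen <- max(8L, as.integer(round(config$energy_frame_ms / 1000 * sampling_rate)))
  hop <- max(1L, as.integer(round(config$energy_hop_ms / 1000 * sampling_rate)))
  n <- length(x)
  if (n < flen) {
    return(list(rms = numeric(0), zcr = integer(0), start = integer(0),
                frame_length = flen, hop = hop))
  }
  starts <- seq(0L, n - flen, by = hop)
  idx <- outer(seq_len(flen), starts, `+`)     # 1-based sample indices
  fr <- matrix(x[idx], nrow = flen)
  rms <- sqrt(colMeans(fr^2))
  sgn <- sign(fr)
  sgn[sgn == 0] <- 1
  zcr <- colSums(abs(diff(sgn)) > 0)
  list(rms = rms, zcr = zcr, start = starts, frame_length = flen, hop = hop)
}

# Double-threshold segmenter. Returns a matrix with columns start,end
# (0-based, half-open, in samples), one row per detected segment.
detect_segments <- function(x, config = preprocess_config(),
                            sampling_rate = 4000L) {
  prof <- short_time_profile(x, config, sampling_rate)
  nf <- length(prof$rms)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nf == 0L) return(empty)
  # silence floor from the leading 100 ms, guarded against a hot start
  # by the lower decile of the whole profile; thresholds are capped
  # relative to the loudest frame so an all-voiced trace still passes,
  # and floored absolutely so a pure noise trace never does.
  n_sil <- max(3L, as.integer(round(100 / config$energy_hop_ms)))
  floor_rms <- max(min(stats::median(prof$rms[seq_len(min(n_sil, nf))]),
                       stats::quantile(prof$rms, 0.1)), 1e-5)
  max_rms <- max(prof$rms)
  t_high <- max(0.010, min(config$energy_threshold_high * floor_rms,
                           0.5 * max_rms))
  t_low <- max(0.005, min(config$energy_threshold_low * floor_rms,
                          0.22 * max_rms))
  above_high <- prof$rms > t_high
  above_low <- prof$rms > t_low |
    (prof$zcr > config$zcr_threshold & prof$rms > 1.5 * floor_rms)
  if (!any(above_high)) return(empty)
  # grow each high-energy run outward while frames pass the low threshold
  active <- above_low
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & vapply(seq_along(runs$values), function(i) {
    runs$values[i] && any(above_high[starts[i]:ends[i]])
  }, logical(1))
  segs <- cbind(starts[keep], ends[keep])
  if (!nrow(segs)) return(empty)
  # frame indices -> sample spans; the boundary estimate is the centre
  # of the first/last passing frame (the transition lies inside it),
  # which keeps span edges unbiased instead of smearing by one window
  half <- prof$frame_length %/% 2L
  span <- cbind(ifelse(segs[, 1] == 1L, prof$start[segs[, 1]],
                       prof$start[segs[, 1]] + half),
                ifelse(segs[, 2] == nf,
                       prof$start[segs[, 2]] + prof$frame_length,
                       prof$start[segs[, 2]] + half))
  # merge segments separated by a short gap
  min_gap <- config$min_gap_ms / 1000 * sampling_rate
  merged <- span[1, , drop = FALSE]
  if (nrow(span) > 1) {
    for (i in 2:nrow(span)) {
      if (span[i, 1] - merged[nrow(merged), 2] < min_gap) {
        merged[nrow(merged), 2] <- span[i, 2]
      } else {
        merged <- rbind(merged, span[i, ])
      }
    }
  }
  min_len <- config$min_voiced_ms / 1000 * sampling_rate
  merged <- merged[merged[, 2] - merged[, 1] >= min_len, , drop = FALSE]
  merged[, 2] <- pmin(merged[, 2], length(x))
  colnames(merged) <- c("start", "end")
  merged
}

#' Endpoint (voice activity) detection
#'
#' Locates the speech-bearing region with a double-threshold short-time
#' energy + zero-crossing-rate detector. Returns the tightest 0-based
#' half-open sample span covering all detected segments, or an empty
#' span (`c(0, 0)`) when nothing passes.
#'
#' @param x Numeric trace (normalized amplitude).
#' @param config A [preprocess_config()].
#' @param sampling_rate Samples per second.
#' @return Integer vector `c(start, end)`, half-open.
#' @export
detect_endpoints <- function(x, config = preprocess_config(),
                             sampling_rate = 4000L) {
  segs <- detect_segments(x, config, sampling_rate)
  if (!nrow(segs)) return(c(0L, 0L))
  c(as.integer(segs[1, 1]), as.integer(segs[nrow(segs), 2]))
}

#' Frame and window the voiced span
#'
#' Cuts exactly `n_frames` overlapping frames of `frame_length_samples`
#' out of the given span, with adaptive hop
#' `max(1, floor((span_len - frame_length) / (n_frames - 1)))`, and
#' applies a Hamming window to each frame. Frames that run past the end
#' of the trace are zero-padded.
#'
#' @param x Numeric trace.
#' @param span Integer `c(start, end)` 0-based half-open; from
#'   [detect_endpoints()].
#' @param config A [preprocess_config()].
#' @return An object of class `frame_sequence`: list with `frames`
#'   (`n_frames x frame_length` matrix), `frame_length`, `hop`,
#'   `voiced_span`.
#' @export
frame_and_window <- function(x, span, config = preprocess_config()) {
  flen <- config$frame_length_samples
  nfr <- config$n_frames
  span <- as.integer(span)
  span_len <- span[2] - span[1]
  if (span_len < flen)
    stop("voiced span has ", span_len, " samples; at least ", flen,
         " are required")
  hop <- max(1L, as.integer((span_len - flen) %/% (nfr - 1L)))
  starts <- span[1] + hop * (seq_len(nfr) - 1L)      # 0-based
  idx <- outer(seq_len(flen) - 1L, starts, `+`) + 1L # 1-based
  xs <- c(x, numeric(max(0L, max(idx) - length(x))))
  raw <- t(matrix(xs[idx], nrow = flen))
  w <- hamming_window(flen)
  frames <- sweep(raw, 2, w, `*`)
  structure(list(frames = frames, frames_raw = raw, frame_length = flen,
                 hop = hop, voiced_span = span),
            class = "frame_sequence")
}

#' Hamming window
#'
#' @param n Window length.
#' @return `0.54 - 0.46 * cos(2 * pi * k / (n - 1))`, `k = 0..n-1`.
#' @export
hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}
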