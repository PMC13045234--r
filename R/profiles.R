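# Emotion profiles, sentence templates and subject models for the
# synthetic-corpus generator.

EMOTIONS <- c("Angry", "Fear", "Happy", "Neutral", "Sad", "Surprise")
SENTENCE_TEXTS <- c("Let's go eat", "Today is a sunny day",
                    "Add me on contact", "Long time no see",
                    "Please speak louder")

# Default per-emotion prosody. Angry and Sad carry the published
# descriptor values; Fear/Happy/Neutral/Surprise sit on a documented
# grid between those extremes, chosen for mutual separability (see the
# methods vignette). Neutral is anchored by the "Sad energy is half of
# neutral" relation: amp/energy twice Sad's. Frame energy is defined as
# mean absolute normalized amplitude per 20 ms frame, which makes
# amp_norm and energy_mean coincide by construction.
EMOTION_DEFAULTS <- list(
  Angry    = list(speech_rate = 180, pause_rate = 2.8, amp_norm = 0.25,
                  peak_to_peak = 1.55, energy_mean = 0.25, energy_sd = 0.12,
                  articulation = 1.00,
                  energy_cv_between = 0.42,
                  clip_cal = 1.01,
                  f0_range = c(185, 235),
                  band_weights = c(0.45, 0.35, 0.20)),
  Fear     = list(speech_rate = 150, pause_rate = 4.5, amp_norm = 0.12,
                  peak_to_peak = 0.75, energy_mean = 0.12, energy_sd = 0.07,
                  articulation = 0.90,
                  energy_cv_between = 0.60,
                  clip_cal = 0.74,
                  f0_range = c(300, 350),
                  band_weights = c(0.25, 0.55, 0.20)),
  Happy    = list(speech_rate = 160, pause_rate = 3.5, amp_norm = 0.20,
                  peak_to_peak = 1.25, energy_mean = 0.20, energy_sd = 0.09,
                  articulation = 0.90,
                  energy_cv_between = 0.38,
                  clip_cal = 1.00,
                  f0_range = c(245, 295),
                  band_weights = c(0.45, 0.15, 0.40)),
  Neutral  = list(speech_rate = 120, pause_rate = 5.0, amp_norm = 0.16,
                  peak_to_peak = 1.00, energy_mean = 0.16, energy_sd = 0.06,
                  articulation = 0.60,
                  energy_cv_between = 0.30,
                  clip_cal = 1.21,
                  f0_range = c(150, 190),
                  band_weights = c(0.55, 0.35, 0.10)),
  Sad      = list(speech_rate = 100, pause_rate = 6.5, amp_norm = 0.08,
                  peak_to_peak = 0.50, energy_mean = 0.08, energy_sd = 0.04,
                  articulation = 0.45,
                  energy_cv_between = 0.51,
                  clip_cal = 1.11,
                  f0_range = c(100, 140),
                  band_weights = c(0.70, 0.25, 0.05)),
  Surprise = list(speech_rate = 130, pause_rate = 3.2, amp_norm = 0.22,
                  peak_to_peak = 1.40, energy_mean = 0.22, energy_sd = 0.13,
                  articulation = 1.10,
                  energy_cv_between = 0.61,
                  clip_cal = 0.82,
                  f0_range = c(355, 400),
                  band_weights = c(0.20, 0.40, 0.40))
)

# Frequency bands (Hz) over which band_weights distribute energy.
BAND_EDGES_HZ <- c(100, 500, 1500, 2000)

#' Emotion profile
#'
#' Returns the calibrated generator parameters for one of the six
#' emotions: speech rate (voiced word-bursts per minute), pause rate
#' (silences of at least 200 ms per minute), target mean normalized
#' amplitude of voiced samples, nominal peak-to-peak normalized
#' amplitude, per-frame energy mean/SD targets, fundamental-frequency
#' range of the glottal pulse train, and relative energy weights over
#' the 100-500 / 500-1500 / 1500-2000 Hz bands.
#'
#' @param emotion One of `"Angry"`, `"Fear"`, `"Happy"`, `"Neutral"`,
#'   `"Sad"`, `"Surprise"`.
#' @return An object of class `emotion_profile`.
#' @export
make_emotion_profile <- function(emotion) {
  if (length(emotion) != 1L || !emotion %in% EMOTIONS)
    stop("unknown emotion label: ", deparse(emotion),
         " (expected one of ", paste(EMOTIONS, collapse = ", "), ")")
  p <- EMOTION_DEFAULTS[[emotion]]
  p$emotion <- emotion
  validate_emotion_profile(structure(p, class = "emotion_profile"))
}

validate_emotion_profile <- function(p) {
  stopifnot(inherits(p, "emotion_profile"))
  if (!(p$speech_rate > 0)) stop("speech_rate must be positive")
  if (p$pause_rate < 0) stop("pause_rate must be nonnegative")
  if (!(p$amp_norm >= 0 && p$amp_norm <= 1))
    stop("amp_norm must lie in [0, 1]")
  if (any(p$band_weights < 0) ||
      abs(sum(p$band_weights) - 1) > 1e-8)
    stop("band_weights must be nonnegative and sum to 1")
  if (p$f0_range[1] < 80 || p$f0_range[2] > 400 ||
      p$f0_range[1] > p$f0_range[2])
    stop("f0_range must lie within [80, 400] Hz")
  if (p$energy_sd < 0) stop("energy_sd must be nonnegative")
  # joint feasibility of rate and pausing within a 2-4 s recording
  busy <- p$speech_rate / 60 * 0.19 + p$pause_rate / 60 * 0.30
  if (busy > 0.92)
    stop("speech_rate ", p$speech_rate, " and pause_rate ", p$pause_rate,
         " jointly exceed the available recording time")
  p
}

#' Sentence templates
#'
#' The five fixed sentences of the recognition task. Each template
#' carries a syllable count, a relative per-syllable duration pattern
#' (tiled over the word-bursts of a recording), a relative intonation
#' contour applied to the fundamental, and a nominal base duration.
#'
#' @param sentence_id Integer 0..4, or `NULL` for the full list.
#' @return A `sentence_template` (or list of all five).
#' @export
sentence_templates <- function(sentence_id = NULL) {
  # syllable_spectra: per-syllable multiplicative tilts of the emotion
  # band weights -- the synthetic stand-in for each sentence's phoneme
  # sequence, giving sentences a learnable spectral signature that is
  # (on average) neutral with respect to the emotion's band structure
  tpl <- list(
    list(sentence_id = 0L, text = SENTENCE_TEXTS[1], syllable_count = 3L,
         syllable_durations = c(1.0, 0.8, 1.3),
         f0_contour = c(1.13, 1.00, 0.84), base_duration = 2.6,
         syllable_spectra = list(c(2.14, 0.61, 0.61), c(0.45, 1.80, 1.00),
                                 c(1.00, 0.78, 2.14))),
    list(sentence_id = 1L, text = SENTENCE_TEXTS[2], syllable_count = 6L,
         syllable_durations = c(0.8, 1.1, 0.6, 0.7, 1.2, 1.0),
         f0_contour = c(0.92, 1.00, 1.08, 1.00, 1.16, 0.87),
         base_duration = 3.8,
         syllable_spectra = list(c(0.45, 1.50, 1.50), c(1.80, 0.78, 0.61),
                                 c(0.78, 1.80, 0.45), c(1.50, 0.45, 1.50),
                                 c(0.61, 1.23, 1.80), c(1.23, 1.00, 0.45))),
    list(sentence_id = 2L, text = SENTENCE_TEXTS[3], syllable_count = 5L,
         syllable_durations = c(1.1, 0.7, 0.7, 1.2, 0.9),
         f0_contour = c(1.00, 1.10, 0.92, 1.03, 0.81),
         base_duration = 3.3,
         syllable_spectra = list(c(1.80, 1.00, 0.45), c(0.61, 0.61, 2.50),
                                 c(1.50, 1.23, 0.45), c(0.45, 1.50, 1.23),
                                 c(1.80, 0.45, 1.00))),
    list(sentence_id = 3L, text = SENTENCE_TEXTS[4], syllable_count = 4L,
         syllable_durations = c(1.2, 1.1, 0.7, 1.4),
         f0_contour = c(0.87, 1.00, 1.13, 1.26), base_duration = 3.0,
         syllable_spectra = list(c(0.61, 2.14, 0.61), c(1.80, 0.61, 1.00),
                                 c(0.78, 1.00, 1.80), c(1.50, 1.50, 0.31))),
    list(sentence_id = 4L, text = SENTENCE_TEXTS[5], syllable_count = 4L,
         syllable_durations = c(0.9, 1.4, 1.0, 0.7),
         f0_contour = c(1.19, 0.90, 1.10, 0.78), base_duration = 2.9,
         syllable_spectra = list(c(1.50, 0.45, 1.80), c(0.61, 1.80, 0.78),
                                 c(1.80, 1.00, 0.61), c(0.45, 0.78, 2.50)))
  )
  tpl <- lapply(tpl, function(t) structure(t, class = "sentence_template"))
  if (is.null(sentence_id)) return(tpl)
  if (!sentence_id %in% 0:4) stop("sentence_id must be in 0..4")
  tpl[[sentence_id + 1L]]
}

#' Subject models
#'
#' Per-speaker variation: multiplicative fundamental-frequency and
#' amplitude scales, relative timing jitter of syllable durations, and
#' the sensor noise floor (normalized units). The four defaults emulate
#' the mixed-sex, mixed-age panel of the recording study and are
#' mutually distinct.
#'
#' @param n_subjects Number of subjects to return.
#' @return List of `subject_model` objects.
#' @export
default_subject_models <- function(n_subjects = 4L) {
  stopifnot(n_subjects >= 1)
  base <- list(
    list(subject_id = 0L, f0_scale = 1.00, amplitude_scale = 1.00,
         timing_jitter = 0.05, noise_floor = 0.005),
    list(subject_id = 1L, f0_scale = 0.88, amplitude_scale = 0.92,
         timing_jitter = 0.08, noise_floor = 0.006),
    list(subject_id = 2L, f0_scale = 1.12, amplitude_scale = 1.08,
         timing_jitter = 0.06, noise_floor = 0.004),
    list(subject_id = 3L, f0_scale = 0.94, amplitude_scale = 0.97,
         timing_jitter = 0.10, noise_floor = 0.007)
  )
  out <- lapply(seq_len(n_subjects), function(i) {
    if (i <= 4L) return(base[[i]])
    # deterministic extras beyond the default panel
    list(subject_id = i - 1L,
         f0_scale = 0.7 + 0.6 * ((i * 7) %% 11) / 10,
         amplitude_scale = 0.9 + 0.2 * ((i * 5) %% 7) / 6,
         timing_jitter = 0.05 + 0.01 * (i %% 5),
         noise_floor = 0.004 + 0.001 * (i %% 4))
  })
  lapply(out, function(s) structure(s, class = "subject_model"))
}

#' Neutral reference subject
#'
#' A subject with unit scales and a low noise floor, used when a
#' recording should reflect an emotion profile without speaker effects
#' (e.g. descriptor-recovery measurements).
#'
#' @return A `subject_model`.
#' @export
default_subject <- function() {
  structure(list(subject_id = 0L, f0_scale = 1, amplitude_scale = 1,
                 timing_jitter = 0.05, noise_floor = 0.005),
            class = "subject_model")
}
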