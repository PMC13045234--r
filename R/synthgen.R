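# Synthetic throat-vibration recordings: glottal pulse-train source,
# band shaping, prosodic timeline, telemetry chain.

# Calibration constants of the generator (fixed by design; see the
# methods vignette for how they were derived).
SYNTH_RAMP_S <- 0.015        # raised-cosine burst attack/decay, seconds
SYNTH_PULSE_DUTY <- 0.45     # open-phase fraction of a glottal period
SYNTH_CV_WITHIN <- 0.30      # frame-energy CV contributed within bursts
SYNTH_CLIP_CAL <- 1.10       # soft-limiter headroom for peak-to-peak
SYNTH_NOISE_REL <- 0.06      # in-burst aspiration noise, relative amplitude
SYNTH_MAX_NORM <- 0.97       # normalized-amplitude ceiling before ADC
SYNTH_REF_DURATION <- 3.12   # corpus-mean nominal duration, seconds

# Deterministic per-recording seed chain: LCG-style combine of the
# master seed with the cell coordinates; stays below 2^31 - 1.
derive_seed <- function(master_seed, ...) {
  h <- as.numeric(master_seed) %% 2147483647
  for (v in c(...)) {
    h <- (h * 48271 + as.numeric(v) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a private RNG stream; the caller's RNG state is
# untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Rectified-sine glottal pulse train at fundamental f0, unit peak.
glottal_pulse_train <- function(n_samples, f0, sampling_rate) {
  t <- (seq_len(n_samples) - 1) / sampling_rate
  phase <- (t * f0) %% 1
  ifelse(phase < SYNTH_PULSE_DUTY, sin(pi * phase / SYNTH_PULSE_DUTY), 0)
}

# Reweight the spectrum of a burst so band energies over BAND_EDGES_HZ
# match `weights`; removes DC and energy outside [80, 2000] Hz.
shape_bands <- function(x, weights, sampling_rate) {
  n <- length(x)
  if (n < 8L) return(x)
  sp <- stats::fft(x)
  freq <- (seq_len(n) - 1) / n * sampling_rate
  freq <- pmin(freq, sampling_rate - freq)   # mirror to [0, fs/2]
  gain <- numeric(n)
  edges <- BAND_EDGES_HZ
  e_tot <- sum(Mod(sp)^2)
  for (b in seq_len(length(edges) - 1L)) {
    sel <- freq >= edges[b] & freq < edges[b + 1L]
    e_b <- sum(Mod(sp[sel])^2)
    if (e_b > 1e-12 * e_tot) {
      gain[sel] <- sqrt(weights[b] / e_b)
    } else if (weights[b] > 0) {
      # band empty (e.g. f0 harmonics miss it): seed it with a flat comb
      sp[sel] <- sqrt(e_tot) * 1e-3
      gain[sel] <- sqrt(weights[b] / sum(Mod(sp[sel])^2))
    }
  }
  keep <- freq >= 80 & freq < edges[length(edges)]
  gain[!keep] <- 0
  Re(stats::fft(sp * gain, inverse = TRUE)) / n
}

# Scale-then-soft-clip so the burst has mean |x| exactly `target` with
# peaks bounded near `limit`; fixed-point iterations, exact final scale.
scale_and_limit <- function(x, target, limit) {
  m <- mean(abs(x))
  if (m < 1e-12 || target <= 0) return(x * 0)
  for (i in 1:3) {
    x <- x * (target / max(mean(abs(x)), 1e-12))
    x <- limit * tanh(x / limit)
  }
  x * (target / max(mean(abs(x)), 1e-12))
}

# Sub-phone articulation: split a burst into ~80 ms chunks, each with
# its own perturbation of the band weights, fundamental and gain,
# crossfaded; this is what gives the synthetic signal its
# frame-to-frame MFCC dynamics and part of its frame-energy spread.
# `artic` scales the spectral sigmas per emotion (pronounced dynamics
# for Angry, smooth voiceprint for Sad).
SYNTH_SUBPHONE_S <- 0.08
SYNTH_BW_SIGMA <- 0.12
SYNTH_F0_SUB_SIGMA <- 0.02
SYNTH_GAIN_SIGMA <- 0.25

articulated_burst <- function(n_s, f0, weights, sampling_rate,
                              artic = 1) {
  n_sub <- max(1L, as.integer(round(n_s / (SYNTH_SUBPHONE_S * sampling_rate))))
  bounds <- as.integer(round(seq(0, n_s, length.out = n_sub + 1L)))
  lg <- stats::rnorm(n_sub, 0, SYNTH_GAIN_SIGMA)
  if (n_sub >= 3L) {
    lg <- (lg - mean(lg)) / max(stats::sd(lg), 1e-9) * SYNTH_GAIN_SIGMA
  }
  out <- numeric(n_s)
  xfade <- as.integer(0.01 * sampling_rate)
  for (k in seq_len(n_sub)) {
    i0 <- bounds[k]; i1 <- bounds[k + 1L]
    lo <- max(0L, i0 - xfade); hi <- min(n_s, i1 + xfade)
    len <- hi - lo
    if (len < 8L) next
    w_k <- weights * exp(stats::rnorm(3, 0, SYNTH_BW_SIGMA * artic))
    w_k <- w_k / sum(w_k)
    f0_k <- min(400, max(80, f0 * exp(stats::rnorm(1, 0,
                                                   SYNTH_F0_SUB_SIGMA * artic))))
    seg <- glottal_pulse_train(len, f0_k, sampling_rate)
    seg <- shape_bands(seg, w_k, sampling_rate)
    seg <- seg * exp(lg[k])
    win <- rep(1, len)
    nin <- min(xfade, len %/% 2L)
    if (nin > 0) {
      ramp <- 0.5 - 0.5 * cos(pi * seq_len(nin) / nin)
      win[seq_len(nin)] <- ramp
      win[len - nin + seq_len(nin)] <- rev(ramp)
    }
    out[(lo + 1L):hi] <- out[(lo + 1L):hi] + seg * win
  }
  out
}

#' Synthesize one throat-vibration recording
#'
#' Builds a prosodic timeline (word-bursts, inter-word gaps, pauses,
#' lead/tail silence) matching the profile's speech and pause rates,
#' fills each burst with a band-shaped glottal pulse train plus
#' aspiration noise, scales voiced segments to the profile's amplitude
#' targets, and passes the normalized trace through the telemetry chain
#' (voltage divider, 12-bit ADC, ADPCM round trip). Identical arguments
#' yield bit-identical recordings.
#'
#' @param profile An [make_emotion_profile()] result.
#' @param sentence A [sentence_templates()] entry.
#' @param subject A subject model ([default_subject_models()]).
#' @param seed Nonnegative integer seed for this recording.
#' @param repetition Repetition index stored in the metadata.
#' @param telemetry A [telemetry_config()].
#' @param apply_adpcm Run the ADPCM round trip (as the firmware does).
#' @return An object of class `throat_recording`: integer `samples`
#'   (12-bit ADC codes), `sampling_rate`, and the label metadata.
#' @export
synthesize_recording <- function(profile, sentence, subject, seed,
                                 repetition = 0L,
                                 telemetry = telemetry_config(),
                                 apply_adpcm = TRUE) {
  stopifnot(inherits(profile, "emotion_profile"),
            inherits(sentence, "sentence_template"),
            inherits(subject, "subject_model"))
  if (seed < 0) stop("seed must be nonnegative")
  validate_emotion_profile(profile)
  fs <- telemetry$sampling_rate

  with_seed(seed, {
    # --- timeline ---------------------------------------------------
    d <- min(4, max(2, sentence$base_duration * stats::runif(1, 0.92, 1.08)))
    # leading silence covers the detector's 100 ms floor-estimation prefix
    lead <- stats::runif(1, 0.14, 0.20)
    tail <- stats::runif(1, 0.06, 0.12)
    mu_w <- profile$speech_rate * d / 60
    n_w <- max(1L, as.integer(floor(mu_w) + stats::rbinom(1, 1, mu_w %% 1)))
    # pauses are rare (< 1 per recording); a quasi-random draw keyed to
    # the recording seed keeps the corpus-level pause rate tight where
    # an independent Poisson draw would leave ~18% sampling noise over
    # a few hundred recordings
    mu_p <- profile$pause_rate * SYNTH_REF_DURATION / 60
    u_p <- (seed * 0.61803398874989) %% 1
    n_p <- as.integer(floor(mu_p) + (u_p < mu_p %% 1))
    n_p <- min(n_p, max(0L, n_w - 1L))
    pause_len <- stats::runif(n_p, 0.28, 0.45)
    gap_len <- if (n_w > 1) stats::runif(n_w - 1L, 0.10, 0.15) else numeric(0)
    voiced_total <- d - lead - tail - sum(pause_len) - sum(gap_len)
    # guard rare infeasible draws: shed pauses, then gaps, until words fit
    while (voiced_total / n_w < 0.08 && n_p > 0L) {
      n_p <- n_p - 1L
      pause_len <- pause_len[seq_len(n_p)]
      voiced_total <- d - lead - tail - sum(pause_len) - sum(gap_len)
    }
    if (voiced_total / n_w < 0.06)
      stop("profile speech_rate/pause_rate jointly infeasible within ",
           signif(d, 3), " s")
    pat <- rep_len(sentence$syllable_durations, n_w)
    pat <- pat * exp(stats::rnorm(n_w, 0, subject$timing_jitter))
    word_len <- voiced_total * pat / sum(pat)
    pause_after <- if (n_p > 0)
      sort(sample.int(n_w - 1L, n_p)) else integer(0)

    # --- per-burst synthesis ---------------------------------------
    f0_rec <- stats::runif(1, profile$f0_range[1], profile$f0_range[2]) *
      subject$f0_scale
    contour <- rep_len(sentence$f0_contour, n_w)
    # between-burst loudness spread; the profile carries a calibrated
    # value (accounts for within-burst spread and limiter compression),
    # with a derivation fallback for user-built profiles
    cv_b <- if (!is.null(profile$energy_cv_between)) {
      profile$energy_cv_between
    } else {
      cv_t <- if (profile$energy_mean > 0)
        profile$energy_sd / profile$energy_mean else 0
      sqrt(max(cv_t^2 - SYNTH_CV_WITHIN^2, 0.0004))
    }
    s_b <- stats::rgamma(n_w, shape = 1 / cv_b^2, rate = 1 / cv_b^2)
    if (n_w >= 3L) {
      # standardize so the realized between-burst CV matches the target
      # exactly (a handful of bursts otherwise shrinks the sample SD)
      s_b <- 1 + (s_b - mean(s_b)) * cv_b / max(stats::sd(s_b), 1e-9)
    }
    s_b <- pmin(pmax(s_b, 0.35), 2.8)
    clip_cal <- if (!is.null(profile$clip_cal)) profile$clip_cal
                else SYNTH_CLIP_CAL
    limit <- max(profile$peak_to_peak / 2 * subject$amplitude_scale *
                   clip_cal, 1e-6)

    n_total <- as.integer(round(d * fs))
    x <- stats::rnorm(n_total, 0, subject$noise_floor)
    pos <- lead
    for (i in seq_len(n_w)) {
      n_s <- max(8L, as.integer(round(word_len[i] * fs)))
      f0_b <- min(400, max(80, f0_rec * contour[i] *
                             exp(stats::rnorm(1, 0, 0.02))))
      tilt <- sentence$syllable_spectra[[(i - 1L) %%
                                           sentence$syllable_count + 1L]]
      w_i <- profile$band_weights * tilt
      w_i <- w_i / sum(w_i)
      burst <- articulated_burst(n_s, f0_b, w_i, fs,
                                 artic = profile$articulation)
      mref <- mean(abs(burst))
      if (mref > 1e-12) {
        burst <- burst + stats::rnorm(n_s, 0, SYNTH_NOISE_REL * mref)
      }
      ramp_n <- min(as.integer(SYNTH_RAMP_S * fs), n_s %/% 3L)
      if (ramp_n > 0) {
        r <- 0.5 - 0.5 * cos(pi * seq_len(ramp_n) / ramp_n)
        env <- c(r, rep(1, n_s - 2L * ramp_n), rev(r))
        burst <- burst * env
      }
      amp_target <- profile$amp_norm * s_b[i] * subject$amplitude_scale
      burst <- scale_and_limit(burst, amp_target, limit)
      i0 <- as.integer(round(pos * fs))
      sel <- (i0 + 1L):min(i0 + n_s, n_total)
      x[sel] <- x[sel] + burst[seq_along(sel)]
      pos <- pos + word_len[i] +
        (if (i < n_w) gap_len[i] else 0) +
        (if (i %in% pause_after) pause_len[match(i, pause_after)] else 0)
    }
    x <- pmin(pmax(x, -SYNTH_MAX_NORM), SYNTH_MAX_NORM)

    # --- telemetry chain -------------------------------------------
    r0 <- telemetry$reference_resistance
    r_sensor <- r0 * (1 + x) / (1 - x)
    v <- resistance_to_voltage(r_sensor, telemetry)
    codes <- adc_quantize(v, telemetry)
    if (apply_adpcm) codes <- adpcm_roundtrip(codes, telemetry)

    rec <- structure(list(samples = codes,
                          sampling_rate = fs,
                          subject_id = subject$subject_id,
                          emotion = profile$emotion,
                          sentence_id = sentence$sentence_id,
                          repetition = as.integer(repetition),
                          seed = as.integer(seed),
                          duration = n_total / fs),
                     class = "throat_recording")
    # ground-truth timeline, used by generator-recovery tests
    attr(rec, "timeline") <- list(n_words = n_w, n_pauses = n_p,
                                  lead = lead, tail = tail,
                                  word_len = word_len, gap_len = gap_len,
                                  pause_len = pause_len,
                                  pause_after = pause_after, s_b = s_b)
    rec
  })
}

#' Generate a balanced labeled corpus
#'
#' Produces `n_subjects * 6 * 5 * reps_per_cell` recordings, one per
#' (subject, emotion, sentence, repetition) cell, with per-recording
#' seeds derived deterministically from `master_seed`. The default
#' configuration (4 subjects, 10 repetitions) reproduces the 1200-
#' recording corpus layout of the recording study.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param reps_per_cell Repetitions per cell (>= 1).
#' @param master_seed Integer master seed.
#' @param subjects Optional list of subject models (defaults to
#'   [default_subject_models()]).
#' @param telemetry A [telemetry_config()].
#' @param apply_adpcm Run the ADPCM round trip per recording.
#' @return A list with `recordings` (list of `throat_recording`) and
#'   `manifest` (data.frame: recording_id, subject_id, emotion,
#'   sentence_id, repetition, seed).
#' @export
generate_corpus <- function(n_subjects = 4L, reps_per_cell = 10L,
                            master_seed = 1L,
                            subjects = default_subject_models(n_subjects),
                            telemetry = telemetry_config(),
                            apply_adpcm = TRUE) {
  stopifnot(n_subjects >= 1, reps_per_cell >= 1,
            length(subjects) >= n_subjects)
  templates <- sentence_templates()
  profiles <- lapply(EMOTIONS, make_emotion_profile)
  recs <- vector("list", n_subjects * 6L * 5L * reps_per_cell)
  rows <- vector("list", length(recs))
  k <- 0L
  for (si in seq_len(n_subjects)) {
    subj <- subjects[[si]]
    for (ei in seq_along(EMOTIONS)) {
      for (ti in seq_along(templates)) {
        for (rep_i in seq_len(reps_per_cell)) {
          k <- k + 1L
          seed <- derive_seed(master_seed, subj$subject_id, ei - 1L,
                              ti - 1L, rep_i - 1L)
          recs[[k]] <- synthesize_recording(
            profiles[[ei]], templates[[ti]], subj, seed,
            repetition = rep_i - 1L, telemetry = telemetry,
            apply_adpcm = apply_adpcm)
          rows[[k]] <- data.frame(
            recording_id = sprintf("s%02d_%s_t%d_r%02d", subj$subject_id,
                                   tolower(EMOTIONS[ei]), ti - 1L,
                                   rep_i - 1L),
            subject_id = subj$subject_id,
            emotion = EMOTIONS[ei],
            sentence_id = ti - 1L,
            repetition = rep_i - 1L,
            seed = seed,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  list(recordings = recs, manifest = manifest)
}
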