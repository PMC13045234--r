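test_that("MFCC stack has the documented 40 x 128 layout", {
  rec <- tone_recording()
  fm <- extract_features(rec)
  expect_s3_class(fm, "feature_matrix")
  expect_identical(dim(fm$values), c(40L, 128L))
  expect_true(all(is.finite(fm$values)))
  expect_identical(unname(fm$row_layout),
                   c(13L, 13L, 13L, 1L))
})

test_that("delta rows vanish for identical frames; silence is floored", {
  cfg <- preprocess_config()
  # constant-content frames: replicate one frame's samples
  x <- rep(sin(2 * pi * 300 * seq_len(128) / 4000), 200)
  fs <- frame_and_window(x, c(0L, as.integer(128 * 128)), cfg)
  # force every frame identical
  fs$frames <- matrix(fs$frames[1, ], 128, 128, byrow = TRUE)
  fs$frames_raw <- matrix(fs$frames_raw[1, ], 128, 128, byrow = TRUE)
  fm <- mfcc_stack(fs)
  expect_equal(max(abs(fm$values[14:39, ])), 0)
  # all-zero frames: energy row at the floor, MFCC rows constant
  fs$frames <- matrix(0, 128, 128)
  fs$frames_raw <- matrix(0, 128, 128)
  fm0 <- mfcc_stack(fs)
  expect_equal(stats::sd(fm0$values[40, ]), 0)
  expect_equal(max(abs(fm0$values[14:39, ])), 0)
})

test_that("mel spectrogram localizes tones and respects band structure", {
  cfg <- preprocess_config()
  rec <- tone_recording(freq = 256)
  x <- adc_normalize(rec$samples)
  fs <- frame_and_window(x, c(0L, length(x)), cfg)
  ms <- mel_spectrogram(fs)
  expect_identical(dim(ms$values), c(40L, 128L))
  expect_true(all(ms$values >= 0))
  # argmax band contains 256 Hz
  band <- which.max(rowMeans(ms$values))
  lo <- ms$mel_band_edges[band]; hi <- ms$mel_band_edges[band + 2L]
  expect_true(lo <= 256 && 256 <= hi)
  # synthetic Sad recordings concentrate mel energy below 500 Hz
  prof <- make_emotion_profile("Sad")
  tpl <- sentence_templates(0)
  rec <- synthesize_recording(prof, tpl, default_subject(), seed = 9L)
  xs <- adc_normalize(rec$samples)
  fss <- frame_and_window(xs, detect_endpoints(xs), cfg)
  mss <- mel_spectrogram(fss)
  centre <- ms$mel_band_edges[2:41]
  low <- sum(mss$values[centre <= 500, ])
  expect_gt(low, sum(mss$values) / 2)
})

test_that("scale covariance: gain shifts log energy, leaves c2..c13", {
  cfg <- preprocess_config()
  set.seed(11)
  x <- 0.2 * sin(2 * pi * 200 * seq_len(6000) / 4000) + rnorm(6000, 0, 0.01)
  span <- c(0L, 6000L)
  f1 <- mfcc_stack(frame_and_window(x, span, cfg))
  f2 <- mfcc_stack(frame_and_window(2 * x, span, cfg))
  # row 40 shifts by 20*log10(2) dB everywhere
  expect_equal(f2$values[40, ] - f1$values[40, ],
               rep(20 * log10(2), 128), tolerance = 1e-6)
  # cepstral rows c2..c13 unchanged (gain lands in c0, excluded)
  expect_lt(max(abs(f2$values[2:13, ] - f1$values[2:13, ])), 1e-6)
})

test_that("prosodic descriptors: silence yields zeros, tone yields one burst", {
  set.seed(2)
  silence <- structure(list(
    samples = as.integer(round(2047.5 + rnorm(8000, 0, 4))),
    sampling_rate = 4000L, subject_id = 0L, emotion = "Neutral",
    sentence_id = 0L, repetition = 0L, seed = 1L, duration = 2),
    class = "throat_recording")
  d <- prosodic_descriptors(silence, with_delta_mfcc = FALSE)
  expect_identical(d$speech_rate, 0)
  expect_identical(d$pause_rate, 0)
  expect_identical(d$energy_mean, 0)
  rec <- tone_recording(duration = 2, amp = 0.3)
  d2 <- prosodic_descriptors(rec, with_delta_mfcc = FALSE)
  expect_identical(d2$n_bursts, 1L)
  expect_equal(d2$speech_rate, 30, tolerance = 0.2)  # 1 burst / 2 s
  expect_equal(d2$mean_norm_amplitude, 0.3 * 2 / pi, tolerance = 0.05)
  expect_lte(d2$peak_to_peak_norm, 2)
})

test_that("descriptor recovery on generated Angry/Sad samples", {
  # reduced-size version of the corpus-level recovery invariant
  # (the full 200-recording measurement runs in scripts/acceptance.R)
  tpl <- sentence_templates()
  subj <- default_subject()
  for (emo in c("Angry", "Sad")) {
    prof <- make_emotion_profile(emo)
    res <- vapply(1:40, function(s) {
      rec <- synthesize_recording(prof, tpl[[(s - 1) %% 5 + 1]], subj,
                                  seed = s)
      d <- prosodic_descriptors(rec, with_delta_mfcc = FALSE)
      c(d$speech_rate, d$pause_rate, d$mean_norm_amplitude,
        d$energy_mean, d$energy_sd, d$peak_to_peak_norm)
    }, numeric(6))
    m <- rowMeans(res)
    expect_lt(abs(m[1] - prof$speech_rate) / prof$speech_rate, 0.10)
    expect_lt(abs(m[2] - prof$pause_rate) / prof$pause_rate, 0.15)
    expect_lt(abs(m[3] - prof$amp_norm) / prof$amp_norm, 0.10)
    expect_lt(abs(m[4] - prof$energy_mean) / prof$energy_mean, 0.10)
    expect_lt(abs(m[5] - prof$energy_sd) / prof$energy_sd, 0.15)
    expect_lt(abs(m[6] - prof$peak_to_peak) / prof$peak_to_peak, 0.12)
  }
})

test_that("Angry delta-MFCC dynamics sit near the printed 1.8", {
  tpl <- sentence_templates()
  prof <- make_emotion_profile("Angry")
  v <- vapply(1:12, function(s) {
    rec <- synthesize_recording(prof, tpl[[(s - 1) %% 5 + 1]],
                                default_subject(), seed = s)
    prosodic_descriptors(rec)$delta_mfcc_mean
  }, numeric(1))
  expect_equal(mean(v), 1.8, tolerance = 0.15 * 1.8)
})
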