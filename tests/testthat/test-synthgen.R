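test_that("emotion profiles: printed anchors, invariants, rejection", {
  ang <- make_emotion_profile("Angry")
  expect_equal(ang$speech_rate, 180)
  expect_equal(ang$pause_rate, 2.8)
  expect_equal(ang$amp_norm, 0.25)
  expect_equal(ang$energy_mean, 0.25)
  expect_equal(ang$energy_sd, 0.12)
  sad <- make_emotion_profile("Sad")
  expect_equal(sad$speech_rate, 100)
  expect_equal(sad$pause_rate, 6.5)
  expect_equal(sad$amp_norm, 0.08)
  # Neutral anchored at twice Sad (energy halving read inversely)
  neu <- make_emotion_profile("Neutral")
  expect_equal(neu$amp_norm, 2 * sad$amp_norm)
  expect_equal(neu$energy_mean, 2 * sad$energy_mean)
  for (emo in c("Angry", "Fear", "Happy", "Neutral", "Sad", "Surprise")) {
    p <- make_emotion_profile(emo)
    expect_gt(p$speech_rate, 0)
    expect_gte(p$pause_rate, 0)
    expect_true(p$amp_norm > 0 && p$amp_norm <= 1)
    expect_equal(sum(p$band_weights), 1)
    expect_true(all(p$band_weights >= 0))
    expect_true(p$f0_range[1] >= 80 && p$f0_range[2] <= 400)
  }
  # six profiles are pairwise distinct
  key <- vapply(c("Angry", "Fear", "Happy", "Neutral", "Sad", "Surprise"),
                function(e) {
                  p <- make_emotion_profile(e)
                  paste(p$speech_rate, p$amp_norm, p$f0_range[1])
                }, character(1))
  expect_identical(anyDuplicated(key), 0L)
  expect_error(make_emotion_profile("Bored"), "unknown emotion")
})

test_that("sentence templates and subject models satisfy their contracts", {
  tpl <- sentence_templates()
  expect_length(tpl, 5L)
  expect_identical(vapply(tpl, `[[`, integer(1), "sentence_id"), 0:4)
  expect_true(all(vapply(tpl, `[[`, integer(1), "syllable_count") >= 2L))
  subs <- default_subject_models(4L)
  expect_true(all(vapply(subs, function(s)
    s$f0_scale > 0 && s$amplitude_scale > 0, logical(1))))
  vecs <- vapply(subs, function(s)
    paste(s$f0_scale, s$amplitude_scale, s$timing_jitter), character(1))
  expect_identical(anyDuplicated(vecs), 0L)
})

test_that("synthesize_recording: determinism, range, zero-amplitude", {
  prof <- make_emotion_profile("Happy")
  tpl <- sentence_templates(2)
  subj <- default_subject()
  r1 <- synthesize_recording(prof, tpl, subj, seed = 42L)
  r2 <- synthesize_recording(prof, tpl, subj, seed = 42L)
  expect_identical(r1$samples, r2$samples)
  r3 <- synthesize_recording(prof, tpl, subj, seed = 43L)
  expect_false(identical(r1$samples, r3$samples))
  expect_true(all(r1$samples >= 0 & r1$samples <= 4095))
  expect_identical(r1$sampling_rate, 4000L)
  expect_true(r1$duration >= 1 && r1$duration <= 10)
  # zero-amplitude profile: ADC midpoint + noise floor only
  p0 <- prof; p0$amp_norm <- 0
  r0 <- synthesize_recording(p0, tpl, subj, seed = 1L)
  x0 <- adc_normalize(r0$samples)
  expect_lt(max(abs(x0)), 0.05)
  expect_lt(stats::sd(x0), 3 * subj$noise_floor)
  # seed must be nonnegative
  expect_error(synthesize_recording(prof, tpl, subj, seed = -1L))
})

test_that("generator RNG stream does not disturb the caller's RNG", {
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(runif(0))
  invisible(synthesize_recording(make_emotion_profile("Fear"),
                                 sentence_templates(0), default_subject(),
                                 seed = 3L))
  expect_identical(runif(1), before)
})

test_that("corpus generation is balanced, deterministic, correctly sized", {
  corpus <- quick_corpus(n_subjects = 2L, reps = 1L, seed = 5L)
  expect_length(corpus$recordings, 2L * 6L * 5L)
  m <- corpus$manifest
  expect_identical(nrow(m), 60L)
  cells <- table(m$subject_id, m$emotion, m$sentence_id)
  expect_true(all(cells == 1L))
  expect_identical(anyDuplicated(m$recording_id), 0L)
  # reruns are byte-identical
  corpus2 <- quick_corpus(n_subjects = 2L, reps = 1L, seed = 5L)
  expect_identical(lapply(corpus$recordings, `[[`, "samples"),
                   lapply(corpus2$recordings, `[[`, "samples"))
  # per-recording seeds differ and derive from the master seed
  expect_identical(anyDuplicated(m$seed), 0L)
  corpus3 <- quick_corpus(n_subjects = 2L, reps = 1L, seed = 6L)
  expect_false(identical(corpus3$manifest$seed, m$seed))
})

test_that("energy ordering Angry > Neutral > Sad holds on a small corpus", {
  tpl <- sentence_templates()
  subj <- default_subject()
  e <- vapply(c("Angry", "Neutral", "Sad"), function(emo) {
    prof <- make_emotion_profile(emo)
    mean(vapply(1:12, function(s) {
      rec <- synthesize_recording(prof, tpl[[(s - 1) %% 5 + 1]], subj,
                                  seed = s)
      prosodic_descriptors(rec, with_delta_mfcc = FALSE)$energy_mean
    }, numeric(1)))
  }, numeric(1))
  expect_gt(e[["Angry"]], e[["Neutral"]])
  expect_gt(e[["Neutral"]], e[["Sad"]])
})
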