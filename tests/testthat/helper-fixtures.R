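# Shared fixtures: reduced recognizer configurations and quick
# synthetic inputs. Everything is generated in code at test time.

tiny_recognizer_config <- function(...) {
  recognizer_config(
    n_feature_rows = 8L, n_frames = 8L, conv_channels1 = 2L,
    conv_channels2 = 3L, lstm_units = 4L, attn_dim = 8L, attn_heads = 2L,
    ff_dim = 8L, fc_units = 8L, dropout_lstm = 0, dropout_fc = 0, ...)
}

# a recording-sized pure tone at the ADC scale
tone_recording <- function(freq = 256, duration = 2, amp = 0.3,
                           fs = 4000L, seed = 1L) {
  set.seed(seed)
  t <- seq_len(duration * fs) / fs
  x <- amp * sin(2 * pi * freq * t) + rnorm(length(t), 0, 0.003)
  codes <- as.integer(round(pmin(pmax(x, -1), 1) * 2047.5 + 2047.5))
  structure(list(samples = codes, sampling_rate = fs,
                 subject_id = 0L, emotion = "Neutral", sentence_id = 0L,
                 repetition = 0L, seed = seed,
                 duration = duration),
            class = "throat_recording")
}

# silence + one burst + silence, with known boundaries (in samples)
planted_burst_trace <- function(pre_s = 1, burst_s = 1, post_s = 1,
                                amp = 0.3, freq = 250, fs = 4000L,
                                noise = 0.004, seed = 2L) {
  set.seed(seed)
  n_pre <- round(pre_s * fs); n_b <- round(burst_s * fs)
  n_post <- round(post_s * fs)
  t <- seq_len(n_b) / fs
  burst <- amp * sin(2 * pi * freq * t)
  x <- c(rnorm(n_pre, 0, noise), burst + rnorm(n_b, 0, noise),
         rnorm(n_post, 0, noise))
  list(x = x, start = n_pre, end = n_pre + n_b)
}

quick_corpus <- function(n_subjects = 2L, reps = 1L, seed = 5L) {
  generate_corpus(n_subjects, reps, master_seed = seed)
}
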