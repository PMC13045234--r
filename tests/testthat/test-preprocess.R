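test_that("pre-emphasis matches its definition and is linear", {
  # impulse response [1, -alpha, 0, ...]
  expect_equal(pre_emphasis(c(1, 0, 0, 0), 0.98), c(1, -0.98, 0, 0))
  # DC attenuation by (1 - alpha)
  expect_equal(pre_emphasis(rep(2, 5), 0.98), c(2, rep(0.04, 4)))
  # linearity on random traces
  set.seed(1)
  x <- rnorm(100); z <- rnorm(100)
  expect_equal(pre_emphasis(3 * x - 2 * z),
               3 * pre_emphasis(x) - 2 * pre_emphasis(z))
  # boosts high frequencies: spectral centroid strictly increases
  centroid <- function(v) {
    p <- Mod(fft(v))[2:50]^2
    sum((2:50) * p) / sum(p)
  }
  expect_gt(centroid(pre_emphasis(x)), centroid(x))
})

test_that("endpoint detection finds planted bursts, silence, all-voiced", {
  cfg <- preprocess_config()
  # pure noise floor -> empty span
  set.seed(4)
  expect_identical(detect_endpoints(rnorm(8000, 0, 0.004), cfg), c(0L, 0L))
  # planted burst: boundaries within +/- 50 ms (200 samples)
  pl <- planted_burst_trace()
  span <- detect_endpoints(pl$x, cfg)
  expect_lt(abs(span[1] - pl$start), 200)
  expect_lt(abs(span[2] - pl$end), 200)
  # all-voiced trace -> essentially the full span
  t <- seq_len(4000) / 4000
  full <- 0.3 * sin(2 * pi * 220 * t)
  span <- detect_endpoints(full, cfg)
  expect_lte(span[1], 100)
  expect_gte(span[2], 3900)
})

test_that("endpoint detection is translation-equivariant", {
  cfg <- preprocess_config()
  pl <- planted_burst_trace(pre_s = 0.8, burst_s = 0.6, post_s = 1.6)
  base <- detect_endpoints(pl$x, cfg)
  hop <- 40  # detector hop in samples
  for (k in c(400, 1200)) {
    shifted <- c(pl$x[(k + 1):length(pl$x)], pl$x[seq_len(k)])
    sp <- detect_endpoints(shifted, cfg)
    expect_lt(abs((base[1] - k) - sp[1]), 2 * hop + 1)
  }
})

test_that("framing yields exactly 128 Hamming-windowed frames", {
  cfg <- preprocess_config()
  x <- rnorm(6000)
  fs <- frame_and_window(x, c(500L, 5500L), cfg)
  expect_identical(dim(fs$frames), c(128L, 128L))
  expect_identical(fs$hop, (5000L - 128L) %/% 127L)
  # all-ones trace: each frame equals the Hamming window
  ones <- rep(1, 4000)
  fs1 <- frame_and_window(ones, c(0L, 4000L), cfg)
  w <- hamming_window(128L)
  expect_equal(fs1$frames[1, ], w)
  expect_equal(fs1$frames[77, ], w)
  expect_equal(w[1], 0.08)
  # minimal overlap arithmetic: span of frame_length + 127 -> hop 1
  fs2 <- frame_and_window(rnorm(300), c(0L, 255L), cfg)
  expect_identical(fs2$hop, 1L)
  # frame count invariant across durations
  for (len in c(400L, 1777L, 12000L)) {
    fsv <- frame_and_window(rnorm(len), c(0L, len), cfg)
    expect_identical(nrow(fsv$frames), 128L)
  }
  expect_error(frame_and_window(rnorm(500), c(0L, 100L), cfg), "at least")
})
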