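# Independent plain-R IMA ADPCM codec used as the oracle for the
# compiled implementation. Written directly from the published IMA
# step-size and index-adjustment tables; intentionally kept separate
# from the package code path.

ima_step_table <- c(
  7, 8, 9, 10, 11, 12, 13, 14, 16, 17, 19, 21, 23, 25, 28, 31, 34, 37,
  41, 45, 50, 55, 60, 66, 73, 80, 88, 97, 107, 118, 130, 143, 157, 173,
  190, 209, 230, 253, 279, 307, 337, 371, 408, 449, 494, 544, 598, 658,
  724, 796, 876, 963, 1060, 1166, 1282, 1411, 1552, 1707, 1878, 2066,
  2272, 2499, 2749, 3024, 3327, 3660, 4026, 4428, 4871, 5358, 5894,
  6484, 7132, 7845, 8630, 9493, 10442, 11487, 12635, 13899, 15289,
  16818, 18500, 20350, 22385, 24623, 27086, 29794, 32767)
ima_index_table <- c(-1, -1, -1, -1, 2, 4, 6, 8)

# encoder rule: the 4-bit code whose standard IMA reconstruction is
# closest to the sample (ties broken toward the smaller code)
oracle_adpcm_encode <- function(pcm16, init_pred, init_index = 0L) {
  pred <- init_pred; index <- init_index
  codes <- integer(length(pcm16))
  magnitudes <- 0:7
  for (i in seq_along(pcm16)) {
    step <- ima_step_table[index + 1L]
    delta <- step %/% 8L +
      ifelse(bitwAnd(magnitudes, 4L) > 0, step, 0L) +
      ifelse(bitwAnd(magnitudes, 2L) > 0, step %/% 2L, 0L) +
      ifelse(bitwAnd(magnitudes, 1L) > 0, step %/% 4L, 0L)
    cand <- c(pred + delta, pred - delta)        # codes 0..7, 8..15
    cand <- pmax(-32768L, pmin(32767L, cand))
    code <- which.min(abs(pcm16[i] - cand)) - 1L
    pred <- cand[code + 1L]
    index <- max(0L, min(88L, index + ima_index_table[(code %% 8L) + 1L]))
    codes[i] <- code
  }
  codes
}

oracle_adpcm_decode <- function(codes, init_pred, init_index = 0L) {
  pred <- init_pred; index <- init_index
  out <- integer(length(codes))
  for (i in seq_along(codes)) {
    code <- codes[i]
    step <- ima_step_table[index + 1L]
    delta <- step %/% 8L
    if (bitwAnd(code, 4L) > 0) delta <- delta + step
    if (bitwAnd(code, 2L) > 0) delta <- delta + step %/% 2L
    if (bitwAnd(code, 1L) > 0) delta <- delta + step %/% 4L
    pred <- pred + if (bitwAnd(code, 8L) > 0) -delta else delta
    pred <- max(-32768L, min(32767L, pred))
    index <- max(0L, min(88L, index + ima_index_table[(code %% 8L) + 1L]))
    out[i] <- pred
  }
  out
}
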