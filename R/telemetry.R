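# Telemetry chain: voltage-divider readout, 12-bit ADC, ADPCM codec.

#' Telemetry configuration
#'
#' Describes the on-patch data path: a resistive sensor read through a
#' voltage divider powered at 3.3 V, digitised at 4 ksps with 12-bit
#' resolution, and compressed with 4-bit IMA ADPCM before wireless
#' transfer.
#'
#' @param supply_voltage Supply of the divider, volts.
#' @param reference_resistance Fixed divider resistor, ohms.
#' @param adc_bits ADC resolution in bits.
#' @param sampling_rate Samples per second.
#' @param adpcm_bits_per_sample Codec word size (4 for IMA ADPCM).
#' @return An object of class `telemetry_config`.
#' @export
telemetry_config <- function(supply_voltage = 3.3,
                             reference_resistance = 1e4,
                             adc_bits = 12L,
                             sampling_rate = 4000L,
                             adpcm_bits_per_sample = 4L) {
  stopifnot(supply_voltage > 0, reference_resistance > 0,
            adc_bits >= 1, sampling_rate > 0)
  if (adpcm_bits_per_sample != 4L)
    stop("only 4-bit IMA ADPCM is implemented")
  structure(list(supply_voltage = supply_voltage,
                 reference_resistance = reference_resistance,
                 adc_bits = as.integer(adc_bits),
                 sampling_rate = as.integer(sampling_rate),
                 adpcm_bits_per_sample = 4L),
            class = "telemetry_config")
}

#' Voltage-divider readout
#'
#' Maps sensor resistance to the divider output voltage
#' `V = Vs * R / (R + Rref)`; strictly increasing in `r_sensor`.
#'
#' @param r_sensor Sensor resistance(s), ohms; must be nonnegative.
#' @param config A [telemetry_config()].
#' @return Voltage(s) in volts, same length as `r_sensor`.
#' @export
resistance_to_voltage <- function(r_sensor, config = telemetry_config()) {
  if (any(!is.finite(r_sensor)) || any(r_sensor < 0))
    stop("r_sensor must be finite and nonnegative; got ",
         paste(utils::head(r_sensor[!is.finite(r_sensor) | r_sensor < 0], 3),
               collapse = ", "))
  config$supply_voltage * r_sensor / (r_sensor + config$reference_resistance)
}

#' 12-bit ADC quantization
#'
#' Clips the voltage trace to `[0, supply]` and rounds to the nearest of
#' `2^bits` levels: `round(clip(v) / supply * (2^bits - 1))`.
#'
#' @param v Voltage trace.
#' @param config A [telemetry_config()].
#' @return Integer codes in `[0, 2^bits - 1]`.
#' @export
adc_quantize <- function(v, config = telemetry_config()) {
  if (any(!is.finite(v))) stop("voltage trace must be finite")
  full <- 2^config$adc_bits - 1
  vc <- pmin(pmax(v, 0), config$supply_voltage)
  as.integer(floor(vc / config$supply_voltage * full + 0.5))
}

#' Map ADC codes to normalized amplitude
#'
#' Centres 12-bit codes on the ADC midpoint and scales to `[-1, 1]`.
#'
#' @param codes Integer ADC codes.
#' @param adc_bits ADC resolution.
#' @return Numeric trace in `[-1, 1]`.
#' @export
adc_normalize <- function(codes, adc_bits = 12L) {
  half <- (2^adc_bits - 1) / 2
  (codes - half) / half
}

#' ADPCM compression
#'
#' Encodes a 12-bit trace with 4-bit IMA ADPCM. Codes are carried with
#' the initial predictor state so decoding is self-contained.
#'
#' @param samples Integer ADC codes in `[0, 4095]`.
#' @param config A [telemetry_config()].
#' @return An object of class `compressed_stream` with fields `codes`
#'   (4-bit integers), `initial_predictor`, `initial_index`, `n_samples`.
#' @export
adpcm_encode <- function(samples, config = telemetry_config()) {
  samples <- as.integer(samples)
  full <- 2^config$adc_bits - 1
  if (length(samples) && (min(samples) < 0 || max(samples) > full))
    stop("samples must lie in [0, ", full, "]")
  if (!length(samples)) {
    return(structure(list(codes = integer(0), initial_predictor = 0L,
                          initial_index = 0L, n_samples = 0L),
                     class = "compressed_stream"))
  }
  half <- as.integer(2^(config$adc_bits - 1))
  pcm16 <- (samples - half) * as.integer(2^(16 - config$adc_bits))
  enc <- .adpcm_encode_cpp(pcm16, pcm16[1], 0L)
  structure(list(codes = enc$codes,
                 initial_predictor = pcm16[1],
                 initial_index = 0L,
                 n_samples = length(samples)),
            class = "compressed_stream")
}

#' ADPCM decompression
#'
#' @param stream A `compressed_stream` from [adpcm_encode()].
#' @param config A [telemetry_config()].
#' @return Integer ADC codes of length `stream$n_samples`.
#' @export
adpcm_decode <- function(stream, config = telemetry_config()) {
  stopifnot(inherits(stream, "compressed_stream"))
  if (stream$n_samples == 0L) return(integer(0))
  pcm16 <- .adpcm_decode_cpp(stream$codes, stream$initial_predictor,
                             stream$initial_index)
  half <- as.integer(2^(config$adc_bits - 1))
  codes <- as.integer(round(pcm16 / 2^(16 - config$adc_bits))) + half
  pmin(pmax(codes, 0L), as.integer(2^config$adc_bits - 1))
}

#' ADPCM encode/decode round trip
#'
#' @param samples Integer ADC codes.
#' @param config A [telemetry_config()].
#' @return Reconstructed integer codes, same length as the input.
#' @export
adpcm_roundtrip <- function(samples, config = telemetry_config()) {
  adpcm_decode(adpcm_encode(samples, config), config)
}

#' Serialize a compressed stream to a raw blob
#'
#' Layout: 4-byte little-endian n_samples, 2-byte initial predictor,
#' 2-byte initial step index, then packed 4-bit codes (low nibble first).
#'
#' @param stream A `compressed_stream`.
#' @return A raw vector.
#' @export
compressed_stream_serialize <- function(stream) {
  stopifnot(inherits(stream, "compressed_stream"))
  header <- c(writeBin(as.integer(stream$n_samples), raw(), size = 4,
                       endian = "little"),
              writeBin(as.integer(stream$initial_predictor), raw(), size = 2,
                       endian = "little"),
              writeBin(as.integer(stream$initial_index), raw(), size = 2,
                       endian = "little"))
  codes <- stream$codes
  if (length(codes) %% 2L == 1L) codes <- c(codes, 0L)
  lo <- codes[seq(1L, length(codes), by = 2L)]
  hi <- codes[seq(2L, length(codes), by = 2L)]
  c(header, as.raw(bitwOr(lo, bitwShiftL(hi, 4L))))
}

#' Deserialize a compressed stream
#'
#' @param blob A raw vector from [compressed_stream_serialize()].
#' @return A `compressed_stream`.
#' @export
compressed_stream_deserialize <- function(blob) {
  stopifnot(is.raw(blob), length(blob) >= 8)
  n <- readBin(blob[1:4], "integer", size = 4, endian = "little")
  pred <- readBin(blob[5:6], "integer", size = 2, signed = TRUE,
                  endian = "little")
  idx <- readBin(blob[7:8], "integer", size = 2, endian = "little")
  packed <- as.integer(blob[-(1:8)])
  codes <- as.integer(rbind(bitwAnd(packed, 15L), bitwShiftR(packed, 4L)))
  codes <- codes[seq_len(n)]
  structure(list(codes = codes, initial_predictor = pred,
                 initial_index = idx, n_samples = n),
            class = "compressed_stream")
}
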