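---
title: "Methods: synthetic throat-signal corpora and dual-head recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic throat-signal corpora and dual-head recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`throatspeech` re-implements, as a tested and reproducible pipeline, the
computational stack of a wearable artificial-throat patch: a laryngeal
strain sensor read through a voltage divider, digitised at 4 ksps with
12-bit resolution, compressed with ADPCM, and analysed by a speech
front end (pre-emphasis, endpoint detection, framing, MFCC features)
feeding a hybrid convolutional–recurrent–attention classifier that
jointly predicts one of six emotions and one of five fixed sentences.
The original recording corpus (4 subjects x 6 emotions x 5 sentences x
10 repetitions) is proprietary; this package therefore ships a
calibrated synthetic-corpus generator whose measurable prosodic
statistics match the published per-emotion descriptors, so that every
downstream stage can be exercised and property-tested end to end.

A green test suite here establishes that the pipeline is internally
correct and that the classifier can separate the *stated* acoustic
world; it does not establish performance on real laryngeal recordings,
which contain speaker physiology, sensor artifacts and phonetic detail
that the generator does not model.

## The synthetic acoustic world

Each recording is a 2–4 s trace built from a prosodic timeline:

* **Word-bursts.** The number of voiced bursts is
  `speech_rate * duration / 60` (stochastically rounded). A "word" is
  operationally one contiguous voiced burst; burst durations follow the
  sentence's relative syllable-duration pattern, jittered per subject.
* **Gaps and pauses.** Inter-word gaps are 100–150 ms — below the
  200 ms threshold that defines a pause. Pauses (280–450 ms of extra
  silence) are planted at the profile's pause rate. Because pauses are
  rare events (< 1 per recording), an independent Poisson draw would
  leave ~18% sampling noise in a 200-recording mean; pause occurrence
  is instead drawn from a golden-ratio low-discrepancy sequence keyed
  to the recording seed, which preserves the planted mean rate and
  per-seed determinism while making the corpus-level estimate tight.
* **Glottal source.** Each burst is a rectified-sine pulse train at a
  fundamental drawn from the emotion's f0 range (scaled per subject),
  spectrally reshaped so that energy in the 100–500 / 500–1500 /
  1500–2000 Hz bands matches the emotion's band weights. The band
  structure is capped at 2000 Hz: the stated 4 ksps sampling rate makes
  this the Nyquist limit, even though some published figure axes extend
  further — the sampling rate is taken as authoritative.
* **Articulation.** Bursts are split into ~80 ms sub-phones, each with
  its own perturbation of band weights, fundamental and gain,
  crossfaded. This is what gives the signal realistic frame-to-frame
  MFCC dynamics; the perturbation scale is itself emotion-dependent
  (pronounced for Angry, smooth for Sad, matching the published
  qualitative description).
* **Sentence identity.** Each sentence carries (a) a relative
  syllable-duration pattern, (b) an intonation contour on the
  fundamental, and (c) a fixed per-syllable table of band-weight tilts
  — the synthetic stand-in for its phoneme sequence. The tilts average
  out across a sentence, so they leave the emotion's band signature
  intact while giving the sentence classifier a learnable spectral
  rhythm.
* **Amplitude control.** Each burst is scaled so its mean absolute
  normalized amplitude equals `amp_norm` times a per-burst loudness
  factor; the realized between-burst spread is standardized to the
  profile's calibrated CV, and a per-emotion soft limiter (tanh) bounds
  peaks so that the recording-level peak-to-peak amplitude matches the
  profile. Voiced "frame energy" is defined as mean absolute amplitude
  per 20 ms frame — a reading consistent with the published Angry
  values, where mean amplitude (0.25) and energy mean (0.25) coincide.

Angry and Sad profiles carry the published values (180/100 words/min,
2.8/6.5 pauses/min, amplitudes 0.25/0.08, Angry energy SD 0.12,
peak-to-peak 1.55). Neutral is anchored by the published relation that
Sad's overall energy is half of neutral speech (amplitude 0.16).
Fear, Happy and Surprise are not numerically published; they sit on a
documented grid between the Sad and Angry extremes (rate, amplitude,
f0, band tilt) chosen to keep all six profiles mutually separable.

### Calibration constants

The generator contains a small set of fixed constants (per-emotion
between-burst CV, per-emotion limiter headroom, articulation sigmas)
that were derived once by measuring generated corpora against the
planted values and then frozen. They compensate for systematic
measurement effects — endpoint-detection edge dilution, limiter
compression, small-sample SD shrinkage — and are not tuned per test
run. With them, all planted descriptors are recovered within a few
percent (well inside the +/-10% recovery contract) on 200-recording
samples.

## Telemetry

The sensor chain is emulated as: normalized amplitude -> sensor
resistance (inverse-divider mapping, so the divider output is linear in
the normalized signal) -> `V = Vs R/(R+Rref)` at 3.3 V -> 12-bit ADC
with round-to-nearest and clipping -> IMA ADPCM (4-bit, standard
step-size table) encode/decode. The codec variant is an assumption: the
firmware's ADPCM flavour is not published, and IMA is the canonical
embedded choice with public reference behaviour, which lets the test
suite carry an independent plain-R oracle implementation and require
bit-exact agreement. The encoder picks, at each step, the 4-bit code
whose standard IMA reconstruction is closest to the input; the decoder
is bit-standard, so any IMA decoder reads the stream. Reconstruction
SNR exceeds 30 dB for tones well inside the tracking range (tens of
samples per cycle); at 200 Hz the 4 ksps rate leaves only 20 samples
per cycle and the 4-bit format caps SNR near 28 dB — a
dynamic-programming search over step-index trajectories confirms this
is the format's ceiling, not an encoder artifact.

## Speech front end

* Pre-emphasis `y[n] = x[n] - 0.98 x[n-1]` is applied before endpoint
  detection (the published order is unstated; this choice is fixed and
  documented).
* Endpoint detection is the classical double-threshold short-time
  energy + zero-crossing detector (20 ms windows, 10 ms hop), with the
  silence floor estimated from the leading 100 ms guarded by the lower
  decile of the whole profile. Thresholds are capped relative to the
  loudest frame (so an all-voiced trace is still detected) and floored
  absolutely (so a pure noise trace never is). Segment boundaries are
  reported at the centre of the transition frame, which keeps span
  edges unbiased rather than smeared by one window.
* Framing always produces exactly 128 overlapping frames of 32 ms
  (128 samples), with the hop adapted to the voiced-span length:
  `hop = max(1, floor((L - 128)/127))`. This makes the 40 x 128 feature
  shape unconditional. Frames are Hamming-windowed.

## Features

Per frame: 256-point power spectrum, 40 triangular mel filters over
0–2000 Hz, log in dB, orthonormal DCT-II, keeping c1..c13 (the
energy-like c0 is excluded because log frame energy is appended
separately — this makes 13 + 13 + 13 + 1 = 40 rows). Deltas and
delta-deltas use the standard +/-2-frame regression with replicated
edges. Row 40 is the log (dB) energy of the raw (unwindowed) frame.

The dB log convention matters: it is the default of the field's
standard MFCC implementations, and it is what places the mean absolute
delta-MFCC statistic of generated Angry speech at ~1.8, matching the
published value; under a natural-log convention the statistic cannot
exceed ~0.5 for any plausible generator setting.

## Recognizer

The architecture follows the published description: two 3x3
convolution stages (32, 64 channels, ReLU), a 2-layer bidirectional
LSTM (128 units/direction, dropout 0.3), a transformer encoder block
(8 heads, width 128), global average pooling, a 128-unit
fully-connected layer (dropout 0.5), and two softmax heads (6 emotions,
5 sentences) trained with the sum of the two cross-entropies under
Adam (lr 0.001), batch 64, early stopping with patience 10. Choices the
publication leaves open, fixed here: batch normalization after each
convolution; 2x2 max pooling after each stage (keeping 32 time steps
for the recurrent stage); a fully shared trunk with equal loss weights;
one pre-LN encoder block with feed-forward width 256; class order
alphabetical for emotions and by id for sentences. Training details
chosen for stable convergence at the stated optimizer settings:
global gradient-norm clipping at 5, He initialization for ReLU layers,
block-orthogonal LSTM recurrent initialization, forget-gate bias 1.
(Raising the learning rate above the stated 0.001 collapses the trunk
into dead ReLUs, with or without clipping, so the stated value is also
the practical one.)

No deep-learning framework exists in the supported R stack, so the
network — forward, backward and Adam — is implemented directly on
Armadillo (single precision) and verified against central finite
differences on a reduced configuration. Feature rows are z-scored with
training-set statistics stored in the model. Training is deterministic
given the seed (shuffling, initialization and dropout all derive from
it).

## Evaluation

`make_split()` reproduces the published protocol: the held-out
subject's recordings form the test set (300 of 1200 at the default
corpus size) and the rest are split 80/20 into training and validation.
`run_loso()` runs one fold per subject and aggregates accuracies as
unweighted mean +/- SD. Confusion matrices use fixed class orders; the
row sums always equal the per-class truth counts, and per-class
precision is NA (not zero) for classes absent from a test set.

## Numerical and degenerate-input choices

* Mel energies are floored at 1e-10 before the log; an all-zero frame
  yields the floor value, not -Inf.
* A voiced span shorter than one frame falls back to framing the whole
  trace (the feature shape contract holds for any input above the
  minimum duration).
* ADC quantization clips to [0, 3.3] V by contract; quantization error
  is bounded by half an LSB in range.
* The burst scaler guards against zero-amplitude profiles (amp 0 means
  midpoint + noise floor only).
* Recording durations are clipped to [2, 4] s; sentence base durations
  scale with syllable count.

## Known limitations

* The generator emulates prosody and coarse spectral structure, not
  intelligible speech: no phone inventory, no formant dynamics, no
  coarticulation, no sensor drift or motion artifacts. Cross-subject
  generalization in this world is therefore easier than on real
  recordings for emotion (strong planted signatures) and harder for
  sentences (identity is carried only by rhythm, contour and the
  per-syllable spectral tilts).
* Published headline accuracies (90.20% emotion / 84.71% text) were
  obtained on the proprietary corpus and are not reproducible here;
  the acceptance surface instead checks property-based thresholds on
  the synthetic corpus and exact desk-scale invariants.
* The ADPCM variant and the endpoint-detection details are stated
  assumptions, not published facts.
* Training the full architecture is CPU-heavy; the test suite runs the
  learning checks on a reduced corpus and capped epochs to stay inside
  its time budget, and documents this in the acceptance test.
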