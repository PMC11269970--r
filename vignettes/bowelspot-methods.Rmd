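---
title: "Spotting sparse bowel-sound events: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spotting sparse bowel-sound events: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bowelspot)
```

## The problem

Bowel sounds (BS) are short acoustic events produced by gastrointestinal
motility. In continuous recordings from wearable abdominal microphones they
are rare (about 0.9% of the audio), short (18 ms to several seconds, median
around 223 ms), and often barely louder than the background. Detecting them
is a *spotting* problem: the detector must return event onsets and offsets
inside an unsegmented stream dominated by the NULL class (noise, speech,
motion artifacts), not classify pre-cut clips. The extreme class imbalance
is the central difficulty — a detector whose false-positive rate looks
negligible on balanced data drowns the true events at a 0.9% positive rate.

`bowelspot` implements a complete spotting pipeline for this setting:
preprocessing, a frame-labelling neural segmentation model, training,
mask-to-event decoding, and an evaluation suite designed for sparse events,
plus a synthetic-corpus generator so the whole chain is testable without
access to clinical recordings.

## Pipeline and model

Audio is mono 16 kHz. Each channel is processed independently:

1. **High-pass biquad, 60 Hz cutoff** removes offset and rumble. We use the
   RBJ cookbook design with Q = 1/sqrt(2) (the reference gives only
   "biquadratic, 60 Hz") and apply it causally, which matches how a wearable
   device could filter online. A zero-phase variant would halve the (tiny)
   group delay but is not what an online system sees.
2. **Non-overlapping 10-second segments** (160,000 samples). The final
   partial segment is zero-padded to 10 s for inference and predictions are
   truncated back to real samples.
3. **Log-Mel spectrogram**: 25 ms Hann window, 10 ms stride, 128 Mel bands,
   giving 128 x 998 per segment; standardized to zero mean / unit variance
   per spectrogram; zero-padded along time to 128 x 1056 (the input
   geometry of 10-s-clip audio tagging encoders). Conventions the reference
   leaves open are fixed here: FFT size 512, HTK Mel scale spanning
   0–8000 Hz, log(power + 1e-6), and the order *standardize, then pad* so
   the pad value equals the post-standardization mean. These choices change
   spectrogram values, never shapes.
4. **Frame labels**: a 25 ms frame is positive when its overlap with
   annotated events reaches half the *frame* length (200 samples). With the
   18 ms minimum event duration this guarantees every conforming event at
   least one positive frame, since the best-aligned frame overlaps it by at
   least 15 ms. Tentative annotations (events raters could not confirm) are
   the NULL class. Events straddling a segment boundary contribute their
   clipped part to both masks.

The model, `build_effunet()`, is a U-shaped segmentation network: an
EfficientNet encoder of inverted-bottleneck (MBConv) blocks — expansion
1x1 convolution, depthwise 3x3/5x5, squeeze-excitation, projection 1x1,
batch norm and SiLU throughout, residual connections between equal-shape
blocks — and a U-Net decoder whose blocks are a 2x2 transposed convolution
followed by two 3x3 convolutions (batch norm + ReLU), concatenating skip
features from each encoder resolution. A final 1x1 convolution maps to two
channels (BS, NBS); average pooling over the frequency axis then a softmax
yields one class distribution per 25 ms frame, so the temporal resolution
of the spotter equals the frame length. Where the reference wording is
ambiguous we pool *after* the 2-class projection; the alternative order
(pool, then project) differs only by where the frequency average meets a
linear map and was not observed to matter at tiny scale.

The B2 configuration uses the EfficientNet-B2 compound scaling (width 1.1,
depth 1.2; stages 16/24/48/88/120/208/352, head 1408) on a 1-channel
input, with decoder widths 512-256-128-64-32 — the classic halving
sequence — which lands the total at 18.27 M parameters. Decoder weights
are He-initialized; `load_pretrained_encoder()` imports encoder tensors
(e.g. from audio-tagging pretraining) by name and leaves the decoder
untouched, since tagging corpora carry no onset/offset supervision.

A `tiny` variant (3 encoder stages, head 32, decoder 16-8-4, ~18 k
parameters) exists purely so CPU test suites can exercise every code path
— MBConv, SE, batch norm, skips, decoder, decoding — at interactive speed.

Because no deep-learning framework is part of this package's dependency
set, the layer engine is implemented in the package itself: compiled
direct-convolution kernels (src/ops.cpp), BLAS matrix products for
pointwise convolutions, and hand-derived backward passes. The test suite
verifies every backward pass against central finite differences through
the full network; batch-norm statistics are per feature map during
training with running-average statistics for inference.

## Training objective and schedule

The loss is the unweighted sum `L = L_CE + L_dice`: mean per-frame
cross-entropy plus soft dice on the BS probability channel with smoothing
eps = 1. Cross-entropy drives per-frame accuracy; dice directly rewards
overlap with the sparse positive mask and is what keeps the minority class
from being ignored. Padded frames are excluded from both terms — their
labels are artifacts of padding. Defaults in `train_config()` follow the
published recipe: 25 epochs, imbalanced batches of 32 (uniform segment
sampling, no class rebalancing), Adam(beta1 = 0.95, beta2 = 0.999, weight
decay 5e-7), learning rate 1e-4 decayed by 0.85 per epoch from the sixth
epoch, final-epoch weights kept (no early stopping or model selection).

Augmentation (training only): frequency masking up to 24 Mel bins and a
single contiguous time mask up to 10% of the time bins (spectrogram only —
labels are not masked, following SpecAugment practice), a time shift
uniform in ±10 bins applied identically to spectrogram and mask (labels
must move with content), and additive white noise with magnitude drawn
below 0.1 on the standardized spectrogram. The 10% time-mask budget is
spent on one contiguous block; multiple smaller blocks would be a
reasonable alternative the reference does not distinguish.

Validation is leave-one-participant-out: `lopo_splits()` keeps every
channel of a participant on one side of the split, so no recording can
leak across folds.

## Decoding

`spot_recording()` runs the pipeline over all segments, takes the per-frame
argmax, strips padded frames, concatenates the per-segment masks in time
order and decodes maximal runs of positive frames into events spanning the
union of their 25 ms frame windows; a single positive frame yields a 25 ms
event, the resolution floor. Two consequences of the geometry are worth
stating. First, decoding on the concatenated mask means detections touching
a 10-s boundary merge into one event instead of splitting — per-segment
decoding is available (`merge_across_segments = FALSE`) for comparison.
Second, because the frame window (400 samples) exceeds two strides (320),
the spans of runs separated by a single negative frame overlap; the decoder
returns their union as one event, which keeps decoded events sorted and
non-overlapping by construction. No further smoothing or nearby-event
merging is applied.

## Evaluation for highly imbalanced streams

* `samplewise_prf()` compares predictions and annotations sample by sample
  (interval arithmetic, verified against rasterization), independent of the
  spotter's resolution. Undefined precision (no predictions) is reported as
  0 with a flag. Tentative events are excluded from the positives; by
  default their samples still count against precision (conservative), and
  `tentative = "ignore"` removes them from scoring entirely for
  sensitivity analyses.
* `segment_errors()` decomposes FP time into insertion / overfill / merge
  and FN time into deletion / underfill / fragmentation by cutting the
  timeline at every truth or prediction boundary and classifying each
  maximal error segment by whether detection flanks it on both sides, one
  side, or neither. The six durations conserve total FP and FN time
  exactly.
* `segment_snr()` measures 10·log10 of in-event over out-of-event mean
  squared amplitude within a 10-s segment; `pr_vs_snr()` pools counts over
  segments at or above each threshold (cumulative, matching the thresholded
  analysis; per-bin counts are recoverable from the table).
* `pr_vs_duration()` filters both truth and predictions to events of at
  least a duration threshold before scoring — the analysis that reveals
  fragmentation of long events as a recall drop.
* `bs_ratio_sweep()` resamples evaluation frames (K positives, J negatives,
  ratio K/(K+J)) from 1e-5 to 0.6 without retraining, quantifying how
  precision depends on class imbalance. For a predictor with fixed
  per-frame TPR and FPR, precision follows
  r·TPR / (r·TPR + (1−r)·FPR); the suite verifies the sweep against this
  closed form, which is the mechanism behind "precision rises with BS
  ratio" comparisons across differently balanced corpora.
* `ratio_to_event_rate()` converts a BS ratio to events/hour linearly via
  the mean event duration (ratio·3600/mean duration) — at the study's
  0.0089 ratio and this generator's 0.383 s mean duration, about 84
  events/hour, consistent with the 100–300 events/hour scale reported for
  such corpora once per-participant variation is considered.
* `median_iqr()` implements the reporting convention in which Q1 is the
  midpoint of minimum and median and Q3 the midpoint of median and maximum
  (so IQR = (max − min)/2), alongside standard sample quartiles.

Fold-level scores pool tp/fp/fn within a participant (micro-average), and
medians/IQRs are taken across folds.

## The synthetic corpus

No public corpus of annotated wearable bowel-sound audio exists, so
`corpus_spec()` / `generate_recording()` / `write_corpus()` emulate the
statistical structure of such recordings:

* **Sparsity**: confirmed-event coverage targets a BS ratio of 0.0089.
  The target counts confirmed (non-tentative) events, matching how
  annotated corpora report it; tentative events add on top.
* **Durations**: log-normal with median 223 ms, log-sd 1.04 (making the
  mean 0.383 s), truncated to [18 ms, 6.29 s]. The log-sd is chosen to
  reproduce the heavy short-duration mode with occasional multi-second
  events; only the median, bounds and qualitative shape are constrained by
  the reference.
* **Acoustics**: events are exponentially decayed band-limited noise
  bursts (80–200 Hz to 600–2000 Hz passband, 2 ms attack); events longer
  than 1 s are trains of 2–10 bursts with intra-event silences under
  100 ms, so they remain single events under the annotation guideline.
  The background is pink noise (Kellet filter) at fixed RMS.
* **SNR**: each event is scaled to a per-event SNR uniform over
  [−20, +8] dB relative to the background RMS. Events below −13 dB are
  flagged *tentative*, yielding roughly the one-quarter tentative fraction
  seen in rater annotations.
* **Guidelines**: inter-event gaps are at least 100 ms and durations at
  least 18 ms by construction, so generated annotations are
  guideline-consistent.

What the generator does **not** emulate: non-stationary interference
(speech, motion artifacts, breathing), channel coupling across sensors,
and physically realistic abdominal acoustics. Two consequences matter for
interpreting green tests. Measured segment SNR here includes the stationary
background beneath the event, so it reads 10·log10(1 + 10^(s/10)) for a
configured SNR s and cannot go below 0 dB — sub-zero measured SNRs in real
data come from loud non-stationary noise elsewhere in the segment, which
is absent here. And a model that passes the mechanism test on this corpus
has demonstrated that the pipeline can learn and localize sparse transient
events end to end — not that it reaches any particular performance on
clinical recordings.

## Problem sizes used by the test and acceptance runs

Construction of the full B2 model is tested (parameter count, within 3% of
18.1 M); training runs use the tiny variant. The mechanism ("smoke") run
trains the tiny model on 3 synthetic participants x 3 minutes of easy
audio (BS ratio 0.05, SNR 14–20 dB, durations log-normal with median
0.35 s and log-sd 0.6 so that multi-second burst trains — whose
intra-event silences are the hardest frames — are rare), one
leave-one-participant-out fold, 15 epochs, batch 2, learning rate 3e-3
decaying from epoch 9, augmentation off, and requires samplewise F1 of at
least 0.8 on the held-out participant. Under these conditions the run
passes across independent seeds, not only the one pinned in the test. These training hyperparameters are
the package's choice for the reduced model — the published recipe's 1e-4
rate is tuned to a pretrained 18 M-parameter encoder, not an 18 k-parameter
network trained from scratch, and at 1e-4 the tiny model merely
underfits. Oracle-equivalence suites run on hundreds to a thousand random
layouts at 3 s of stream each; generator statistics are checked on 30 min
of synthetic audio.

## Known limitations

* Per-map (instance-style) batch-norm statistics during training, since
  optimization proceeds sample by sample with gradient accumulation;
  inference uses running averages as usual.
* The full B2 model is practical for construction and weight import on
  CPU, but training it requires hardware this package does not target.
* Causal filtering, a fixed Mel convention and the pool-after-projection
  head are pinned choices among reasonable alternatives; all are
  documented above and isolated behind the module interfaces.
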