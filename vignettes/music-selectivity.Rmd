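---
title: "Emergence of music-selective units: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emergence of music-selective units: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(musedetect)
```

This vignette documents the scientific content of `musedetect`: the models
and statistics it implements, what the synthetic corpus does and does not
emulate, the numerical conventions, and the design decisions taken where
the design was genuinely open. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## 1. The question and the experimental logic

Music-selective neural populations exist in human auditory cortex even in
listeners without musical training, which raises the question of how such
selectivity can arise without explicit experience of music. The package
implements a modeling answer: train a generic convolutional sound-event
tagger on natural (non-music) sound detection, and ask whether units tuned
to music appear anyway in its feature layer. Four experiments carry the
logic:

1. **Emergence.** Train the tagger on a corpus from which every clip with
   a music-related label has been removed. Compute each feature unit's
   music-selectivity index (MSI) on one data split, select the top 12.5%,
   and measure their music/non-music response ratio and a linear
   music-classification probe on an independent split. A
   random-initialization network provides the baseline.
2. **Temporal structure (quilting).** Present sound quilts of music at
   segment lengths from 50 to 1600 ms. If MS units encode long-range
   temporal structure, their (normalized) response should fall as segments
   get shorter, while non-selective units stay flat.
3. **Memorization control.** Retrain the network on the same audio with
   randomly permuted label sets. The network can memorize (high training
   mAP) but cannot generalize (held-out mAP at chance); if selectivity and
   its temporal-structure signature fail to appear here, generalization —
   not mere exposure — is what produces them.
4. **Ablation.** Zero each unit group (MSI top / middle / bottom, and the
   strongest-responding L1 group) and measure the detection mAP over
   non-music categories. If MS units are a functional basis for natural
   sound detection, their ablation should hurt the most.

## 2. Model and training recipe

The tagger is a conventional audio CNN: a log-Mel frontend (64 mel bands,
0–8000 Hz, 25 ms Hann window, 12.5 ms hop, natural log of power with an
additive floor `eps = 1e-10`), four convolutional blocks (3×3 kernels,
batch normalization, ReLU, max pooling, dropout 0.2), global average
pooling into the feature layer, and two fully connected layers with
per-category sigmoid outputs. The loss is the mean binary cross-entropy
`-[y log x + (1-y) log(1-x)]` over categories; optimization is AdamW
(weight decay 0.01) under a one-cycle learning-rate schedule that rises
linearly from 4e-5 to 1e-3 over the warm-up epochs and falls linearly to
4e-9 at the final epoch, interpolated per optimization step. Weights from
the epoch with the best validation mAP (10% of the training clips held
out) are used for analysis; ties resolve to the later epoch because a
desk-scale validation split can saturate early. The memorization control
uses final-epoch weights, since validation mAP is meaningless when
held-out labels are noise, and its training mAP is measured on the clips
actually optimized over.

The backend is a purpose-built RcppArmadillo implementation (im2col
convolutions, exact batch-norm backward, AdamW, seeded mt19937
initialization/shuffling/dropout), verified against finite-difference
gradients in the test suite and bit-reproducible for a given seed on one
machine.

Frame counts follow the left-aligned no-padding convention
`T = floor((N - window)/hop) + 1` with `window = floor(0.025 sr)` and
`hop = floor(0.0125 sr)` samples — a 10 s clip at 22,050 Hz gives exactly
800 frames. The mel scale is the HTK variant; the choice is recorded in
`frontend_config()` and held fixed so all comparisons are
variant-consistent.

## 3. The synthetic corpus

The generator (`synth_config()`, `generate_dataset()`) emulates the
*structure* of a balanced multi-label natural-sound corpus, not its
perceptual richness. Ten categories are synthesized: two music-related
(`music`: harmonic additive synthesis on a beat grid with a random-walk
melody that repeats exactly at the 2 s phrase scale, plus a beat-locked
percussion layer; `singing`: the same generator with vibrato and formant
coloration), a speech-like category (syllable-rate amplitude-modulated
formant trains with irregular syllable durations), and seven environmental
ones (stationary water-like noise, wind, jittered bark and tick event
trains, machinery hum, frequency chirps, and bells — slowly decaying
inharmonic strikes at random times). Three corpus-level properties were
deliberate design choices:

* **Within-category diversity.** Every generator draws per-clip parameters
  from ranges (tempo, scale, register, timbre exponent, rates, formants,
  band edges), and every clip receives a random smooth channel-EQ curve
  (±4 dB, emulating recording-channel variation) and an ambient pink-noise
  bed 25 dB below signal RMS. Natural corpora are diverse in exactly these
  ways; without this diversity clips within a category are near-duplicates,
  which both trivializes category detection and makes label memorization
  impossible (a memorizing network needs per-clip signatures to latch
  onto).
* **Spectrally music-like non-music.** The `bells` category shares the
  harmonic, tonal character of music but has no beat grid or phrase
  structure. Without such a category, *any* harmonicity-sensitive unit
  separates music perfectly and the middle-MSI probe baseline sits at
  ceiling.
* **Co-occurring events.** A fraction of clips are multi-event: `mixed`
  clips overlay one music and one non-music event at equal RMS (these are
  excluded from all selectivity analyses, as their group is ambiguous),
  and `overlay` clips combine two non-music events (group `non-music`).
  Event co-occurrence is the norm in field recordings and keeps the
  detection task off ceiling, which the ablation analysis needs.

The long-range-structure contract of the generator is testable: the
envelope autocorrelation at the phrase lag is high for music (phrase
repetition), low for every non-music category (onsets are jittered or
random), and destroyed by 50 ms quilting. What the corpus does **not**
emulate: reverberation, source motion, label noise, the heavy-tailed
category distribution of real corpora, or any perceptual notion of
musicality. Consequently, passing the scaled-down experiments demonstrates
that the *pipeline logic* reproduces the phenomenon under controlled
conditions; it is not evidence about real-world audio.

The generator-level train/test split is 50/50, stratified by category and
disjoint by clip id. MSI identification uses the test split; response
ratios, probes and quilting sources use the training split, so the
identification data are independent of the evaluation data.

## 4. Linear baselines

Two linear feature extractors serve as controls. PCA takes the top
principal components of the vectorized log-Mel spectrograms (basis fitted
on training data only). The Gabor filter bank implements complex
spectro-temporal modulation filters `g(k,n) = s_{w_k}(k-k_0) s_{w_n}(n-n_0)
h(k-k_0) h(n-n_0)` with carriers `s_w(x) = exp(iwx)`. Two conventions
required a decision:

* **Envelope.** The raised-cosine envelope is taken as
  `0.5 + 0.5 cos(2πx/b)` on `(-b/2, b/2)` — peaked at the filter center
  and zero at the support edge — with extent `b = νπ/w` (the width that
  holds `ν` semi-cycles of the carrier). The sign-flipped variant
  `0.5 - 0.5 cos(·)` vanishes at the center and cannot act as a matched
  filter. Filters with nonzero modulation get their envelope-weighted mean
  removed (insensitive to constant spectrogram offsets) and unit L2
  normalization.
* **Grid truncation and redundancy.** Modulation frequencies descend from
  `w_max = π/4` with ratio `(1+c/2)/(1-c/2)`, `c = 8d/ν`, and are truncated
  where the envelope no longer fits the representation: spectral
  frequencies need `b ≤ 64` mel channels (`w ≥ νπ/64`), temporal
  frequencies `b ≤ 80` frames (1 s of context at the 12.5 ms hop). The
  spectral axis is mirrored to negative frequencies (upward vs downward
  sweeps); the temporal axis is non-negative. This reproduces 15 spectral
  and 18 temporal frequencies exactly, and the redundant filters are the
  seven negative-spectral filters at zero temporal modulation, which are
  complex conjugates of their positive twins — hence 15 × 18 − 7 = 263
  independent filters. Features are the time-frequency mean of
  ReLU(real part) of each "same"-mode zero-padded convolution.

## 5. Selectivity, quilting, probes, ablation: conventions

* MSI equals the Welch *t* statistic (asserted against an independent
  implementation to 1e-10). Zero-variance units with equal means get index
  0; with unequal means, a signed infinity plus a degeneracy flag.
* Group selection ranks units by index descending, ties broken by unit
  position, with round-down percentile arithmetic: the top 12.5% of 256
  units is ranks 1–32; the middle 43.75–56.25% band of 256 is ranks
  113–144. Group membership is invariant under strictly monotone
  transforms of the index.
* The response ratio is the group mean of per-unit
  (mean response to music)/(mean response to non-music); units with a zero
  denominator are excluded with a warning.
* Quilt plans are built greedily: starting from a seeded random segment,
  each step appends the unused segment whose junction change in log-Mel
  edge features best matches the original's change at that position, with
  the original successor excluded from the candidates while alternatives
  remain (this forces a genuine reordering; with two segments the swap is
  forced). The greedy step is validated against exhaustive search over all
  feasible permutations on small toys. Rendering phase-aligns each
  junction within ±5 ms and applies a 2 ms equal-power cross-fade — short
  windows, because junction processing exists to minimize boundary
  artifacts, not to blur segment content — then cuts the content to 8 s
  and zero-pads to 10 s so all quilts carry equal sound content.
  Whether the source algorithm forbids the identity permutation outright
  is not documented anywhere we could find; forbidding it for three or
  more segments is this package's recorded convention.
* Linear probes are least-squares scores on 0/1 targets (optional ridge,
  default 0; intercept included — the package's recorded convention),
  evaluated by average precision on a clip-disjoint split; no threshold is
  involved. t-SNE (exact, seeded, perplexity 10 by default) is for
  visualization; its tested surface is the silhouette of the binary
  grouping in the embedding, not the picture. Duplicate feature rows
  raise an error unless seeded jitter is requested.
* Ablation zeroes feature units and recomputes detection mAP with
  music-related categories excluded from the macro average; the baseline
  row is the unablated model, and per-category APs are retained for paired
  tests. The study runner evaluates on the held-out *non-music* clips:
  the question is what the units contribute to natural-sound detection,
  and in a ten-category corpus music clips would otherwise constitute a
  fifth of every category's negatives, so the measure would be dominated
  by false-positive relief on music (a composition artifact that a
  527-category corpus does not have) rather than by information loss.
* Average precision uses the non-interpolated step curve with tied scores
  processed as blocks (every positive in a tied block is credited the
  end-of-block precision), so a constant-score ranking scores exactly the
  positive prevalence — the chance level. Wilcoxon tests use the exact
  null distribution up to n = 10 per group without ties and the normal
  approximation with continuity correction otherwise, with the method
  recorded in the outcome; the reported U is the first-sample
  Mann-Whitney statistic (complete separation at n = 5 vs 5 gives U = 25).

## 6. Desk-scale study conditions

`study_config()` fixes the problem sizes used by the experiment runners,
the test suite and the acceptance script. They were chosen once, as the
smallest sizes that preserve the structure of the analyses:

* corpus: 10 categories × 24 label appearances (about 190 clips after
  mixed/overlay accounting), 5% mixed, 15% overlay clips;
* inputs: 64 × 800 log-Mel spectrograms average-pooled along time by 8
  (100 frames, 100 ms per pooled frame);
* network: channels 12-32-64-128 (feature layer 128 units, so the top
  12.5% MSI group has 16 units), pooling 2×2 in the first two blocks and
  2×1 (frequency only) in the last two — the time-preserving pools keep
  ~100 spatial cells under the global average, so dropout noise on the
  pooled features stays small and sub-second temporal structure survives
  to the feature layer;
* training: 40 epochs, batch size 8 (with ~100 training clips this keeps
  a meaningful number of optimization steps per epoch), one-cycle warm-up
  30% of epochs; the memorization control trains for a 200-epoch budget.

The default `arch_config()` (channels 64-128-256-256, 2×2 pools, 256-d
features) is the reference-scale architecture; the study configuration is
its scaled companion.

## 7. Known limitations

* Determinism is per-machine: training is bit-reproducible for a seed on
  one BLAS/compiler configuration, not necessarily across platforms.
* The ablation comparison is under-powered at desk scale: the mAP change
  from silencing 16 of 128 units in a dropout-trained (hence
  ablation-robust) read-out is of order 0.01 while its seed-to-seed spread
  is of order 0.02, so the ordering of the unit groups is not stable
  across corpus realizations even when aggregated over three seeds. There
  is also a structural tension: the corpus contract that categories be
  identifiable from *time-averaged* spectra makes temporal-structure
  features inessential to the detection task, whereas the full-scale
  ablation effect rests on exactly those features being the task's
  generalization backbone. The top-versus-bottom and top-versus-L1
  comparisons lean the expected way; top-versus-middle does not resolve.
* The memorization control's attainable training mAP depends on network
  width relative to corpus size; the study configuration reaches the
  0.95 regime, but substantially smaller networks will not, because
  dropout noise then dominates the per-clip feature differences a
  memorizer must exploit.
* The GBFB truncation rule (envelope must fit 64 channels / 80 frames) is
  a reconstruction that reproduces the published grid sizes exactly; the
  original truncation convention is not printed anywhere we could verify.
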