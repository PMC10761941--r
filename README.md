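# musedetect

Music-selective units can emerge in a neural network that is trained to
detect everyday sounds and never hears music. `musedetect` is an R package
that implements, end to end and at desk scale, the analysis pipeline behind
that finding: it builds a labeled synthetic soundscape corpus, trains a
convolutional multi-label sound-event tagger on it *without* the
music-related clips, and then interrogates the network's pooled feature
units with the tools of auditory neuroscience — selectivity indices, sound
quilts, linear probes, and unit ablation.

The package is aimed at computational-neuroscience and machine-listening
researchers who want a self-contained, seeded, testable replication of the
analysis logic without an external corpus or a GPU.

## The core quantities

* **Music-selectivity index (MSI).** For each unit of the feature layer
  (the global-average-pooling layer of the tagger), with mean response
  *m*, standard deviation *s* and clip count *n* per group,

      MSI = (m_music − m_non-music) / sqrt(s²_music/n_music + s²_non-music/n_non-music)

  i.e. a Welch-style *t* statistic contrasting music against non-music
  clips (mixed clips are excluded). Units in the top 12.5% of MSI form the
  putative music-selective (MS) group.

* **Sound quilting.** A source clip is cut into equal segments
  (50–1600 ms, octave spaced) and reordered so that the junction-to-junction
  change in the log-Mel spectrogram tracks the original's segment-to-segment
  change; junctions are phase aligned and cross-faded. Quilting preserves
  short-timescale structure and destroys long-timescale structure, so the
  dependence of MS-unit responses on segment length measures how much
  temporal structure those units encode.

* **Gabor filter bank (GBFB) baseline.** Complex spectro-temporal
  modulation filters `g(k,n) = exp(i w_k k) exp(i w_n n) h(k) h(n)` with
  raised-cosine envelopes, on a geometric frequency grid with ratio
  `(1 + c/2)/(1 − c/2)`, `c = 8d/ν`. At the reference parameters
  (`d_k = 0.1`, `d_n = 0.045`, `ν = 3.5`, `w_max = π/4`) the grid has 15
  spectral and 18 temporal modulation frequencies and 263 independent
  filters.

* **Evaluation statistics.** Average precision (non-interpolated, tied
  scores processed blockwise so constant scores give exactly the positive
  prevalence), macro mAP over categories, Wilcoxon rank-sum/signed-rank
  tests (exact for small samples) and the common-language effect size.

## Worked example

```r
library(musedetect)

# one seeded desk-scale study: synthesize the corpus, train the tagger
# without music, build the random-init baseline and the memorization
# control, run the quilt and ablation experiments (~8 min on one CPU)
st <- run_study(seed = 1)
print(st)
#> <study_result seed 1 >
#>   MS response ratio (trained without music): 3.806
#>   MS response ratio (random init):           1.680
#>   probe AP, MSI top vs middle units: 1.000 vs 0.633
#>   memorization: train mAP 0.959, held-out 0.184 (chance 0.132)
#>   ablation mAP:  none 0.915, msi_top 0.913, msi_mid 0.913, msi_bottom 0.908, l1_top 0.928
```

Reading the numbers: units with the top 12.5% MSI values in the network
trained **without music** respond ~3.8× more strongly to held-out music
than to non-music (a random-initialization network gives only ~1.7×); a
linear music/non-music probe on those 16 units is perfect while the same
probe on middle-MSI units is clearly worse; and a network trained on
label-randomized data memorizes its training set (mAP 0.96) while staying
at chance on held-out clips — generalization, not memorization, is what
produces the selectivity. (The final line is the unit-ablation comparison,
whose effects are small at this scale; see the methods vignette.)

Individual stages are exposed as ordinary functions:

```r
clip <- generate_music_clip(seed = 1)      # 10 s, 22.05 kHz synthetic music
spec <- to_log_mel(clip)                   # 64 x 800 log-Mel spectrogram
quilt <- quilt_clip(clip, segment_ms = 50) # 50 ms sound quilt
long_range_index(clip)                     # ~0.9  (phrase-scale structure)
long_range_index(quilt)                    # ~0    (destroyed by quilting)

bank <- build_filterbank(gabor_grid())     # 263 spectro-temporal filters
features <- gbfb_features(spec, bank)      # linear baseline feature vector
```

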