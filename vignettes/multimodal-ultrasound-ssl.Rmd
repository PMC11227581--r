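---
title: "Self-supervised audio-visual-text representation learning for ultrasound video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised audio-visual-text representation learning for ultrasound video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During a routine obstetric ultrasound examination the sonographer narrates
what the probe is showing — "this is the heart", "looking at the femur" —
while the machine renders a continuous grayscale video. The narration is a
free, naturally-occurring annotation stream: whenever an anatomy-related
utterance co-occurs with the video (within a fraction of a second), the pair
(video clip, speech segment) is a positive example of cross-modal
correspondence, and windows spliced together from different scans or distant
timestamps are negatives. `sonossl` implements a framework that exploits
this structure to learn visual and audio representations without manual
labels, adds the transcribed text as a third modality with a learned
per-token gate, and transfers the pretrained encoders to three downstream
tasks: standard plane detection (SPD), eye-gaze saliency prediction, and
audio-guided anatomy localisation.

Real scan collections of this kind are not publicly available, so the
package ships a synthetic scan generator that reproduces the *statistical
structure* the framework relies on, together with complete ground truth.
All experiments in the test suite and the acceptance script run on this
synthetic study.

## The model

Three branch encoders map each modality into a shared embedding dimension
$D$:

* **Video**: two frames are sampled uniformly from the clip, passed through
  a 4-block strided convolutional net (3×3 kernels, stride 2, channel widths
  16/32/64/$D$), their feature maps concatenated channel-wise and merged by
  a 1×1 convolution. The merged map (H′×W′×$D$, H′ = W′ = input/16) is the
  *spatial* video feature; global average pooling plus a linear layer gives
  the pooled vector.
* **Audio**: a 0.6 s speech window is resampled to 24 kHz and converted to a
  256×256 log-spectrogram (STFT, 10 ms Hann window, 5 ms hop, 256 linear
  frequency bands, `log(1+x)` compression, time axis interpolated to 256
  columns). The spectrogram is mean-pooled 4× at the stem and passed through
  an architecturally identical conv net with disjoint weights.
* **Text**: tokens are looked up in a fixed random embedding table (seeded
  from a hash of the vocabulary, width $E = 64$) standing in for pretrained
  word vectors; two fully-connected layers project $E \to D$. Tokens missing
  from the vocabulary map to a reserved unk row and are flagged.

### Objectives

With correspondence labels $c_i \in \{0,1\}$ and predicted probabilities
$p_i$, the correspondence loss is the standard binary cross-entropy

$$L_{base} = -\tfrac1N \sum_i \big[c_i \log p_i + (1-c_i)\log(1-p_i)\big].$$

The cross-modal contrastive loss treats each aligned pair $(V_i, A_i)$ as an
anchor with in-batch negatives,
$$L_{contra} = -\tfrac1N\sum_i \log
\frac{\mathrm{sim}(V_i, A_i)}{\sum_j \mathrm{sim}(V_j, A_i)},
\qquad \mathrm{sim}(x,y) = \exp(\cos(x,y)/\tau),$$
with temperature $\tau = 0.1$. Two denominator conventions are implemented:
the default (`"infonce"`) includes the positive term and is bounded below by
zero; the `"literal"` mode excludes it (and can therefore go negative); both
are tested. The joint objective is the convex combination
$$\mathscr{L} = \alpha L_{base}(V,A) + \beta L_{base}(V,T)
 + \gamma L_{contra}(V,A) + \delta L_{contra}(V,T),$$
with equal weights $\alpha=\beta=\gamma=\delta=0.25$ by default and the
constraint that the weights sum to one enforced at construction.

### Spatial-aware fusion

The basic fusion strategy concatenates the pooled embeddings and feeds them
through a small fully-connected head. The spatial-aware strategy instead
takes the element-wise product of the audio vector with every cell vector of
the spatial video map. The per-cell channel sums of that product tensor form
the **response map** used for localisation; its global average pool over
cells is the fused $D$-vector that the correspondence head consumes. Inside
the training graph, cells and audio vectors are L2-normalised before the
product and the pooled vector is rescaled by $\sqrt{D}$, so the head sees
O(1), cosine-structured inputs; the exposed response map remains the raw
dot-product map. The heads are two-layer perceptrons with a linear skip
path, which lets similarity-structured inputs reach the logit directly
instead of having to be rediscovered through the hidden layer.

For the spatial contrastive term, the raw score of (video $j$, audio $i$) is
the pooled response computed from normalised vectors — the mean per-cell
cosine — which keeps the exponentiated scores bounded at any temperature.

### Selective information gating (SIG)

Transcribed speech contains corrupted tokens (ASR errors) and off-topic
chatter. The SIG module computes a per-token gate: a 1×1 convolution over
the token axis followed by a fully-connected layer and a softplus, applied
to the projected embeddings (gating after projection). Gates at unk
positions are forced to exactly zero, so the pooled output — the
gate-normalised weighted sum of projected embeddings — is *exactly*
invariant to whatever content sits at corrupted positions. The
keyword-spotting variant additionally multiplies the gates of tokens absent
from an anatomy keyword dictionary by a depression factor $\lambda \in
[0,1)$ ($\lambda = 0$ by default, i.e. hard selection; $\lambda = 1$
recovers the outlier-filtering variant). A sequence whose every gate is
masked to zero yields an empty-feature flag, and such pairs are excluded
from the two text loss terms with the remaining weights renormalised.

## The synthetic study

`generate_scan()` emulates one scan session: a timeline of anatomy events
(2.2–3.4 s each, separated by 0.6–1.6 s of background), each rendering one
of 13 class-specific geometric shapes (ellipses, rings, crosses, bars,
paired blobs, …) at a random centroid over speckle noise. Narration follows
the events: with probability `1 - p_offtopic` the event's transcript segment
contains its class keyword (segment midpoint within ±0.3 s of the event) and
the waveform carries the class's acoustic signature — a two-tone mixture
(class $k$: 500+400k Hz and 6000+400k Hz) amplitude-modulated at 4 Hz to
mimic a speech envelope; otherwise the segment draws distractor words over a
neutral low-frequency signature. Tokens are corrupted into out-of-vocabulary
strings with probability `p_invalid_token`. Ground truth (per-frame plane
labels, region masks, Gaussian gaze maps) is emitted alongside.

Defaults: 60 s per scan, 6 fps, 64×64 frames, 24 kHz audio,
`p_offtopic = 0.3` (the real proportion of off-topic speech is not known;
this is a free choice exposed in the config), `p_invalid_token = 0.1`,
`noise_sigma = 0.05`. The tone frequencies are spaced 400 Hz apart so that
adjacent classes remain separable after the audio stem's 4× spectrogram
pooling (≈188 Hz per pooled band) — with narrower spacing the classes
alias together and the audio branch has no learnable signal, defeating the
generator's purpose.

What the generator does **not** emulate: realistic speckle physics, human
speech, probe motion, multi-fetus scans, within-class shape variability, or
class-imbalanced narration. Passing tests therefore demonstrate that the
framework recovers structure *of the kind it assumes*, at desk scale — not
clinical performance.

## Training procedure and numerical choices

Pairs are anchored at keyword-selected transcript segments — the output of
the audio cleaning chain (energy-based voice activity detection,
dominant-speaker selection, dictionary matching) — because anchoring at
arbitrary timestamps would make up to `p_offtopic` of the positives
uninformative. Negatives substitute the window of an anchor from a
different scan, or the same scan shifted by ≥ 5 s. The video clip is
co-extensive with the 0.6 s audio window.

Optimisation is SGD with momentum 0.9. The package defaults mirror the
reference schedule (learning rate 10⁻³ divided by 10 every 20 epochs, batch
size 40); the desk-scale experiments use a faster schedule (0.02, drop at
80) chosen from training-loss convergence on the synthetic study. Heads
train with a 10× learning-rate multiplier. Training frames receive random
±12 px translation augmentation — the synthetic study has few distinct
event instances per class, and translation is the nuisance factor the
generator actually varies; weaker augmentation (±6 px) measurably degrades
held-out transfer. After the main loop a short **head-calibration
phase** freezes the encoders and trains only the active correspondence head
on the correspondence term without augmentation, so the decision threshold
of p = 0.5 is calibrated under inference conditions; without it the head's
boundary sits visibly off the optimum of the held-out p-distribution.

Degenerate inputs are handled explicitly: all-zero saliency predictions are
flagged undefined by the compactness metric rather than dividing by zero;
constant maps get NSS 0 and AUC 0.5; a constant localisation response
yields an all-zero normalised map (ε-guarded min–max); contrastive terms
require at least two anchors and text terms at least one non-empty gated
feature, otherwise they are dropped with weight renormalisation.

## Problem sizes used in the harness

Two scales are exercised (chosen so the whole suite runs comfortably on one
CPU): a *recovery* scale — 6 scans × 60 s, D = 64, 110 epochs + 8
calibration epochs — for held-out correspondence accuracy and audio-guided
localisation; and an *ablation* scale — 4 scans × 45 s, D = 32, 35 + 6
epochs, 5 seeds × 2 variants — for direction comparisons (full model vs
video-audio baseline) on held-out accuracy and SPD transfer macro-F1.
The recovery-scale runs use τ = 0.05 (sharper in-batch separation than the
τ = 0.1 package default, selected on held-out correspondence accuracy of
the training fold's companion scans). Unit tests run on 2 scans × 20 s
with a 16-dimensional model.

### Dense localisation maps

The trained video map is 4×4 at 64 px input (stride 16), too coarse for
pixel-level localisation: the argmax of a bilinearly upsampled map always
sits on a map knot, i.e. a cell centre. `localise_from_audio()` therefore
evaluates the last two convolution blocks at stride 1 with dilated kernels,
yielding a 16×16 (stride 4) response map whose every 4th position equals
the trained strided features *exactly* — the standard dense-prediction
evaluation of a strided network, with no retraining and no new parameters.
The map is bilinearly upsampled to frame size and min–max normalised with
an ε-guard for constant maps.

## Design choices where the design was open

* **Spectrogram time axis**: a 0.6 s window at 5 ms hop yields ~118 STFT
  frames, not 256; the time axis is linearly interpolated to 256 columns
  (zero-padding and hop adjustment were the alternatives; interpolation
  keeps the full window in view at a fixed geometry).
* **"Frequency bands of 256"** is read as 256 linear bins (FFT size 512,
  Nyquist bin dropped), not mel bands.
* **Eq-form of the correspondence loss**: implemented as the standard
  negative-mean BCE, the only reading that is non-negative and minimised at
  p = c.
* **Gate placement**: the SIG gate is computed from, and applied to, the
  *projected* embeddings.
* **Fusion head input**: "combine with the word embeddings" is realised as
  scalar gate × embedding, then a normalised sum.
* **Saliency decoder**: four upsample-plus-3×3-conv blocks (nearest-
  neighbour 2×, then convolution) from the 4×4 map back to 64×64, followed
  by a 1×1 conv and a pixel softmax; upsample-conv was preferred over
  transposed convolution to avoid checkerboard artifacts and to reuse the
  tested convolution kernels.
* **Dictionary matching** is exact token match after case-folding; no
  stemming or phrase-level matching.
* **Embedding dimension at the fusion point** is configurable
  (`model_config(embed_dim=)`, default 128; the desk experiments use 64 and
  32).

## Known limitations

* The encoders are intentionally tiny; the `"paper"` preset exposes the
  256→224 centre-crop geometry but no large pretrained backbone.
* The audio cleaning chain uses an energy VAD and ground-truth-carried
  speaker labels as stand-ins for neural VAD/diarization/ASR; the plug-in
  points accept real models (waveform→waveform denoisers,
  waveform→segments transcribers).
* Correspondence accuracy on the synthetic study has an intrinsic ceiling
  below 1: about 1/13 of cross-scan negatives share the anatomy class of
  the video clip and are genuinely indistinguishable from positives.
* Single-threaded runs are bit-reproducible given a seed; multi-threaded
  BLAS may introduce rounding-level differences.
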