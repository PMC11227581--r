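# sonossl

Self-supervised audio-visual-text representation learning for clinical
ultrasound video, at desk scale, in R.

During a routine obstetric scan the sonographer describes what the probe is
showing ("this is the heart") while the machine records video. Narration
that co-occurs with the video is a free supervision signal: a video clip and
the speech window recorded at the same moment form a positive
correspondence pair, while windows spliced in from other scans form
negatives. `sonossl` implements a multi-modal framework built on this
signal:

* **Correspondence loss** — binary cross-entropy on matched/mismatched
  cross-modal pairs:
  `L_base = -(1/N) Σ [c·log p + (1-c)·log(1-p)]`.
* **Cross-modal contrastive loss** — for aligned pairs `(V_i, A_i)` with
  in-batch negatives:
  `L_contra = -(1/N) Σ_i log( sim(V_i,A_i) / Σ_j sim(V_j,A_i) )`,
  `sim(x,y) = exp(cos(x,y)/τ)`, τ = 0.1 (a "literal" mode excluding the
  positive from the denominator is also provided).
* **Spatial-aware fusion** — the audio vector is fused with every cell of
  the H′×W′×D video feature map by element-wise product; the per-cell
  channel sums form a response map used for sound-guided anatomy
  localisation.
* **Selective information gating (SIG)** — a per-token gate over transcript
  embeddings that zeroes corrupted ⟨unk⟩ tokens exactly (outlier filtering)
  and depresses tokens outside an anatomy keyword dictionary (keyword
  spotting).
* **Joint objective** — `α·L_base(V,A) + β·L_base(V,T) + γ·L_contra(V,A) +
  δ·L_contra(V,T)` with `α+β+γ+δ = 1` (equal weights by default).
* **Downstream transfer** — 14-way standard plane detection, eye-gaze
  saliency prediction (KL objective, evaluated with KL/NSS/AUC/CC/SIM and a
  saliency-compactness score `Comp = IoU · η_H / α_S`), and audio-guided
  localisation.

The real clinical data this kind of framework is trained on is not publicly
available, so the package includes a synthetic scan generator
(`generate_scan()`) that reproduces the structure the framework assumes —
sparse audio-visual co-occurrence, off-topic speech, transcription noise —
with complete ground truth (plane labels, anatomy masks, gaze maps). The
training machinery (a small reverse-mode autodiff tape over matrices with
Rcpp convolution kernels) is self-contained.

## Worked example

```r
library(sonossl)

# one synthetic scan: 20 s of video at 6 fps with narrated anatomy events
rec <- generate_scan(scan_config(duration_s = 20, seed = 1))
rec
#> <scan_record> 120 frames @ 6 fps, 20.0 s audio @ 24000 Hz, 5 events, 5 transcript segments

# audio front end: 0.6 s window around an anatomy utterance -> 256x256
sp <- log_spectrogram(audio_window(rec$waveform, t = 5))
sp
#> <spectrogram> 256 bands x 256 frames, 0-11953.1 Hz

# selective information gating: corrupted tokens are zeroed exactly,
# keyword spotting keeps dictionary terms only
m <- init_model(model_config(embed_dim = 32),
                vocab = c(rec$config$anatomy_vocab, filler_words), seed = 1)
sig_keyword_spot(m, embed_text(m, c("this", "is", "the", "heart")),
                 keyword_dictionary(rec$config$anatomy_vocab))
#> <gated_text_feature> D=32, 4 tokens, gate mass 0.699

# saliency compactness: a tight, correctly-placed prediction scores high
pred <- matrix(0, 4, 4); pred[1:2, 1:2] <- c(1, 1, 0.4, 0.4)
ref  <- matrix(0, 4, 4); ref[1:2, 1:2] <- 1
comp_metric(pred, ref, thres = 0.5)
#> <comp_result> alpha_S=0.25 alpha_H=0.125 eta_H=0.500 IoU=1.000 comp=2
```

`alpha_S` is the fraction of the image covered by the predicted saliency
support, `alpha_H` the fraction above the confidence threshold, `eta_H`
their ratio (how much of the prediction is high-confidence), and `comp`
rewards predictions that are compact (small `alpha_S`), confident (high
`eta_H`) and correctly placed (high IoU against the reference support).

Pretraining on the standard synthetic study (6 scans of 60 s, ~6 min on one
CPU) and transfer:

```r
scans <- standard_scan_set(seed = 0)
pr <- standard_pretrain(scans, variant = "full", seed = 0)   # video+audio+text, SIG, spatial fusion
evaluate_correspondence(pr$model, scans[5:6], "full", n_pairs = 240)
localisation_hit_rate(pr$model, scans[5:6])
cl <- finetune_spd(pr$model, scans, train_scans = 1:4, val_scans = 5:6)
cl$report$macro_f1
```

A thin command-line wrapper over the same functions lives at
`inst/cli/sonossl.R` (`generate`, `pretrain`, `finetune-spd`,
`finetune-saliency`, `localise`, `evaluate`).

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic study | `scan_config`, `generate_scan`, `render_frame`, `make_gaze_map`, `write_scan` |
| Audio pipeline | `resample_waveform`, `detect_voice_segments`, `select_sonographer`, `log_spectrogram`, `select_keyword_segments` |
| Encoders | `model_config`, `init_model`, `encode_video`, `encode_audio`, `embed_text` |
| Gating | `sig_filter_outliers`, `sig_keyword_spot`, `keyword_dictionary` |
| Objectives | `loss_base`, `loss_contrastive`, `similarity_matrix`, `fuse_concat`, `fuse_spatial`, `spatial_objective`, `joint_loss` |
| Pretraining | `sample_pairs`, `pretrain`, `evaluate_correspondence`, `standard_pretrain`, `run_ablation` |
| Transfer | `finetune_spd`, `finetune_saliency`, `localise_from_audio`, `localisation_hit_rate` |
| Metrics | `classification_report`, `saliency_metrics`, `comp_metric` |
| Config/CLI | `load_config`, `run_command` |
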