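---
title: "Dual-stream spatial-temporal transformers for EEG emotion classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-stream spatial-temporal transformers for EEG emotion classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stteeg)
```

## The problem

Music reliably evokes emotion, and emotion leaves measurable traces in
scalp EEG: liked music is associated with increased frontal-midline theta
(4–8 Hz) power, disliked music with increased frontal beta (13–30 Hz)
power. `stteeg` classifies the evoked emotion — negative/positive, or
negative/neutral/positive — directly from raw multi-channel EEG, without a
hand-crafted feature stage. The classifier is a pair of small transformer
encoders that consume the same raw signal patches in two different token
orders, one emphasizing the electrode (spatial) axis and one the epoch
(temporal) axis, whose class-token logits are fused by a layer-normalized
linear map.

The corpus the package targets is a music-listening protocol: 32 subjects,
each hearing 12 one-minute clips (4 positive, 4 negative, 4 neutral), on a
32-channel 10-20 montage resampled to 128 Hz. Such corpora are typically
private; the package therefore ships a synthetic generator that reproduces
the protocol's structure and the literature's band-power effects so that
every stage is testable end to end.

## From recording to model input

**Epoching.** Each recording is cut into 4-s windows (512 samples at
128 Hz) on a fixed grid with 50% overlap, i.e. stride 2 s. Windows start at
0, 2, 4, … s over the whole duration `[0, T)`; a window whose end passes
`T` wraps circularly to the start. The count is therefore exactly
`floor(T / stride)`: a 4-min recording per class yields 120 epochs, so the
two-class corpus yields 240 and the three-class corpus 360 — the counts the
protocol prescribes. An end-clamped rule (`(T − w)/s + 1` windows) cannot
produce those counts, which is why the wrap rule is used. Offsets are
0-based and half-open; samples are stored time-major (rows = samples,
columns = electrodes in montage order).

The montage constant reproduces the acquisition list verbatim, including
the idiosyncratic label `FC` at the position conventionally called `FC2`;
readers accept `FC2` (and any case variant) as an alias.

**Grouping.** The model consumes groups of `G = 8` epochs sharing one
label. Epochs are grouped within each subject-by-label stratum, ordered by
clip and then start offset, in consecutive non-overlapping runs of 8;
120 epochs per stratum give exactly 15 groups. Leftovers shorter than `G`
are dropped with a warning.

## The model

**Tokenization.** Every epoch is sliced into slabs of `H = 5` consecutive
electrodes (montage order) × `W = 512` samples; 32 electrodes give
`ceil(32/5) = 7` slabs, the last zero-padded from two rows. A group thus
yields 56 tokens of dimension `H·W·C = 2560` (`C = 1` raw-voltage channel).
Both streams see the *same* tokens; they differ only in order. The spatial
stream enumerates slabs within each epoch (electrode axis fastest), the
temporal stream enumerates epochs within each slab (time axis fastest), so
each stream's learned position embedding indexes a different axis of the
data. This realizes a genuinely dual view with a single tokenizer and
identical information in both streams.

**Encoder.** Tokens are mapped by an affine layer to `D` dimensions, a
learnable class token is prepended, and a learned position embedding is
added. Each of `L` pre-norm blocks applies
`x <- x + MSA(LN(x))` then `x <- x + MLP(LN(x))`, with multi-head scaled
dot-product self-attention (`n_heads` heads) and a two-layer MLP of width
`mlp_mult × D` with exact (Gaussian-CDF) GELU between. The two streams are
structurally identical and share no parameters: updating one never changes
the other's output. A final layer norm on the class token feeds an affine
classification head (the ViT convention), giving `Y_spatial` and
`Y_temporal`.

**Fusion.** The reported output is
`Y = Linear(LayerNorm([Y_spatial ‖ Y_temporal]))` — layer normalization
applied to the concatenation of the two logit vectors followed by one
affine map to the class scores. Any of the three logit sets can drive a
classification on its own, which is what the channel ablation exploits.

Defaults follow the reference configuration: `n_heads = 4`, `L = 8`
(the best cell of the heads-by-layers ablation), `alpha = 0.3`. `D = 64`,
`mlp_mult = 4` and `dropout = 0.1` are desk-scale conventions, all
configurable.

**Initialization.** Weight matrices are truncated-normal with Glorot
(fan-in/fan-out) scaling; the class token and position embedding use the
ViT-conventional sigma = 0.02. A fixed sigma of 0.02 on the attention and
MLP matrices — the literal ViT recipe — is an order of magnitude below the
Glorot scale at `D = 32` and left small models stuck at the symmetric
chance-level saddle for hundreds of optimizer steps, with strong
seed-to-seed variability; Glorot scaling removed both effects. The
patch-embedding map itself is initialized *spectrally* by default
(`stt_config(embed_init = )`): columns form sine/cosine quadrature pairs
at random per-window frequencies with random electrode weightings, each
scaled to the norm a truncated-normal column would have. The first layer
thus starts as a random bank of band-selective filters — the natural
coordinate system for oscillatory signals — and training only has to
learn their phase-invariant combinations. Plain Glorot initialization of
the embedding (`embed_init = "normal"`) is retained as an option.

A note on the two streams' semantics: descriptions of such dual-channel
models sometimes suggest the spatial stream should mix epochs *across*
subjects listening to the same music. Grouping across subjects would,
however, contradict the same-subject definition of the model input, so
both streams here consume groups from a single subject; the streams differ
in token order only. Ternary class indices are ordered (−1, 0, +1);
binary tasks use (−1, +1) with `+1` as the positive class of the single
confusion view.

## Training

The objective is the composite loss
`alpha·CE(Y_spatial) + (1 − alpha)·CE(Y_temporal)`, with `alpha = 0.3` by
default. Because the fused `Y` is the output actually reported, a
unit-weight `CE(Y)` term is added by default
(`train_config(include_fused_loss = )` disables it to train the bare
composite). The optimizer is AMSGrad (adaptive moments with a
non-decreasing second-moment maximum, bias-corrected) at learning rate
0.001.

Two training choices are this package's own:

* **Input standardization.** Raw microvolt patches are divided by the
  pooled training-set standard deviation (stored on the model and applied
  at prediction time). With truncated-normal σ = 0.02 initialization,
  unstandardized inputs two orders of magnitude off unit scale leave the
  optimizer crawling; this is an implementation necessity, not a tuned
  constant.
* **Decoupled weight decay** (AdamW-style, default 0.01 on weight matrices
  only) and dropout after the embedding, the attention projection and the
  MLP. At desk scale the corpus is a few hundred groups while the model has
  tens of thousands of parameters; without regularization the encoder
  memorizes the training groups and transfers poorly. Both are standard
  transformer practice and fully configurable.
* **Circular time-shift augmentation** (`train_config(augment_shift = )`,
  on by default). At each presentation every training epoch is rolled by a
  uniform random number of samples with wrap-around — exactly the epoching
  convention's wrap, so a shifted epoch is a legitimate epoch of the same
  recording at a different grid phase. The emotion signatures of interest
  are oscillatory band-power effects, which are invariant to such shifts,
  while waveform memorization is not; the augmentation therefore steers
  the encoder toward the spectral features that generalize. Evaluation
  always sees unshifted epochs.

Gradients are computed by hand-derived analytic backpropagation through
the fusion head, both encoders and the embeddings; a finite-difference
check in the test suite validates every parameter tensor's gradient to
1e-4. Training is deterministic given the seed: initialization, batch
shuffling and dropout masks all derive from it, and identical
configurations reproduce identical parameters bit for bit.

Degenerate inputs: non-finite activations abort with the failing layer
index; a training loss that leaves the finite range aborts the fold with a
training error; an all-one-label corpus trains and scores trivially, with
the undefined specificity reported as `NA` rather than 0.

## Evaluation protocol

Groups are split into `k = 10` stratified folds (sizes differ by ≤ 1
overall and per label); each fold is held out once, a fresh model (new
seed-derived initialization) is trained on the rest, and the held-out fold
is scored with the fused logits. Sensitivity `TP/(TP+FN)`, specificity
`TN/(TN+FP)` and accuracy `(TP+TN)/N` are computed from one-vs-rest
confusion counts — a single view with positive class `+1` for binary,
macro-averaged over the three views for ternary (the ternary definition is
this package's choice; the macro average is the common convention). The
aggregate is the arithmetic mean over folds.

Group-level fold assignment mirrors the sample-wise protocol the headline
results use. Note that with 50%-overlapping epochs, groups cut from the
same recording share signal, so sample-wise splitting leaks information
across folds and flatters absolute accuracies; `kfold_split(by =
"subject")` provides the honest subject-disjoint alternative. Both modes
are first-class; the leakage caveat applies to any protocol that epochs
before splitting.

**Ablations.** `ablation_channels()` trains three variants on identical
folds: spatial-only (`alpha = 1`, no fused term, spatial head),
temporal-only (`alpha = 0`, temporal head) and the combined model.
`ablation_grid()` sweeps heads × layers with shared folds and writes one
row per cell, resuming from a checkpoint CSV if interrupted.
`sweep_alpha()` traces the loss-weight trade-off. Each returns a tibble
with an `autoplot()` method.

## The synthetic corpus

`synth_spec()` describes a balanced protocol-shaped corpus; defaults are
32 subjects × 4 clips/class × 3 classes × 60 s × 128 Hz × 32 channels.
Each channel is Gaussian `1/f` background noise (spectral exponent 1.0,
the standard EEG broadband model; SD 10 µV) plus class-conditional
band-limited oscillations: positive clips add a theta (4–8 Hz) oscillation
at Fz, Cz, AF3, AF4; negative clips a beta (13–30 Hz) oscillation at Fp1,
Fp2, F3, F4, F7, F8; neutral clips add nothing. Topographies follow the
frontal-midline-theta / frontal-beta effects reported for liked and
disliked music. An oscillation is a sum of eight equal-amplitude sinusoids
spanning the band with phases drawn once per subject×clip (coherent across
the affected electrodes), scaled so its RMS equals `gain × snr` background
standard deviations — by default 1.0, a deliberately strong, cleanly
separable effect. The generator is a pure function of its spec: identical
seeds give bit-identical corpora.

What the generator does *not* emulate: volume conduction and realistic
topographic mixing, non-stationarity within a clip, ocular/cardiac
artifacts (an eyes-closed protocol is assumed), inter-subject variability
in effect topography, and effect sizes of realistic magnitude. Passing the
recovery tests therefore demonstrates that the pipeline can learn genuine
class-conditional spectral structure from raw signal — not that it would
reach the same accuracy on real recordings.

## Problem sizes used by the shipped checks

The packaged tests and the acceptance script run the full protocol at
reduced scale, chosen to exercise every stage in minutes on one core:
recovery runs use the default generator reduced to 8 subjects (ternary,
360 groups) with a small model (`D = 32`, `L = 2`, 2 heads) under 3-fold
cross-validation; the channel ablation runs on the same corpus with 2
folds (the ternary task keeps every variant away from the accuracy
ceiling, so the stream comparison is informative — on an easy binary
corpus a single stream saturates at 1.0 and the comparison degenerates to
granularity noise); determinism checks use 2 subjects and 2 folds. The
epoching arithmetic (240/360 epochs, 512 samples) is exact at any scale.
Fold counts below 10 keep per-fold test sets comparable to the full
protocol's while bounding the number of trained models. The checks train
with the default optimizer settings (AMSGrad, learning rate 0.001) in
batches of 16 groups, for 40 epochs (15 for the shuffled-label control).

## Known limitations

* Attention is computed in a per-group loop (compiled, as are layer norm
  and GELU; the plain-R reference implementations are kept and
  cross-checked in the tests); fine for desk-scale corpora, slow for
  thousands of groups.
* No GPU path; everything is BLAS-backed double precision.
* Checkpoints serialize parameters as decimal text, exact only to
  double-precision printing.
* The EDF writer quantizes to the 16-bit digital grid (relative error
  ~3e-5 of the per-channel range), so corpora round-trip via CSV exactly
  and via EDF approximately.
* Sample-wise folds inherit the overlap-leakage caveat above.
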