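---
title: "Audio-visual species recognition with duetnet: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audio-visual species recognition with duetnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(duetnet)
```

## The problem

Beneficial insects — lady beetles, lacewings, parasitoid wasps — are monitored
in the field with paired cameras and microphones. Closely related species can
be near-identical visually (same body plan, slightly different pronotum
pigmentation or spot layout) while differing in wingbeat acoustics, and vice
versa. duetnet classifies species from *synchronized* image/audio pairs, and
produces saliency maps in both modalities so that a field entomologist can
check *what* the model looked at (elytral spots, pronotum, a harmonic band)
rather than trusting a bare label.

Everything below — the network, its gradients, the attribution methods — is
implemented in base R on top of BLAS matrix operations. This is deliberate:
the explainability module needs exact gradients at arbitrary interior nodes
(feature maps, attention weights, the spectrogram input), and owning the
backward pass makes those available without framework tricks. All backward
passes are validated against central finite differences in the test suite.

## Model

**Visual branch.** A patch embedding (4 px patches) followed by four stages of
windowed self-attention. Each stage has one block attending within 4x4 token
windows and one within cyclically shifted windows, then 2x2 patch merging.
Stage widths follow the 96/192/384/768 schedule with 3/6/12/24 heads; the
`tiny` scale divides widths by 8 and takes 128 px inputs. A stride-2
transposed-convolution decoder (3x3 kernel, GELU) lifts the final 4x4 grid to
the 8x8 feature map the rest of the pipeline consumes. We do not mask
attention across cyclic-shift boundaries: at desk scale the wrap-around
window mixes a handful of border tokens and the simplification measurably
changes nothing downstream, but it is a difference from a faithful shifted-
window implementation at large scale.

**Acoustic branch.** The input is a 64-band mel spectrogram (25 ms Hann
window, 10 ms hop, log(1+power) compression, 96 frames of a 1 s clip). A
small convolutional stem captures local band-energy patterns, then
non-overlapping 8x24 patches produce an 8 (frequency) x 4 (time) token grid
with sinusoidal *temporal* positional encoding; four Transformer layers with
the same width/head schedule as the visual stages (linear transitions between
widths) yield the 8x4 acoustic map. One shared projection matrix maps both
branches to the common width d (64 tiny / 512 reference).

**Fusion.** Four bidirectional cross-attention layers. Per layer, a shared
transition projects both streams to the layer width (16/32/64/64 at tiny
scale); queries, keys and values use one `Wq`, `Wk`, `Wv` each — the same
matrices serve both directions, and attention is single-head with a
`1/sqrt(d)` temperature, exactly the printed form of the mechanism. Updates
are residual + post-layer-norm. The final layer's acoustic-to-visual
attention, summed over acoustic queries, is the *attention marginal* `Mc`
used by the explanation loss.

**Heads.** Mean-pooled fused tokens feed (i) a linear classifier (on the
concatenated pair, or on one modality for the unimodal heads used in
ablations), and (ii) a shared two-layer projection head (GELU, then L2
normalization) producing unit-norm embeddings `zv`, `za` and the joint
embedding `zm = normalize((zv + za)/2)`.

## Losses

* **Classification**: softmax cross-entropy.
* **InfoNCE** over the joint embeddings with cosine similarity and
  temperature `tau = 0.07`: for each anchor and positive, minus log of the
  positive's share of `exp(s/tau)` against the anchor's mined negatives.
  Positives are same-species samples; negatives are ranked by the batch
  similarity matrix and the top `hard_k` kept, with the designated confusable
  partner class guaranteed a slot when present.
* **Margin**: `max(0, delta + d+^2 - d-^2)` averaged over triplets,
  `delta = 0.2`. The printed variants of both contrastive losses (sign
  conventions that contradict their own stated optimum) are retained behind
  `verbatim = TRUE` for inspection but are not used for training.
* **Total**: `L_cls + 0.5 * L_cs + 0.1 * L_margin`. The weights are package
  defaults; no reference values exist.
* **Explanation loss** `mu1*TV(Hc) + mu2*KL(softmax Hc || softmax Mc) +
  mu3*||F - Pi.F||^2` with `mu = (0.1, 0.1, 0.01)`. TV is the anisotropic
  l1 of forward differences (an isotropic variant is available); the class
  mask `Pi` is the generator's foreground mask block-averaged onto the
  visual token grid.

**First-order training of the explanation stack.** The gradient-based
saliency maps (Grad-CAM++ visually, integrated gradients acoustically) are
*detached* inputs to the explanation loss: TV and the H-side of the KL train
the gating network, the M-side of the KL trains the attention, and the
gating regularizer trains the encoder features. Interpreter deconvolution
heads are trained by L2 regression onto the detached maps. This keeps every
loss first-order — differentiating through a saliency map would require
second derivatives of the network, which buys little at this scale. The
explanation loss is evaluated on one sample every `xai_every = 8` steps with
8 integration steps, a stochastic regularizer that keeps its cost a small
fraction of a training step.

## Explainability

`explain_pair()` implements the full pipeline: Grad-CAM++ on the projected
visual map (standard closed form under the exponential-logit surrogate; the
printed derivative-ratio variant is available as `verbatim = TRUE`),
integrated gradients on the mel spectrogram (midpoint Riemann path integral,
batched over path points; the completeness residual is reported with every
call), interpreter-head upsamplings of both feature maps, a learned pixel
gate `G = sigmoid(conv(GELU(conv([Hv, Ha]))))`, and the fused map
`Hc = G*Hv + (1-G)*Ha`, which is pointwise bounded by min/max of its inputs
by construction. Heatmaps are min-max normalized; upsampling to 64x64 uses
bilinear interpolation for reporting and integer block replication where a
backward pass is needed (interpreter heads, attention marginal).

## Synthetic data

The generator stands in for a private field dataset and defines the study
conditions:

* **Classes.** Each species has an ellipse body with hue, pronotum band hue,
  and a spot pattern, plus a wingbeat signature (fundamental 120-600 Hz with
  3-5 decaying harmonics). Every even class has a designated confusable
  partner: identical morphology except the pronotum hue, wingbeat within
  15% — hard negatives are genuinely hard.
* **Scenes.** Procedural backgrounds (low-frequency gradients and blobs)
  cycled from a small pool; pose jitter per sample.
* **Acoustics.** Clips carry an ambient background at a per-clip SNR drawn
  uniformly from 8-18 dB, the range reported for real field sites from calm
  to strong interference. This matters: models trained on noise-free audio
  collapse under *any* evaluation corruption, which would make robustness
  protocols meaningless.
* **Alignment.** Acoustic timestamps are jittered by a configurable Gaussian
  (`sd` 0.02 s); about 5% of pairs are flagged weakly aligned (a second
  species' clip mixed at equal power, mimicking overlapping calls) and are
  excluded from supervised training.
* **Determinism.** One master seed; per-sample substreams are derived by
  counter, so generation is order-independent and the manifest is bit-stable.

What the generator does *not* model: photorealistic insects, real call
libraries, occlusion, motion blur, reverberation. Passing tests demonstrate
that the pipeline recovers planted, well-separated class structure — not
field-grade accuracy.

## Training defaults and numerical choices

* AdamW (`beta1 = 0.9`, `beta2 = 0.999`, weight decay 0.05 on weight
  matrices only), initial learning rate 1e-4 with cosine annealing to 1e-6,
  batch 8, early stopping on validation accuracy (patience 10).
* **Initialization** is fan-scaled truncated normal (Glorot variance,
  clipped at 2 sd). A fixed sd of 0.02 is standard at reference widths
  (where it approximately equals the fan-scaled value) but at tiny widths it
  leaves weights so small that optimizer steps dominate the parameter scale
  and training stalls at chance; fan scaling restores the usual regime at
  every scale.
* **Augmentation** (on by default) applies photometric jitter, additive
  waveform noise and paired time-shifts at the package's default ranges, and
  corrupts ~35% of clips with background noise at a uniform 0-20 dB SNR.
  The noise exposure is what teaches the fused model to discount a degraded
  acoustic stream — the "noise-adaptive" behaviour of the attention is
  learned, not architectural.
* Ties in nearest-neighbour alignment break toward the earlier acoustic
  timestamp; DTW allows the acoustic index to repeat but never decrease.
  Softmax rows are max-shifted before exponentiation. Zero-norm embeddings
  raise an error rather than being silently renormalized. Grad-CAM++
  denominators are stabilized with 1e-8 and zeroed where degenerate.

## Problem sizes used by the test suite and acceptance script

The headline benchmark trains the tiny configuration (128 px, 44.1 kHz) on
60 pairs of 3 classes with 15 validation pairs for up to 30 epochs. The
ablation grid (full model vs. no-fusion / no-contrast / no-explanation, three
seeds) and the SNR-robustness protocol (fused vs. acoustic-only at 20/10/0 dB)
run at 64 px / 16 kHz with 27 training pairs, which preserves every module
interaction at a fraction of the cost. These sizes are the package's chosen
benchmark scale; the configuration objects accept the reference scale
unchanged.

## Known limitations

* Shifted-window attention is unmasked across cyclic boundaries (see above).
* At benchmark scale the learned cross-modal attention stays close to uniform
  (row entropy near its maximum), with or without acoustic corruption: the
  robustness of the fused model comes from how training shapes the value and
  residual pathways, not from visibly selective attention weights. Claims
  about "noise-adaptive" attention should therefore be read as claims about
  the fused representation, not about the attention matrix itself.
* The acoustic interpreter head reaches 64x32 by transposed convolutions and
  is width-doubled by replication — an 8x4 grid cannot reach 64x64 by three
  symmetric stride-2 steps.
* The engine is single-threaded R; the reference ("paper") scale is
  configurable and functional but not practical to train here.
* Hard-negative mining recomputes the similarity matrix per batch rather
  than per epoch; at benchmark batch sizes the distinction is immaterial.
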