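---
title: "Hybrid generative-contrastive pretraining for CT nodule classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid generative-contrastive pretraining for CT nodule classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(noduleSSL)
```

## The problem

Distinguishing benign granulomatous nodules from solid lung adenocarcinomas
on CT is hard: both present as solitary solid nodules of 7-30 mm, and
benign granulomas frequently show the spiculation and lobulation usually
associated with malignancy. Labelled data are scarce, which motivates
self-supervised pretraining: learn a representation of lesion appearance
from unlabelled (or weakly labelled) scans, then fine-tune a small
classifier on the limited labelled set.

`noduleSSL` implements a hybrid self-supervised scheme that combines two
complementary pretext tasks on lesion-centred image montages:

* a **generative** task — a masked autoencoder reconstructs hidden montage
  patches from the visible ones, forcing the encoder to model global lesion
  context; and
* a **contrastive** task — a momentum-contrast objective pulls together the
  axial and coronal views of the *same* lesion while pushing apart keys
  from other lesions stored in a FIFO dictionary, forcing the encoder to
  encode lesion-specific identity.

## Data representation: the 5x5 montage pair

Each annotated lesion is turned into two 250 x 250 images:

1. the raw HU volume is resampled to 1 mm isotropic spacing (trilinear,
   border-clamped, output size `round(n * spacing / target)` per axis);
2. intensities are windowed to the lung window (width 1400 HU, level
   -500 HU) and mapped linearly to [0, 1];
3. 25 consecutive slices centred on the lesion (12 each side of the anchor
   slice) are cropped to the 50 mm ROI square around the anchor, in both
   the axial and the coronal plane (coronal slices re-oriented so the
   cranio-caudal axis is vertical; out-of-volume regions padded with
   windowed air, never truncated);
4. the 25 crops are tiled row-major into a 5 x 5 montage.

The isotropic 1 mm grid is what makes the 50 mm ROI exactly 50 px, so the
montage partitions into 25 clean 50 x 50 patches. Augmentation enumerates
4 rotations x 2 horizontal-flip states x 5 anchor translations (centre and
+/-5 mm in-plane) = 40 variants per case; the identity variant reproduces
the unaugmented pair bit-exactly, and fine-tuning uses the unaugmented
dataset only.

## Tokenisation and masking

A montage is partitioned into 25 patches; a mask plan hides
`floor(25 * ratio + 0.5)` of them, drawn uniformly without replacement
(ratio 0.5 by default; the two views of a pair are masked independently).
Visible patches are flattened row-major, linearly projected, and summed
with sinusoidal position embeddings
(`PE[pos, 2i] = sin(pos / 10000^(2i/d))`,
`PE[pos, 2i+1] = cos(pos / 10000^(2i/d))`); a learnable class token without
position embedding leads the sequence. Masked patch content never enters
the encoder.

## Architecture

The encoder is a pre-norm vision transformer (GELU MLP at ratio 4, final
layer norm). Two presets are built in: `"large"` (24 blocks, width 1024,
16 heads — the ViT-Large scale used on clinical data, with an 8 x 512
decoder) and `"tiny"` (2 blocks, width 64, 4 heads, with a 1 x 32 decoder)
for CPU-scale phantom experiments and tests. The decoder receives the
visible latents through a learned width adapter plus one *shared* learnable
mask token at every masked position (each carrying its position's
sinusoidal embedding) and predicts raw pixels for masked patches only.

The momentum encoder starts as an exact copy of the encoder and is updated
only as `theta_m <- (1 - m) theta_m + m theta_e` with `m = 0.01`; it never
receives gradients. The two flattening heads (kernel-1 one-dimensional
convolution over the token axis, mean-pool over positions, linear map to
128, L2 normalisation) are *individual*: the key-path head starts from its
own initialisation and is momentum-updated towards the query head. Starting
the key head as a copy would make the positive similarity begin near 1
(identical networks applied to correlated views), which masks the early
course of the contrastive loss.

Weights are initialised with fan-in scaling (`sd = 1/sqrt(fan_in)`). A
flat constant such as 0.02 is calibrated to ViT-Large widths and starves
narrow presets: signal injected by attention and MLP blocks is then an
order of magnitude too small for patch content to reach the class token.

## The objective

With query `q+` and positive key `k+` (both unit vectors) and queue keys
`k_i`:

* InfoNCE: `L = -log( exp(q.k+/tau) / (exp(q.k+/tau) + sum_i exp(q.k_i/tau)) )`,
  temperature `tau = 0.07` (the established momentum-contrast convention;
  the combination of raw dot products with a fixed temperature is only
  stable for normalised vectors, hence the L2 step in the heads).
* masked MSE: mean squared error over masked pixels only (raw [0,1]
  montage units, no per-patch target normalisation); defined as 0 when
  nothing is masked.
* total: `L = lambda * L_MSE + (1 - lambda) * L_InfoNCE`, `lambda = 0.5`
  by default; `lambda = 1` (or disabling the contrastive branch) recovers a
  plain masked autoencoder, `lambda = 0` pure momentum contrast.

The dictionary holds 700 keys of dimension 128 by default and behaves as a
strict FIFO. At the start of pretraining it is pre-filled with random unit
keys — the reference momentum-contrast convention — so the number of
negatives (and hence the scale of the loss) is stationary from the first
step. Keys are detached: no gradient reaches the momentum encoder, and the
key batch is enqueued after the optimizer step.

## Optimisation protocol

Pretraining uses AdamW (betas 0.9/0.95, decoupled weight decay 0.05 on
weight matrices only) at initial learning rate 1e-2 for 100 epochs, batch
64. The reference protocol specifies rate drops at epochs beyond the 100-epoch
budget, which is unsatisfiable as stated; the package therefore places the
pretraining milestones at 60% and 80% of the configured budget, preserving
the schedule's shape at any scale (raw epoch numbers are also accepted).
Fine-tuning uses 100 epochs at 1e-3 with drops at (raw) epochs 40 and 70,
early stopping after 10 non-improving validation epochs, a case-level
stratified 8:2 train:test split, and 5-fold cross-validation within the
training portion; the returned classifier is the fold ensemble (mean
softmax). Splits are case-level so all augmented variants of a case stay
on one side, preventing leakage.

Fine-tuning trains the full encoder plus a fresh two-class fully connected
layer on the class-token output. The head is parameterised in standardised
coordinates: per-feature mean and standard deviation of the class-token
features over the fold-training cases are computed once when the fold
starts and frozen, and the linear layer acts on the standardised features.
This is an exact affine reparameterisation — the model class is unchanged —
but it conditions the optimisation: early in training the class-token
spread is of order 1e-2, and because Adam's per-parameter step is bounded
by the learning rate, a raw-coordinate head cannot reach a useful operating
point within a short epoch budget.

## The synthetic phantom cohort

Clinical CT datasets cannot be redistributed, so the package generates
HU-valued phantoms that emulate the study conditions: anisotropic volumes
(default 128 x 128 in-plane at 0.7 mm, 80 slices at 2.3 mm, a typical
thin-slice chest protocol), aerated-lung background (-800 +/- 40 HU),
and a single solid nodule (+30 +/- 25 HU) with diameter uniform on
7-30 mm. The nodule surface is a spheroid whose radius is modulated by a
direction-dependent bump field

`r(u) = r0 * (1 + min(a_lob * sum_j vMF(u; d_j, kappa_lob) + s * sum_k vMF(u; s_k, kappa_spk), cap))`

with von Mises-Fisher kernels `vMF(u; d, kappa) = exp(kappa (u.d - 1))`:
broad low-frequency bumps (kappa 4) model lobulation, narrow spikes
(kappa 25) model spiculation. Benign-like cases (label 0) carry 2 lobes;
malignant-like cases (label 1) carry 6 lobes plus 24 spikes of amplitude
0.55 r0. The cap (lobulation total plus two spike amplitudes) prevents
degenerate growth where spikes align and bounds the voxel search region.
The two classes have identical intensity statistics: the signal is purely
morphological.

Calibration targets, chosen once: (i) the scale-free radial shape
statistic (variance of `r(u)/r0` over 1000 random directions) separates the
classes with AUC > 0.95 on 100 cases, and (ii) the same separation survives
projection into the montages — a single 2D boundary-roughness statistic
(thresholded central-slice perimeter over the square root of area) reaches
AUC ~0.95. The second target matters because the generator exists to make
the *downstream* task learnable: morphology that only a 3D statistic can
see cannot be learned from 2D montages. Normalising radii by `r0` is
essential since both classes share the 7-30 mm diameter distribution.

What the phantoms do **not** emulate: pleural surfaces and indentation,
airways and vessels, contrast phases, scanner noise texture
(quantum/reconstruction-kernel effects), or the partial overlap of real
benign/malignant nodule morphology (real granulomatous nodules mimic malignant shape far
more than label-0 phantoms do). Passing phantom experiments therefore demonstrates
that the pipeline can extract class-relevant morphology end-to-end — not
that clinical performance would be reproduced.

## Smoke-scale experiment

The end-to-end experiment used by the test suite and the acceptance script
runs, per seed: 200 unaugmented phantom pairs; tiny preset; 30 epochs of
hybrid pretraining; 20 epochs of fine-tuning. At this scale two of the
paper-scale constants are rescaled with the dataset, as the package's own
smoke-protocol choice: batch size 8 for pretraining and 4 for fine-tuning
(batch 64 would give only 4 optimisation steps per epoch on 200 samples),
and dictionary capacity 64 (a 700-key queue over 200 samples would hold
several stale copies of every sample as its own negatives; an oversized
dictionary is counterproductive when the dataset is small). Package
defaults remain the full-scale values. Typical behaviour: the epoch-mean
total loss over the last five epochs falls below the first five, and the
fold-ensemble held-out AUC on 40 phantom cases exceeds 0.9 within about
five minutes on one CPU.

## Numerical choices and degenerate inputs

* Mask counts round half up; ratio 1 is rejected at pretraining (nothing
  visible to encode), ratio 0 makes the reconstruction loss vacuously 0.
* Layer norm uses eps 1e-6; the L2 normalisation guards against zero norm
  with a 1e-12 floor; log-sum-exp is used for all softmax-type losses.
* Trilinear resampling clamps border samples, so interpolation never
  expands the HU range; a volume already at target spacing is returned
  exactly.
* Anchors are snapped to the nearest voxel centre; even-sized ROI crops
  place the anchor at index 25 of 50 (24 left, 25 right).
* Patch flattening is row-major throughout (tokeniser and reconstruction
  targets must agree).
* AUC is the Mann-Whitney concordance with ties counted one half; the
  bootstrap CI is a stratified percentile interval (2000 resamples,
  seeded). Metrics with zero denominators are reported as `NA`.
* SSIM uses the standard constants (k1 0.01, k2 0.03, 11-pixel Gaussian
  window, sigma 1.5) on the stated data range and averages the map over
  fully interior windows.
* PSNR on [0,1] montages uses data range 1; absolute PSNR/MSE values
  computed on 8-bit-scaled images are on a different scale and are not
  comparable.
* Determinism: a master seed drives everything; per-case seeds are derived
  by integer hashing (all below 2^31), cohort generation is a pure function
  of its arguments, and two pretraining runs with the same seed produce
  bit-identical checkpoints in single-threaded mode.

## Known limitations

* Pure-R training: practical up to the tiny preset; the full ViT-Large
  preset is provided for completeness but is not practical to train
  without GPU acceleration.
* The contrastive task on small cohorts is sensitive to dictionary size;
  instance discrimination over a few hundred near-duplicate lesions is
  intrinsically hard, and the hybrid loss's contrastive component can
  plateau well above its theoretical floor at smoke scale.
* The class-token representation after short pretraining is weak (a known
  property of masked-autoencoder pretraining); the standardised head and
  full fine-tuning compensate at smoke scale, but longer pretraining is the
  real remedy.
* Single nodule per volume, no detection stage: lesion anchors are assumed
  given, as in the annotated clinical workflow.
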