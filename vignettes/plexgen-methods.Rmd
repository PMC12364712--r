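---
title: "Generating protein multiplexes from H&E histology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating protein multiplexes from H&E histology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexgen)
```

## The problem

Multiplexed protein imaging (imaging mass cytometry and related technologies)
quantifies dozens of protein markers at ~1 µm resolution, but is slow,
expensive and restricted to small regions of interest. Routine H&E staining is
cheap and covers whole slides. `plexgen` implements a conditional generative
model that translates H&E tiles into multi-channel protein-marker images,
together with the full analysis pipeline around it: marker normalization,
serial-section registration, whole-slide tiled inference, image-quality
metrics, pseudo-cell analyses, immune phenotyping, and attention-based
multiple-instance learning (MIL) for patient-level outcome prediction.

A central property of the real data regime is that the H&E image and the
marker image come from *consecutive tissue sections*: they are structurally
aligned (after template matching) but never pixel-aligned. The training
objectives are chosen to be robust to this slice-to-slice displacement.

## The translator and its objectives

The translator G is a fully convolutional U-Net. The encoder has six
stride-2, kernel-3 convolution blocks (batch-norm + ReLU); the decoder has
five blocks with nearest-neighbour upsampling followed by a stride-1
convolution, with skip connections at matching resolutions. The H&E grid is
finer than the marker grid by an integer factor (default 4, mirroring
0.25 µm/px vs 1 µm/px), so the decoder contains one resolution-preserving
block and four upsampling blocks: six halvings in and four doublings out give
the net ÷4 from the H&E grid to the marker grid. Six-down/five-up with five
doublings would instead give ÷2, which is inconsistent with the ×4 resolution
factor; the resolution-preserving first decoder block is the minimal
reconciliation and is the one design point where the architecture description
had to be disambiguated. Each of the three output scales (full, 1/2, 1/4 of
the marker grid) has its own 3×3 convolution head with a sigmoid, because the
targets are min–max normalized to [0, 1].

The discriminator D is six conv → spectral-norm → ReLU blocks followed by a
spectral-normalized 1×1 convolution and a global mean, conditioned by
channel-concatenating the H&E tile average-pooled onto the marker grid.

Training optimizes, with weights `loss_weights()`:

* **Least-squares adversarial loss** (real = 1, fake = 0), averaged over the
  output scales; the single shared discriminator scores every scale after the
  lower-scale outputs are upsampled to the full marker grid. We use
  nearest-neighbour upsampling here so that the exact adjoint is available in
  the hand-written backward pass (a bilinear variant would behave
  equivalently at these scales).
* **Gaussian pyramid loss** (weight `lambda_gp = 5`): the L1 distance between
  per-octave primary layers of Gaussian pyramids of the target and the
  full-scale output. An octave applies `n_gs = 3` smoothings (σ = 1, separable
  zero-padded kernel); the next octave starts from the 2× decimation of the
  last smoothed image. Comparing at multiple resolutions relaxes the
  pixel-alignment assumption that a plain L1 loss would make — exactly the
  property needed for serial sections.
* **Patch-wise contrastive loss** (weight `lambda_contrast = 1`): each output
  channel is replicated into a pseudo-RGB image and embedded by a small fixed
  random conv encoder with per-layer projection heads. At 64 shared pixel
  locations per feature layer, the anchor (generated) is contrasted against
  its positive (target, same location) with the other locations' positives as
  negatives (InfoNCE, τ = 0.07, all features L2-normalized). Each term
  carries an adaptive weight
  `w_t = (1 − g(t/T)) + g(t/T)·h(sim(anchor, positive))` with a linear ramp
  `g(u) = u` and `h(u) = clamp((u+1)/2, 0, 1)`: early in training all patches
  count equally; later, patches that already agree with the target dominate,
  which tolerates locally displaced structures. The weight is treated as a
  constant during backpropagation. Several of these choices (octave count,
  per-octave weights, encoder, patch counts, τ, h, g) are not pinned down by
  any single reference configuration; the defaults above are standard practice
  and every one is a config field.
* **R1 gradient penalty** (weight `lambda_r1 = 1`) on the discriminator at
  real inputs: the batch mean of ‖∇_y D(y|x)‖². The discriminator is
  piecewise linear (convolutions + ReLU), so the parameter gradient of this
  penalty is computed by an exact adjoint sweep over the input-gradient graph
  with the ReLU masks frozen — exact almost everywhere, verified against
  finite differences in the test suite. Spectral normalization treats the
  power-iteration vectors as constants when differentiating, the standard
  practice.

Optimization is Adam (β₁ = 0.5, β₂ = 0.999) with learning rates 0.004 (G) and
0.0008 (D). The `"paper"` profile of `train_config()` carries the full-scale
settings (batch 16, 1024 px H&E / 256 px marker patches, 100 epochs); the
`"desk"` profile — batch 4, 128→32 px patches, width-8 translator, ~400 steps,
3 simulated markers — is the configuration all tests and the acceptance
script use, chosen so a complete training run takes under two minutes on one
CPU while still clearly separating a trained from an untrained model.
Augmentation applies flips and quarter rotations consistently to both images
and colour jitter to the H&E only.

### The discrete-time survival head and the risk score

For patient-level outcome prediction, slide patches form a bag; a gated
attention pooling `a_i = softmax(wᵀ(tanh(V h_i) ⊙ σ(U h_i)))`, `g = Σ a_i h_i`
aggregates patch features, and in the multimodal mode a co-attention layer
`Ĥ = Softmax(Q Kᵀ/√d) W_v H` aligns the two modalities in both directions
before pooling, concatenation and a linear projection back to dimension d.
Survival is modelled over quartile-based discrete time intervals with an
independent hazard logit per interval: `f_hazard(j) = sigmoid(ŷ_j)` and
`f_surv(j) = Π_{k≤j}(1 − f_hazard(k))`, trained with the standard
discrete-time negative log-likelihood (censoring coded `c = 0` when death is
observed). All three NLL terms enter with negative sign; a formulation in
which the censored terms enter positively would reward assigning censored
patients low survival probability and is not a likelihood.

The patient risk score is defined as `−Σ_j f_surv(j)`, the negated sum of the
survival function over intervals: high hazards depress the survival curve and
raise the risk, making risk concordant with shorter survival. The negated sum
of the *logits* is sometimes quoted as a risk score; with a hazard
parametrization it orders patients in exactly the opposite direction (we
verified this empirically: on a strongly planted effect it yields a
concordance index of ~0.3 where the survival-sum risk yields ~0.85), so
`survival_head()` reports it only as a reference field. Concordance is
evaluated with the IPCW (Uno-type) time-dependent estimator
(`survival::concordance` with `timewt = "n/G2"`); risk groups for the
Kaplan–Meier curves are split at the median risk, and group separation is
tested with the two-sample log-rank statistic.

## What the tissue simulator emulates — and what it does not

`simulate_paired_roi()` generates paired pseudo-H&E/marker ROIs with known
ground truth. Cells of six types (tumour, CD8 T, CD4 T, B, endothelial,
other) are placed uniformly; cell `i`'s expression of marker `m` is
`E[type_i, m] · s_i · u_im` with log-normal factors `s_i` (shared across
markers, sd 0.25) and `u_im` (independent, sd 0.25). The shared factor
induces a known positive co-expression structure within co-expressed marker
pairs whose population Spearman correlation can be computed independently by
Monte Carlo from the same law — this is the oracle used to validate the
co-localization analysis. Marker channels are rendered as sums of disks,
Gaussian-blurred (σ = 1), perturbed by additive truncated Gaussian noise
(clipping keeps the normalized range closed) and min–max scaled. The
pseudo-H&E renders nuclei as dark basophilic disks on an eosin-like textured
background at the fine grid, then applies a configurable affine jitter whose
exact inverse is stored — emulating slice-to-slice displacement with known
ground truth. Region masks (tumour centre by erosion of the tumour-density
support — the desk-scale analogue of excluding a 500 µm margin from the
tumour boundary — split into intratumoral and stromal compartments by a
density threshold) support the immune-phenotyping pipeline.

The simulator is deliberately stylized: it has no stain physics, no nuclear
morphology differences between cell types beyond position, no tissue
architecture (vessels, stroma textures), and its misalignment is affine
rather than elastic. Passing tests therefore demonstrate that the
implementation is correct and that the pipeline recovers planted structure;
they do not demonstrate performance on real histology, which depends on
morphological signal the simulator does not model.

`simulate_survival_cohort()` embeds a latent patient risk (`effect_size × s`,
`s ~ N(0,1)`) into the first few feature dimensions of every instance of both
modality bags; event times are exponential with rate `exp(risk)`, censoring
is independent with configurable probability, and bins are observed-time
quartiles. With `effect_size = 0` the features are pure noise and held-out
concordance must hover at 1/2; the acceptance suite uses `effect_size = 4` as
its "strong signal" condition, where the concordance ceiling of the true risk
(~0.89 under 20% censoring) leaves clear headroom above the 0.8 bar.

## Numerical choices and degenerate inputs

* Convolutions are im2col + GEMM in C++ (RcppArmadillo); all forward/backward
  pairs are exact adjoints, verified by finite differences. Computation is
  double precision and single-threaded: a fixed seed reproduces results
  bitwise.
* Batch-norm uses batch statistics in training and running averages
  (momentum 0.1, ε = 1e−5) at inference. Constant channels in the marker
  normalization skip standardization with a warning instead of producing NaN.
* Otsu thresholding maximizes between-class variance exhaustively over all
  unique values (up to 256 histogram bins for continuous data); ties take the
  smallest threshold; constant images are an error. The background threshold
  for marker normalization is computed per sample on channels pre-smoothed
  with a kernel-3, σ = 3 Gaussian, after the arcsinh transform by default
  (`otsu_on = "raw"` is available, since the processing order leaves this
  genuinely open).
* Template matching searches integer translations (default ±25% of the image)
  and a discrete rotation set ({0°, ±90°, 180°} plus a fine ±5° sweep) for
  the maximum of the mutual information of a 32×32-bin joint histogram over
  the overlap; candidates with too little overlap are skipped.
* Macenko stain normalization estimates the stain plane by eigendecomposition
  of the OD covariance; the plane basis is oriented so projections stay away
  from the atan2 branch cut before taking robust (1%/99%) angle percentiles —
  without this, tiles whose projections straddle ±π get a collapsed basis.
  Near-white tiles are returned unchanged with a warning.
* MS-SSIM uses the standard five-scale weights, C₁ = (0.01 L)², C₂ = (0.03 L)²,
  and an 11×11 Gaussian window (σ 1.5); at M = 1 it reduces exactly to classic
  SSIM (which may be negative), while the multiscale product clamps negative
  per-scale values at zero so fractional exponents stay defined. Identical
  images give PSNR = +∞, reported as `Inf`.
* Spearman co-localization uses average ranks on ties, skips (and logs)
  constant marker/ROI combinations, and retains pairs with |average GT SCC|
  above 0.15. It operates on pseudo-cell means by default; any
  observation × marker matrix (e.g. flattened pixels) can be passed for a
  pixel-level analysis.
* Tile coordinates are 0-based with half-open `[x, x + size)` intervals in
  level-0 pixel units everywhere, including the persisted CSV. Stitching with
  zero overlap is exact (byte-equal to direct whole-image computation for
  local models); optional overlap uses linear feather blending. A cell
  belongs to the compartment containing its rounded centre pixel.
* The cell typer is a random forest with 100 trees and maximum depth 30
  (`ranger`), with out-of-bag error exposed; the hot/cold classifier uses
  stratified 5-fold cross-validation and reports F1 and AUROC as mean ± sd.
* Quartile time bins come from the training split only; test times beyond the
  last cut clamp into the last bin; a time exactly at a cut point belongs to
  the right bin.

## Known limitations

* The contrastive encoder is a fixed random network. The interface accepts
  any encoder with the same forward contract, but no pretrained pathology
  encoder ships with the package.
* Whole-slide inference holds the stitched output in memory; slides far
  beyond ~10⁹ pixels per channel would need a chunked writer.
* The spatial-heterogeneity (HTA) index sometimes reported alongside immune
  phenotyping has no published formula to implement against and is omitted.
* Bitwise reproducibility assumes single-threaded BLAS; multi-threaded GEMM
  may reorder floating-point sums.

## Problem sizes used by tests and the acceptance script

Desk-scale conditions were fixed once, up front: simulator canvas 96 px
(marker grid) with 120 cells for training ROIs; 4 training ROIs and 1
held-out ROI; 400 training steps at batch 4 with a width-8 translator and 3
markers; co-localization recovery on 20 ROIs × 2000 cells against a
200,000-sample Monte Carlo population value; registration on 20 planted
rigid transforms; survival cohorts of 150 patients (bags of 16 instances of
dimension 16) with a 60-patient held-out split, 3 seeds per condition.
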