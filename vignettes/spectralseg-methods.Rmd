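---
title: "Segmenting brain tissue from multi-energy CT: models, phantoms and evaluation"
author: "spectralseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting brain tissue from multi-energy CT: models, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dual-layer (detector-based dual-energy) CT can synthesize virtual
monoenergetic images (VMIs) at any keV from one acquisition. Attenuation of
— and contrast between — white matter (WM), gray matter (GM) and
cerebrospinal fluid (CSF) varies with the VMI energy: soft-tissue contrast
is highest at low keV where noise is also highest, while at high keV both
contrast and noise flatten out. `spectralseg` implements a family of 2D
convolutional segmentation models that exploit this spectral axis — a
single-level baseline, a spectral-augmentation training strategy (Aug),
per-level input pathways fused by concatenation (Fuse), and Fuse plus an
additive attention gate on the top skip connection (Gated) — together with
the complete training and evaluation stack around them: a class-masked Dice
loss, K-fold cross-validation with fold-ensemble inference, and DSC / HD95 /
volume-difference statistics.

Because no patient data ship with the package, a synthetic head-phantom
cohort generator stands in for the clinical cohort. It is first-class,
tested code: the whole pipeline runs end to end on phantoms.

## The phantom cohort

A phantom is a nested set of ellipsoids, outside-in: background, a CSF
shell, a GM ribbon, a WM core, and a ventricular CSF ellipsoid inside the
core. Tissue interfaces are concentric ellipsoids whose semi-axes are the
head semi-axes minus the cumulative layer thicknesses, so layer thicknesses
are exact along the principal axes and analytic volumes are available for
testing. The GM/WM interface is additionally perturbed radially by

$$\Delta(\theta,\phi) = A\,\cos(f\phi + \phi_0)\,\sin\theta$$

with amplitude $A$ (mm), frequency $f$ (cycles per revolution) and a
seed-drawn phase $\phi_0$. This "cortical folding" is deliberately not
anatomical: its purpose is to create a thin, convoluted ribbon whose
boundary dominates the overlap metrics, the regime where segmentation
models actually differ. The $\sin\theta$ factor tapers the perturbation at
the poles where the azimuth is undefined.

Rendering maps each class to a mean attenuation from a per-level HU table
and adds independent zero-mean Gaussian noise per level. The defaults
(70 keV: CSF 9, WM 29, GM 38 HU; 50 keV: 7/31/44; 120 keV: 10/28/34; noise
SD 6/4/3 HU at 50/70/120 keV) encode the two trends the models are designed
around — GM–WM contrast strictly decreasing and noise strictly decreasing
with keV — and are enforced as validity invariants of `SpectralModel`, not
just defaults. The absolute values are plausible brain-window numbers chosen
once for this package; they are configurable and nothing downstream depends
on them beyond the invariants.

What the phantoms do *not* emulate: partial-volume averaging (labels are
crisp and voxel intensities are class mean + noise, so intensity is fully
informative about the label), beam hardening and artifacts, anatomical
variability beyond affine jitter, and skull/bone (background directly abuts
the CSF shell, since only intracranial classes are segmented). Passing the
phantom-recovery tests therefore demonstrates that the architecture, loss,
training loop and ensemble machinery work — not clinical-grade performance
on patient data, which requires the co-registered MR-derived ground truth
the original study used.

Per-case geometry jitter (uniform ±10% on every length by default) creates
the inter-case variance that cross-validation folds and the leave-one-out
jackknife act on.

```{r}
library(spectralseg)
manifest <- generateCohort(10, "cohort/", seed = 7)
case <- loadCase(manifest, "case_001")
case$stack    # 50/70/120 keV HU volumes
case$labels   # 0 background, 1 WM, 2 GM, 3 CSF
```

## Input layout

Models see 2D axial slices with pseudo-3D context: the slice of interest
plus its neighbors as channels (k = 3 total, center ±1; out-of-range
neighbors are filled by edge replication rather than zero padding, which
would inject a spurious intensity step at the first and last slices).
Intensities are windowed to (0, 100) HU — covering the CSF–GM range — and
mapped affinely to [0, 1].

Channel order is fixed and level-major: for the Fuse/Gated variants the
9 channels are the 50-keV triplet, then 70, then 120, slices running
inferior to superior within a level. The Fuse pathway split is only
well-defined because this order is pinned. Baseline and Aug consume a
single level (3 channels); at test time both use 70 keV, the level that
most closely resembles a conventional polyenergetic image.

## Architectures

Both backbones are built from two-convolution blocks (3×3, instance
normalization, then the backbone's activation — PReLU for U-Net, LeakyReLU
for U-Net++), 2×2 max-pool downsampling, 2×2 stride-2 transposed-convolution
upsampling, and a 1×1 softmax head over the four classes. U-Net++ nests
dense skip decoders: node $X^{i,j}$ receives all previous nodes of its row
plus the upsampled $X^{i+1,j-1}$; deep supervision is off and the final
nested node is the sole output, which keeps ensemble averaging well-defined.

The default channel plans are a doubling encoder (16, 32, 64, 128) with a
widened bottleneck — 448 for U-Net and 304 for U-Net++ — sized so the
default models carry 3.5 M and 2.6 M trainable parameters respectively,
matching the published model sizes; `countParameters()` gives the exact
count. Inputs not divisible by $2^{\text{depth}-1}$ are reflect-padded up
and the output cropped back, so phantom grids are not constrained by the
backbone.

The Fuse input block runs one 3×3 convolution + activation + instance
normalization per VMI level and concatenates the three pathway outputs
(3 × `pathwayWidth` channels) into the first encoder block. One design
note: the figure caption of the original describes batch normalization in
these pathways while the text prescribes instance normalization for all
models; instance normalization is used everywhere here, taking the explicit
global statement as authoritative.

The attention gate is additive (Oktay-style): coefficients
$\alpha = \sigma(\psi(\mathrm{ReLU}(\theta_x x + \phi_g g)))$ from 1×1
projections of the skip features and the gating signal (the last
up-convolution output), with $\alpha$ multiplying the skip features
per position. If the gating signal's spatial size ever differs from the
skip's, it is resampled bilinearly. On U-Net the gate sits between the last
up-convolution and the top skip connection. The original study gates only
the U-Net; for completeness `spectralseg` also admits a gated U-Net++,
gating the concatenated top-row skips feeding the final nested node — the
closest structural analogue of "the top skip connection" in a nested
decoder. Clamping $\alpha \equiv 1$ (via `gateOverride`) reduces Gated to
Fuse exactly, a property the tests exercise.

### The numerical engine

No deep-learning framework is used: the package carries a small
reverse-mode automatic-differentiation tape over (x, y, channel, batch)
arrays, with convolution, transposed-convolution and pooling kernels in
C++ (im2col + BLAS GEMM). Every operator's gradient is validated against
central finite differences in the test suite, end to end through the Dice
loss, for all four variant topologies.

## Training

The loss is a class-masked multi-class soft Dice: per class $c$ present in
the batch,

$$\ell_c = 1 - \frac{2\sum p_c t_c + s}{\sum p_c + \sum t_c + s},$$

and the loss is the mean of $\ell_c$ over *present* classes only. Presence
is decided per batch (any positive target pixel); absent classes contribute
nothing to the value or the gradient — without this, early batches that
happen to lack a class (CSF, typically) push its predictions toward zero.
Background is a class like any other (C = 4), subject to the same masking.
The smoothing term $s = 10^{-5}$ appears symmetrically in numerator and
denominator so a perfect prediction scores (essentially) zero loss.

Cases are partitioned once into K folds (default 7) whose sizes differ by
at most one; the assignment is a deterministic function of the seed and is
reused across model variants. Per epoch the Aug strategy visits every
(case, slice, level) triple — three times the slice count — while baseline
visits each slice once at 70 keV and Fuse/Gated once with all levels packed
into one 9-channel sample. The optimizer is Adam at learning rate $10^{-3}$
with batch size 8; the original study specifies none of these, so they are
package defaults exposed in `trainConfig()`. There is no early stopping or
schedule; the study protocol is a flat 100 epochs, and the desk-scale
defaults simply shorten that.

## Inference and evaluation

A volume is predicted slice by slice and reassembled; the final
segmentation of a case averages the post-softmax probability volumes of the
K fold checkpoints voxel-wise (averaging probabilities rather than logits
is the plain reading of "averaging the outputs"; it is also idempotent and
order-invariant) and takes the per-voxel argmax, ties broken toward the
lowest class code for reproducibility. No post-processing (no
largest-component filtering or hole filling) is applied.

Metrics are reported for WM, GM and CSF (background excluded):

* **DSC** $= 2|A\cap B| / (|A| + |B|)$, defined as 1 when both masks are
  empty.
* **HD95**: border voxels are mask voxels with a face-adjacent (6-connected)
  non-mask neighbor; both directed nearest-neighbor border-to-border
  distance sets are computed in mm and *pooled*, and the 95th percentile
  (linear interpolation between order statistics) of the pooled set is
  reported. Pooling keeps the metric symmetric, mirroring the symmetric
  definition that the percentile replaces. An empty mask makes the metric
  undefined; it is recorded as missing, never as zero.
* **AVD** $= (V_{GT} - V_M)/V_{GT} \times 100\%$, signed per class
  (negative = overestimation); the per-class mean of $|AVD|$ and its grand
  mean summarize volumetric accuracy, and Bland–Altman points pair the
  signed AVD with the mean of the two volumes.

Uncertainty uses delete-one resampling over test cases — with five test
iterations each excluding one case, the described "leave-one-out
bootstrapping" is read literally as the jackknife — with the
normal-approximation interval $\bar x \pm z_{0.975}\,\widehat{SE}_{jack}$.
Model comparison uses Welch's unequal-variance t-test (two-sided, since the
question is directionless) with Bonferroni correction ×7, the number of
compared models, capped at 1.

## Problem sizes and numerical choices

The package's own validation runs at desk scale, chosen once: the
end-to-end recovery study uses 10 phantom cases on 64×64×32 grids at 3 mm
spacing, a narrow U-Net++ (widths 4, 8, 16) trained with the Aug strategy
for 10 epochs on 3 folds over 8 cases, and evaluates the fold ensemble on
the 2 held-out cases; the tiny smoke experiment in `runExperiment()`'s
defaults is smaller still (32×32×16 at 6 mm, 2 folds). The study-scale
protocol (7 folds, 100 epochs, full widths) is reachable purely through
configuration.

Remaining numerical conventions, pinned for reproducibility: percentiles
use linear interpolation (R type 7); weight initialization is He-normal
with a seed derived from the config seed; every stage of `runExperiment()`
derives its seed deterministically from the global seed and logs it;
degenerate inputs (empty masks, zero ground-truth volume, a batch with no
present class, geometry that collapses a tissue to zero voxels) raise
explicit errors rather than returning sentinel values.

## Known limitations

* Phantoms are intensity-separable by construction; real CT tissue
  boundaries carry partial-volume ambiguity the models never see here.
* Soft-Dice training has a well-known slow-start regime: until the
  optimizer routes probability mass to a small class, that class's Dice
  term barely moves, so at desk-scale epoch counts convergence speed varies
  noticeably with the weight initialization — some seeds reach high DSC for
  all classes within 10 epochs, others are still emerging from the
  two-class regime (background + WM) and need more epochs. The class
  masking removes the *absent-class* failure mode but not this one; the
  study protocol's 100 epochs make the distinction moot. The package's
  recovery study pins its seeds for exactly this reason.
* The generative dual-decoder variant and external comparators of the
  original study are out of scope, as are 3D (full-volume) convolutions
  and pretrained weights.
* The clinical headline numbers of the original study are computed on
  patient CT+MR data and are not reproducible from phantoms; this package
  reproduces the *machinery* (architectures at their published sizes, loss,
  ensemble, metrics and statistics), validated by oracle agreement and
  phantom recovery.
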