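---
title: "Attention-augmented CNN classification of whole-body scintigrams: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-augmented CNN classification of whole-body scintigrams: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
pieces look the way they do. It covers the image model, the network and its
attention block, the augmentation and evaluation protocol, the synthetic
phantom that stands in for restricted clinical data, and the numerical and
design choices a maintainer would want to know about.

## The image model

A whole-body planar scintigram is a matrix of radiotracer counts on a
256-column × 1024-row grid with 2.26 mm pixels, each entry a 16-bit unsigned
integer. We fix the orientation convention as rows = 1024 (superior →
inferior) and columns = 256 (patient-left → right in the anterior view);
the acquisition literature quotes the grid as 256 × 1024 without fixing
axis order, and transposing would change every derived feature-map shape,
so the convention is asserted everywhere. Each examination produces an
anterior and a posterior view; occasionally one view is missing.
`scinti_image` carries the pixel matrix plus patient id, view, class label,
pixel size, provenance, and an optional block-sum `downscale` factor.
Block *summation* (not averaging) is used for downscaling because it
preserves total counts and keeps Poisson statistics Poisson.

Counts are Poisson distributed, so acquisition applies a mild Gaussian
correction (kernel 3, sigma 1/3 px). Clinical DICOMs arrive already
corrected; `gaussian_correct()` exists for raw phantom output and is
implemented as a normalized convolution so constant images are preserved
exactly, including at borders.

**Intensity normalization.** Nothing in the acquisition fixes a count scale,
and global uptake varies strongly between patients. We therefore normalize
each image by its own maximum (`pixels / max(pixels)`), mapping into [0, 1]
with max exactly 1. A fixed 1/65535 scale would leave the patient-to-patient
scale variation for the network to absorb; per-image max scaling removes it
at the cost of coupling the scale to the hottest pixel, which is acceptable
because hotspots are precisely what the classes are about. All-zero scans
degrade to an all-zero map with a warning.

## Network

The classifier has exactly eight weight layers — five convolutions, two
1024-unit fully connected layers, and the final 4-way affine feeding
softmax. Batchnorm stages (after the second and fifth convolutions) and the
attention gates are parameterized but are not counted as weight layers;
this is the only counting that makes the stack "eight layers" — counting
the softmax head's affine separately gives 8, reading "Softmax 4" as a bare
activation would give 7. All spatial arithmetic is
`floor((n + 2p − k)/s) + 1`; on the native 1×1024×256 input the feature
maps run 16×255×63 → 16×127×31 → (attention) → 16×127×31 → 16×63×15 →
24×63×15 (three convs) → 24×61×13 → flatten 19032 → 1024 → 1024 → 4, and
`network_shapes()` derives this table for any input grid. The smallest
admissible grid is 256×64 (below that the final pooling window no longer
fits).

Choices the architecture description leaves open, and what we did:

- **Activation**: ReLU after every convolution and FC layer (the comparison
  models in the same experimental protocol all use it); configurable.
- **Loss**: categorical cross-entropy on the softmax output — the standard
  pairing; the softmax itself is computed with max-subtraction so ±1000
  logits are safe.
- **Batchnorm**: batch statistics in training (per mini-batch), running
  averages (momentum 0.1, eps 1e-5) in eval mode; eval-mode inference is
  therefore deterministic.
- **Conv → batchnorm → ReLU** ordering where batchnorm is present.
- **No dropout** (never part of the design).
- **Initialization**: He-normal, seeded; two builds from one seed are
  bit-identical.

## The hybrid attention block

After the first pooling layer a cascaded channel/spatial attention module
re-weights the 16-channel feature map. The channel gate squeezes each
channel by average- and max-pooling over space, passes both descriptors
through a *shared* two-layer MLP and takes `σ(MLP(avg) + MLP(max))`; the
spatial gate stacks the channel-wise mean and max maps and convolves them
with a k×k kernel into `σ(conv([avg; max]))`. The printed composition of
the two gates is typographically ambiguous about whether the spatial gate
sees the original map or the channel-refined one; we implement the standard
cascade from the attention-module literature — `F′ = g_c(F) ⊗ F`, then
`M = g_s(F′) ⊗ F′` — and expose the alternative (`spatial_on_original`) as
an ablation flag. Unstated hyperparameters: reduction ratio 4 (hidden width
4 at the 16-channel insertion point — a nondegenerate bottleneck), spatial
kernel k = 7 (the usual convention), ReLU inside the MLP. All are
config-exposed.

Useful consequences, all tested: zero-initialized parameters make both
gates exactly 0.5, so the block scales its input by exactly 0.25; gates lie
strictly in (0, 1), so attention strictly attenuates nonzero activations;
the channel gate is invariant to spatial permutations and the spatial gate
equivariant to channel permutations; gradients flow to every parameter
(finite-difference checked).

## Augmentation

Three parametric operators, all preserving dtype range, dimensions, patient
id and label:

- `mirror_image()` — reverse columns about the vertical centerline and
  toggle the view flag (an anterior view's mirror plays the role of its
  missing posterior); an involution.
- `translate_image(t, axis)` — integer shift with zero fill (counts do not
  exist outside the detector; reflection or wrap would fabricate them).
- `rotate_image(r)` — rotation about the pixel-grid center
  ((H−1)/2, (W−1)/2) with bilinear interpolation, zero fill, and rounding
  back to integer counts; nearest-neighbor available for exactness-sensitive
  uses.

The translation and rotation bounds are stated as experimentally chosen in
the source protocol without values; we default to t_max = 10 px and
r_max = 5°, small enough that phantom anatomy stays inside the frame, and
both are config-exposed. `augment_cohort()` first completes missing views
by mirroring (mirroring is restricted to that purpose — its stated role —
rather than used as a general augmentation), then tops each class up to its
target count by cycling round-robin over the class's source images, drawing
one uniform random variant per pass (operator fair coin; t uniform on
integers [−t_max, t_max]; r uniform on [−r_max, r_max]). Rebalancing the
reference class counts (334, 174, 252, 318) to targets
(1660, 1582, 1500, 1788) reproduces those targets exactly and lowers the
max/min class ratio from 1.92 to 1.19. Augmented images inherit their
source's patient id, which is what makes the later split leak-free.

## The phantom generator

The clinical cohort is access-restricted, so the package ships a synthetic
stand-in whose *discriminative structure* matches what the classifier must
exploit; it makes no attempt at physical projection or isotope modelling.
A deterministic procedural template (built in code, never stored) provides
a body silhouette, a skeleton of capsules and ellipses, 12 joint sites in 6
bilateral pairs, and a 12×12-pixel neck box on the midline sized like the
thyroid bed (~2.7 cm at 2.26 mm/px). Expected counts are b_body = 5 in soft
tissue and b_bone = 20 on bone — low-count planar levels at which Poisson
noise is material. Lesions are isotropic Gaussian bumps (sigma 4 px) with
amplitude a·b_bone, a ~ U(2, 4):

- normal — no lesions;
- metastasis — 1–5 sites uniform on the skeleton;
- arthritis — 1–3 joint sites, each mirror partner co-affected with
  probability 0.6;
- thyroid carcinoma — exactly one site uniform in the neck box.

Every diseased class draws amplitudes from the same distribution, so
intensity alone cannot separate diseases — placement must. Physiologic
artifacts (injection-site uptake at a wrist/elbow, bladder activity at the
pelvis midline) appear in any class with probability 0.3, so "has a
hotspot" is not a shortcut for "diseased". Posterior views are mirrored
geometry with a 0.9 attenuation factor and independent noise — a deliberate
simplification of real anterior/posterior differences. Posterior views are
missing with probability 0.1. Pixels are Poisson draws from the expected
map (dispersion index verified ≈ 1).

Two properties make the benchmark honest: (1) a trivial hand-crafted
detector — neck-box mean over bone-mask mean, thresholded at 1.5 — already
separates thyroid carcinoma from normal on ≥95% of phantoms, so the task is
learnable before any CNN enters; (2) the class-hardness ordering is built
in structurally: thyroid carcinoma is easiest (fixed location), arthritis
and metastasis are hardest (their placement distributions overlap on the
skeleton). What passing tests on phantoms does *not* show: robustness to
real anatomy variation, scanner artifacts beyond the two modelled ones,
age-dependent uptake, or multi-disease images.

## Protocol

`split_by_patient()` shuffles patients (stratified by class) under a seed
and assigns a per-class prefix so the train image fraction lands as close
to the 7:3 target as patient granularity allows; no patient's images ever
straddle the split, and `run_benchmark()` re-asserts this after
augmentation. Training follows the reference hyperparameters (learning rate
10⁻³, weight decay 10⁻⁴, batch 4; 300 epochs as the documented default).
The optimizer is Adam — named for every comparison model in the source
protocol though not for the main network itself — with weight decay applied
decoupled from the gradient and only to weight matrices; plain SGD is a
flag. The quoted "Epoch 300 / Iteration 1200" pair is internally
inconsistent with batch size 4 on thousands of images; epochs are treated
as authoritative.

The protocol's "run 10 times to reduce the effects of randomness" is
incoherent for deterministic eval-mode inference; `evaluate_runs()`
therefore interprets it as 10 independent train+evaluate repetitions with
consecutive seeds on a fixed split (`mode = "retrain"`), with a literal
repeat-inference mode (`"reinfer"`) kept for completeness.

Metrics: one-vs-rest TP/FN/FP/TN per class; accuracy, precision, recall,
specificity, F-1 per class; macro values are unweighted class means. Macro
F-1 is the mean of per-class F-1 — the printed headline F-1 in the source
protocol is consistent with that definition and inconsistent with the
harmonic combination of macro precision/recall, which is why we fixed this
reading. Per-class accuracy uses the one-vs-rest TN, the only reading that
makes accuracy class-decomposable. Zero-denominator conventions: undefined
rates are NA and excluded from macros; F-1 is 0 when precision or recall is
undefined or both are zero. ROC curves sweep thresholds over unique scores
with ±∞ endpoints so they run from (0,0) to (1,1); the trapezoid AUC equals
the tie-corrected pairwise rank statistic exactly, and both per-class and
macro AUC are emitted (whether the single published ROC per model was
micro- or macro-averaged is unstated; macro is our headline).

## Problem sizes and the reference benchmark

The package's reference validation (`benchmark_profile()`, used by
`scripts/acceptance.R` and the acceptance test) is 100 phantom patients per
class, 7:3 patient split, 20 epochs at batch 4 — roughly 760 images, ~530
of them training — on 512×128 inputs (block-sum factor 2, shapes re-derived
by the same convolution formula). These sizes were chosen so a full run
completes in about ten minutes on one CPU while leaving the learning
problem non-trivial; the native-resolution path and the full 300-epoch
defaults remain available. On this profile the held-out macro accuracy
exceeds 0.9 and the per-class F-1 ordering reproduces the structural
hardness ordering (thyroid ≥ arthritis). Training on the ~530-image profile
takes ~0.2 s per batch; a forward pass at native resolution takes ~0.2 s.

## Numerical notes and limitations

- Convolution is im2col + GEMM in C++ (double precision); eval-mode
  inference is bit-reproducible on a given platform, and training is
  deterministic given the seed up to platform BLAS rounding.
- Max-pooling records argmax indices for exact backprop; ties break to the
  first (column-major) element.
- Gradients of the full stack, including both attention gates and
  batchnorm, are validated against central finite differences.
- The DICOM layer writes and reads a minimal Explicit-VR-little-endian
  Secondary Capture object (single-frame 16-bit monochrome), round-trips
  bit-exactly, and is cross-checked against an independent Python reader in
  the test suite. It is not a general DICOM implementation: no multi-frame,
  compressed transfer syntaxes, or vendor private tags.
- Checkpoints (`save_checkpoint`/`load_checkpoint`) are RDS files holding
  spec + parameters + batchnorm state; a reloaded model reproduces
  evaluation metrics exactly.
- Annotations use the LabelMe JSON dialect; an image is positive only under
  a ≥2-of-3 annotator majority. Annotation ingestion is provided for
  ground-truth bookkeeping; the classifier itself consumes only image-level
  labels (multi-disease, multi-lesion classification is out of scope).
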