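# dscint

Multiclass classification of whole-body bone scintigrams with an
attention-augmented convolutional neural network, in pure R.

## The problem

Whole-body planar bone scintigraphy (⁹⁹ᵐTc-MDP bone scan, or ¹³¹I whole-body
scan after thyroidectomy) records radiotracer counts on a 256 × 1024 detector
grid (2.26 mm pixels, 16-bit counts). Nuclear-medicine readers must decide
whether a scan is normal or shows bone metastasis, arthritis, or thyroid
carcinoma — classes that differ mainly in *where* hotspots occur: metastases
anywhere on the skeleton, arthritis at joints (often symmetrically), thyroid
carcinoma at one fixed neck location. `dscint` implements an automated
4-way classifier for this task, aimed at researchers in medical image
analysis who want a self-contained, inspectable reference pipeline.

## The model

The classifier is an eight-weight-layer CNN:

```
conv 11×11×16, s=4, p=2 → maxpool 3, s=2 → hybrid attention
→ conv 5×5×16, s=1, p=2 → batchnorm → maxpool 3, s=2
→ (conv 3×3×24, s=1, p=1) × 3 → batchnorm → maxpool 3, s=1
→ FC 1024 → FC 1024 → affine 4 → softmax
```

with ReLU after every convolution/FC layer. The hybrid attention block after
the first pooling layer re-weights feature maps `F` in cascade:

- channel gate ("what"): `g_c = σ(MLP(AvgPool(F)) + MLP(MaxPool(F)))`, the
  pooling collapsing each channel to a scalar and the two branches sharing
  one bottleneck MLP;
- spatial gate ("where"): `g_s = σ(conv_{7×7}([mean_c(F′); max_c(F′)]))` on
  the channel-refined map `F′ = g_c ⊗ F`;
- output `M = g_s ⊗ F′`.

Training is mini-batch cross-entropy with Adam (learning rate 10⁻³, decoupled
weight decay 10⁻⁴, batch size 4). Evaluation is one-vs-rest accuracy,
precision, recall, specificity, F-1 (macro = unweighted class mean) plus
per-class ROC/AUC, computed from a 4×4 confusion matrix. Train/test splits
are grouped by patient so correlated views and augmented derivatives never
straddle the split.

Because the clinical dataset behind this design is access-restricted, the
package ships a synthetic phantom generator: a procedural body/skeleton
template, class-conditional Gaussian hotspots (same amplitude distribution
in every diseased class, so placement — not intensity — is what must be
learned), physiologic artifacts (injection site, bladder), anterior +
attenuated mirrored posterior views with occasional missing posteriors, and
Poisson counting noise.

Everything is implemented in R with small Rcpp/RcppArmadillo kernels for
convolution, pooling and the optimizer step; no deep-learning framework is
required.

## A worked example

```r
library(dscint)

# 20 phantom patients per class, 2x downscaled to 512 x 128
cohort <- generate_cohort(phantom_config(n_per_class = 20, seed = 42),
                          downscale = 2L)
split  <- split_by_patient(cohort$manifest, ratio = 0.7, seed = 1)
side   <- split$assignment[cohort$manifest$patient_id]

fit <- dscint(cohort$images[side == "train"],
              control = dscint_control(epochs = 20, seed = 1))
print(fit)
#> Scintigram classifier (8 weight layers, attention on)
#>   trained on 103 images for 20 epochs (97.0 s)
#>   final training loss 0.1668, accuracy 0.913

ev <- evaluate_model(fit, cohort$images[side == "test"])
print(ev$report)
#> per-class (one-vs-rest):
#>                   accuracy precision recall specificity     f1
#> normal              0.9348    0.8000 1.0000      0.9118 0.8889
#> metastasis          0.7826    0.5385 0.6364      0.8286 0.5833
#> arthritis           0.8043    0.6667 0.3636      0.9429 0.4706
#> thyroid_carcinoma   1.0000    1.0000 1.0000      1.0000 1.0000
#> macro:  accuracy 0.8804, precision 0.7513, recall 0.7500, specificity 0.9208, f1 0.7357
#> pooled accuracy: 0.7609
```

Twenty patients per class are already enough for the structurally easy
classes: thyroid carcinoma (one fixed lesion location) is classified
perfectly and normal scans nearly so, while metastasis and arthritis —
whose lesion placements overlap on the skeleton — are still confused with
each other. The reference profile below (100 patients/class, 20 epochs)
lifts held-out macro accuracy above 0.95 and per-class F-1 above 0.90
everywhere, with the same easiest-to-hardest ordering.

Single images round-trip through DICOM:

```r
f <- tempfile(fileext = ".dcm")
write_scinti_dicom(cohort$images[[1]], f)
img <- read_scinti_dicom(f)          # bit-identical counts
probs <- predict(fit, img)           # 1 x 4 probability matrix
```

A thin CLI wrapping the same functions lives at `inst/cli/dscint.R`
(`generate`, `augment`, `predict`, `run` subcommands).

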