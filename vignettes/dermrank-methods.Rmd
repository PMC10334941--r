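---
title: "Knowledge-integrated semisupervised lesion classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-integrated semisupervised lesion classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dermoscopic triage of pigmented lesions often relies on the 3-point
checklist: a lesion scores one point for each of *asymmetry*, *atypical
pigment network*, and *blue-white structures*, and a score of 2 or more
suggests malignancy.  `dermrank` trains a convolutional classifier that
(i) predicts melanoma versus melanocytic nevus, (ii) predicts the three
checklist features, and (iii) is constrained during training to respect
the checklist rule itself — images with higher checklist scores should
receive higher melanoma logits.  A mean-teacher consistency term lets a
large pool of images that carry only a disease label contribute.

Everything is exercised end to end on a synthetic lesion generator whose
three visual cues are embedded programmatically, so the whole method is
testable without clinical images.

## The objective

One shared convolutional trunk feeds two heads: a 2-way softmax disease
head and a 3-way independent-sigmoid feature head.  Four loss terms are
combined as a weighted sum
$L = \lambda_{dsl} L_{dsl} + \lambda_{fsl} L_{fsl} + \lambda_{rl} L_{rl}
+ \lambda_{cl} L_{cl}$:

* **Disease supervised loss (DSL).** Mean softmax cross-entropy of the
  disease head.
* **Feature supervised loss (FSL).** Weighted mean over features of the
  per-feature mean sigmoid binary cross-entropy.  The per-feature weights
  are normalized to sum to 3 so `c(1, 1, 1)` is the plain mean; raising
  one weight (e.g. `c(2, 1, 1)`) emphasizes that feature, the axis probed
  by the asymmetry-weighted ablation row.
* **Ranking loss (RL).** For every unordered pair $(i, j)$ in a batch,
  with checklist scores $s_i, s_j$ and melanoma logits $f_i, f_j$, define
  $o_{ij} = f_i - f_j$ and the sigmoid posterior
  $P_{ij} = 1/(1 + e^{-o_{ij}})$.  The target $\bar P_{ij}$ is 1 if
  $s_i > s_j$, 0 if $s_i < s_j$, and $1/2$ on ties.  The pair
  cross-entropy is evaluated in the numerically stable rewritten form
  $C_{ij} = -\bar P_{ij}\, o_{ij} + \log(1 + e^{o_{ij}})$ and averaged
  over pairs.  Ties are kept (a pair of equal scores pulls the two logits
  together); the mean (rather than sum) over pairs keeps
  $\lambda_{rl}$ comparable across batch sizes.  The loss depends only on
  logit differences, so it is invariant to a common shift of all
  melanoma logits.
* **Consistency loss (CL).** Mean squared difference between the
  student's and the teacher's predicted distributions — the disease
  softmax and the three feature sigmoids concatenated (a disease-only
  mode is provided, since the source description leaves the coverage of
  the feature head open).  The teacher is an exponential moving average
  (EMA) of the student, $\theta' \leftarrow \alpha\theta' +
  (1-\alpha)\theta$ after every optimizer step, receives no gradients,
  and sees an independently perturbed view of each batch.

Terms with zero weight are skipped entirely, so a disabled loss never
requires its labels; every row of the loss-ablation grid (CL, DSL, FSL,
FSL+CL, DSL+FSL, DSL+CL, DSL+FSL+CL, asymmetry-weighted) is expressible
as a `loss_weights()` configuration.

## Preprocessing chain

Three stages, in order, each individually switchable:

1. **Center crop + resize.**  The largest centered square crop, then
   bilinear resampling to the target size.  The centered-square rule is a
   deliberate choice: dermoscopic framing usually centers the lesion, and
   the rule is deterministic.  A bounding-box crop mode was considered
   and left out.
2. **Shades of Gray color constancy.**  The illuminant is estimated per
   channel as the Minkowski mean $e_c = (\mathrm{mean}(I_c^p))^{1/p}$,
   normalized to unit L2 norm; the returned gains map it to neutral gray
   (a gray image yields gains of exactly 1).  $p = 1$ reduces to Gray
   World and large $p$ approaches max-RGB; both limits are tested against
   independent oracles.  The exponent is not fixed by the method
   description; the default $p = 6$ is the canonical setting in the
   dermoscopy color-constancy literature and is configurable.
3. **CLAHE on lightness.**  The image is converted to CIE Lab and only L
   is equalized, with per-tile clipped histograms (256 bins, clip limit
   expressed as a multiple of the mean bin count, excess redistributed
   uniformly) and bilinear interpolation between tile mappings; chroma is
   preserved up to the conversion round trip.  Equalizing per RGB channel
   would distort hue and fight the color-constancy stage.  Per-tile
   mappings are nondecreasing by construction; with one tile and an
   effectively infinite clip limit the stage reduces to global histogram
   equalization.

All stages operate in floating point; quantization happens once, when an
image is written to disk.

## The synthetic study set

The generator emulates the structure of an annotated dermoscopy study at
desk scale: 900 feature-annotated images balanced 450/450 between the two
classes, split 80/20 into training and validation (stratified by
disease), a 2000-image pool carrying only disease labels, and a
400-image fully annotated holdout.  The annotated-pool sizes and the
80/20 rule mirror the annotated study design; the unlabeled pool is a
scaled-down stand-in for an archive-sized pool (the full size is one
configuration field away, `n_unlabeled`).

Each image is one elliptical lesion on a noisy skin-tone background.
The three checklist cues are independently switchable:

* *Asymmetry* multiplies the boundary radius on one (randomly oriented)
  half of the lesion by 1.5, producing a shape whose opposite-angle
  radial profiles differ — the statistic the tests use to verify the cue.
* *Atypical network* overlays a darker sinusoidal mesh across the lesion.
* *Blue-white structure* places a blue-gray blob inside the lesion.

Feature prevalence defaults to 0.5 per feature, independent, which
maximizes the diversity of ranking pairs.  Disease is drawn from the
checklist score through a logistic link,
$P(\text{melanoma}) = \mathrm{logis}(\beta_0 + \beta_1 s)$ with defaults
$\beta_0 = -2.2$, $\beta_1 = 1.5$, making the checklist rule true by
construction (so the ranking loss encodes real signal).  An additional
melanoma-specific darkening of the lesion body (strength 0.6 by default,
independent of the three cues) lets disease accuracy exceed the
checklist's Bayes ceiling, so disease supervision is never redundant
with the feature heads.

Two properties are engineered deliberately:

* **Casts are invertible.**  The per-image illumination cast multiplies
  each channel by a gain drawn from $[1 - r, 1]$ (default $r = 0.25$) —
  dimming tints that never clip, so the cast-free reference is exactly
  recoverable and the color-constancy stage has a well-defined target.
* **The pre-cast render is white-balanced** to equal Minkowski-6 channel
  means.  The cast-free reference therefore has "calibrated camera"
  semantics: Shades of Gray correction of the tinted image recovers it
  nearly exactly.  Without this, the correction would neutralize the
  intrinsic skin tone together with the cast and could never move the
  image closer to the reference.

What the generator does **not** emulate: photorealistic texture, hair
and ruler artifacts, skin-tone diversity, annotator noise on the feature
labels, and class-conditional feature correlations.  Passing tests
therefore demonstrate that the losses, the training machinery and the
pipeline behave as specified on detectable, independent cues — not that
the method reaches any particular accuracy on clinical archives.

A learnability floor is enforced by test: a 10-nearest-neighbor
classifier on color-constancy-corrected, 4×4-mean-pooled pixels must
separate each feature flag with AUC above 0.7 on 500 seeded samples, so
a failing deep model can never be excused by undetectable features.

## Training machinery

* **Optimizer.**  Plain SGD with momentum 0.9 and a
  reduce-on-plateau schedule (mode min, factor 0.5, threshold 0.01,
  patience 7 — the printed hyperparameters of the study the package
  mirrors), monitoring the enabled supervised terms on the validation
  split; that scalar is the only one every ablation row shares.
* **Learning rate.**  Default 0.03.  The backbone has no normalization
  layers (which keeps the trajectory bit-reproducible), and at desk scale
  0.01 leaves the loss near $\ln 2$ for the entire epoch budget while
  0.1 destabilizes the first epochs; inputs are also centered
  (`x - 0.5`) inside the forward pass for the same reason.
* **Backbones.**  `tiny_cnn` — four 3×3 convolution blocks
  (8/16/32/32 channels, stride-2 stem, max pooling, global average
  pooling) — is the desk-scale default; one epoch on 720 64-px images
  takes a couple of seconds on one CPU.  `resnet18_style` provides a
  residual trunk in the spirit of the 18-layer reference baseline with
  widths scaled down for CPU training.  Pretrained weights are out of
  scope.
* **Mean teacher.**  EMA decay defaults to 0.99.  The branch
  perturbation is an independent horizontal/vertical flip per branch;
  90-degree rotations were tried and measurably slowed supervised
  convergence at this scale without helping the consistency term.
  Mixed batches draw half their images from the labeled pool
  (configurable); the consistency weight ramps linearly over the first
  20% of steps, following mean-teacher practice.  The unlabeled pool
  carries disease tags (as in the study design it mirrors), and the
  disease term applies to them by default; a flag provides the stricter
  regime.  Optionally, unlabeled images can join the ranking loss with
  scores obtained by thresholding the teacher's feature predictions at
  0.5.
* **Cross-validation.**  The 80/20 split and the 5-fold rotation are one
  mechanism: ids are shuffled once, dealt round-robin within each
  disease class into 5 near-equal subsets, and each subset serves as the
  20% validation share of one fold.
* **Determinism.**  All randomness flows from fixed-kind R RNG streams
  derived from one seed (separate streams for generation, fold
  assignment and training); with a single-threaded BLAS, histories and
  reports are byte-identical across runs.

## Numerical choices and degenerate inputs

* Ranking and BCE terms use the `log(1 + e^x)` rewriting with the
  `max(x, 0)` split, so ±20-logit pairs evaluate without overflow.
* A batch with fewer than two samples has no ranking pairs; the loss is
  defined as 0 with a warning.
* AUC uses the rank (Mann–Whitney) form with average ranks on ties and
  is reported missing, with a warning, when only one class is present.
* Cohen's kappa is `(p_o - p_e)/(1 - p_e)` with marginal-frequency
  chance agreement; degenerate marginals (`p_e = 1`) yield a missing
  value rather than a division by zero.  Both the pooled three-feature
  kappa and per-feature kappas are reported, since a single published
  agreement figure does not say which aggregation was used.
* Feature probabilities are thresholded at 0.5 for accuracy; AUC uses
  the raw probabilities.
* Fold aggregation reports the sample SD (divisor $n - 1$), stated here
  so the columns are interpretable either way.
* The validation-best parameters are restored at the end of training
  (`restore_best = FALSE` keeps the final epoch, used by overfitting
  probes).

## Scale choices

The test suite and the acceptance script run the full pipeline at
900 labeled / 2000 unlabeled / 400 holdout images of 64 px, with
15–30-epoch training runs — sizes chosen so a complete verification pass
stays within a coffee break on one CPU while still exercising every code
path at the annotated-pool scale of the study design.  The same code
runs unchanged at larger sizes via `synthetic_config()` and
`train_config()`.

## Known limitations

* The synthetic cues are far cleaner than clinical dermoscopy; absolute
  accuracies on the generator say nothing about ISIC-scale performance.
* The ranking loss encodes a rule that is *true by construction* here;
  on real data its benefit depends on how well the checklist correlates
  with histopathology.
* No hair/artifact removal or lesion segmentation is attempted.
* The CLAHE global-equalization limit is verified on the neutral axis;
  strongly saturated colors can leave the sRGB gamut when lightness is
  pushed to the extremes and are clipped on conversion.
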