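---
title: "Decision fusion for skin-lesion classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision fusion for skin-lesion classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionfuse)
```

## The problem and the model

Discriminating melanoma from benign pigmented lesions in ordinary
(non-dermoscopic) photographs is hard: the two classes overlap visually,
collections are small, and melanoma is usually the under-represented class.
`lesionfuse` addresses this with an ensemble that deliberately multiplies
*representations* as well as *classifiers*:

1. **Balancing.** The minority class is grown to exact parity by adding
   altered copies of its images: each copy is the source image posterised by
   K-means colour segmentation (every pixel replaced by its colour-cluster
   centroid). The altered copies keep the lesion geometry but change the
   colour statistics, which is what augmentation needs here.
2. **Feature bank.** Each image is encoded by several independent feature
   extractors (the set *F* of *m* representations). In the original setting
   these are activations tapped from a named layer of ImageNet-pretrained
   CNNs — AlexNet `fc7` (4096-d, 227 px input), GoogLeNet `pool5-7x7_s1`
   (1024-d), ResNet-18 `pool5` (512-d) and ResNet-50 `avg_pool` (2048-d) —
   optionally adapted to the two-class task by replacing the final layers
   with a 2-output head.
3. **Classifier bucket.** A fixed set *C* of *n* probabilistic binary
   classifiers: a polynomial- and a Gaussian-kernel SVM (automatic kernel
   scale), logistic label propagation (LLP) on an rbf graph, and two KNNs
   (k = 3 with Spearman distance, k = 4 with correlation distance). Every
   member returns, per image, a label in {+1 = melanoma, −1 = not-melanoma}
   and a posterior score in [0, 1] for the predicted class.
4. **Fusion.** Every classifier is trained on every representation — the
   n × m combination grid. For a test image this yields a decision matrix
   `D` and an aligned score matrix `S`. Per feature column *j* the *mode*
   of the decisions gives the modal decision `dm[j]`, and the mean of the
   scores at the modal rows gives the modal score `ds[j]`. The final label
   is `dm[j*]` with `j* = argmax ds`: the representation whose consensus is
   most confident decides.
5. **Evaluation.** A bootstrapped 80/20 protocol: per iteration a training
   bag of size 0.8·N is drawn with replacement, the never-drawn images form
   the test set, the training portion only is balanced, and the full grid is
   refitted. Metrics (TPR, TNR, PPV, NPV, ACC, per-class F1, MCC) are
   averaged over 10 iterations.

The package also ships the classical interpolated mode for grouped
frequency data, `grouped_mode(l, h, f1, f0, f2) = l + (f1−f0)/(2f1−f0−f2)·h`.
It is deliberately **not** in the fusion path: for ±1 decision columns the
discrete mode is exact and the grouped formula's class-interval quantities
have no meaning, so the fusion uses `discrete_mode()` and `grouped_mode()`
is provided for completeness.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k_colors` | 5 | colour clusters for the balancing augmentation; 5 keeps lesion / skin / shadow structure while visibly altering the copy. Configurable because no canonical value exists. |
| `train_frac` | 0.8 | training fraction per bootstrap iteration |
| `n_iterations` | 10 | bootstrap iterations; the reported numbers are means |
| `replace` | `TRUE` | with-replacement bags (test = never-drawn images); `FALSE` gives a plain split |
| KNN `k` | 3 / 4 | neighbours; clipped to the training size with a warning rather than failing |
| SVM `kernel_scale` | `"auto"` | resolved as the median pairwise Euclidean distance on (up to 256) training rows |
| LLP `C`, `init`, `maxiter`, `tol` | 1, 0, 1000, 1e-6 | propagation strength `alpha = 1/(1+C)`, start value, iteration cap, convergence tolerance |
| `tie` | `"negative"` | exact ties resolve to not-melanoma; set `"positive"` for conservative screening |

## Numerical and design choices

* **Label coding** is +1 melanoma / −1 not-melanoma everywhere; scores refer
  to the *predicted* class, so they are always ≥ 0 and a flip of all training
  labels flips predictions while leaving reported scores unchanged.
* **SVM posteriors.** Kernel SVMs emit margins, not probabilities; margins
  are mapped through a logistic link fitted on the training margins. The
  mapping is monotone, so ranking-based behaviour is unaffected.
* **KNN posteriors** are neighbour vote fractions; "Spearman" and
  "correlation" distances are 1 − the respective coefficient computed across
  the feature dimensions (the standard conversion). Vectors with zero
  variance get correlation 0 (no signal) rather than NA.
* **LLP internals.** The propagation runs on symmetric-normalised rbf
  affinities over train ∪ test, `f ← alpha·S·f + (1−alpha)·y`, from
  `f = init`, to convergence or `maxiter`; propagated values are squashed
  through a logistic link. The formulation follows the standard
  semi-supervised propagation literature; the exact internals of the
  originally cited variant are not recoverable from its one-line settings,
  so every knob is exposed and the implementation is sanity-checked by its
  agreement with KNN on separable data.
* **Mode ties** (equal +1/−1 counts in a column) are resolved by the mean of
  the supporting scores — consistent with the score-driven final selection —
  then towards −1; argmax ties in `ds` go to the lowest column index. Both
  rules are deterministic and documented; the column rule is configurable.
* **Accuracy** is `(TP+TN)/(TP+FP+TN+FN)`. One published rendering of the
  metric table prints `TP+FN` in the numerator; that conflicts with the
  universal definition and with the accuracies the same sources report, so
  it is treated as a misprint.
* **Undefined metrics** (zero denominators, possible on small bootstrap test
  sets) are reported as `NA` markers, never silently as 0.
* **MCC from rates.** `metrics_from_rates()` uses the identity
  `MCC = sqrt(TPR·TNR·PPV·NPV) − sqrt((1−TPR)(1−TNR)(1−PPV)(1−NPV))`,
  algebraically equal to the count formula when all margins are non-empty;
  the test suite verifies the identity to 1e-12 on 1000 random confusion
  tables.
* **Determinism.** All randomness flows from one root seed; split, balance
  and per-grid-cell seeds are derived from it, so identical plans reproduce
  identical reports bit for bit.
* **Bootstrap bags and images.** On the image path, duplicated draws of the
  same image are collapsed before balancing (pixel-identical duplicates add
  nothing to K-means augmentation and would collide on ids); on the feature
  path the bag's duplicates are honoured as repeated training rows and
  balancing duplicates minority rows round-robin.

## The synthetic generators: what they emulate and what they do not

`synth_images()` emulates a small clinical photo collection: skin-toned
background, one central blob per image; melanoma blobs are darker with an
irregular radially-perturbed boundary, benign blobs lighter and nearly
circular, `lesion_contrast` scaling the luminance gap. This gives the
balancer and the colour-feature extractor genuine structure while staying
byte-reproducible. It does **not** simulate hair, rulers, specular
highlights, varying illumination or real lesion texture — so green tests
show the pipeline's mechanics are correct, not that any accuracy carries
over to clinical images.

`synth_features()` emulates the feature bank directly: per pseudo-extractor,
two isotropic Gaussian clusters at unit within-class standard deviation with
means `class_separation` apart. The mean difference alternates in sign
across dimensions (a pattern, not a constant offset): correlation and rank
distances are invariant to adding a constant to every dimension, so a
constant shift would be invisible to two of the five bucket members and the
generator would not deliver the separation it promises. At separation 10
the task is effectively noiseless — the end-to-end bootstrap reaches
accuracy 1.0 — and at separation 0 it is exactly chance.

Problem sizes used by the shipped tests and the acceptance script — 50
images per class, two pseudo-extractors (30- and 20-dimensional), the full
five-member bucket, 10 bootstrap iterations — were chosen as the smallest
sizes at which the protocol's means are stable.

## Deep backbones without a deep-learning runtime

The four registry backbones declare the layer-tap contract (name, input
size, tapped layer, feature width). Running the real pretrained weights
requires a deep-learning runtime, which is not a dependency of this
package; `extract_features()` therefore accepts a pluggable `engine`
function for users who have one. Without an engine it falls back to a
built-in deterministic weight-free encoder — 16-bin colour histogram
statistics passed through a fixed, backbone-seeded random projection with
ReLU to the declared width — and warns once. The fallback honours every
structural contract (dimension, row order, determinism, offline operation)
but carries no ImageNet knowledge; published benchmark numbers on real
datasets are only reproducible with a real engine, and no such claim is
made by the tests. Fine-tuning settings (mini-batch 5, max 10 epochs,
initial learning rate 3e-4, SGDM, 2-output head, optional early-layer
freezing) are modelled on the spec'd adaptation recipe and carried on the
backbone spec for engines that train.

## Known limitations

* Binary fusion only: the mode/argmax rule is implemented for the two-class
  case; multi-class would need a different modal-score definition.
* The LLP member is transductive (it propagates over train ∪ test), so its
  per-image cost grows with the joint set; the grid predicts test batches in
  one pass to amortise this.
* Published-benchmark fidelity depends on the feature engine; the built-in
  encoder is a structural stand-in, labelled as such.
* Balancing by posterisation changes colour statistics only; it cannot
  create new lesion geometry.

## A worked fusion example

```{r fusion-example}
D <- matrix(c(1, 1, -1,   -1, 1, -1), nrow = 3)
S <- matrix(c(0.9, 0.8, 0.55,   0.6, 0.7, 0.95), nrow = 3)
fu <- fuse(D, S)
tidy(fu)
fu$final_label; fu$final_score
```

Column 1's majority is +1 (rows 1–2, mean score 0.85); column 2's majority
is −1 (rows 1 and 3, mean score 0.775). Column 1 has the higher modal
score, so the fused decision is +1 (melanoma) at confidence 0.85.

## End-to-end on synthetic data

```{r end-to-end}
feats <- synth_features(synth_feature_spec(
  n_per_class = 50, dims = c(30, 20), class_separation = 10, seed = 101))
res <- run_bootstrap(feats, bucket = default_bucket(),
                     plan = boot_plan(n_iterations = 10, seed = 7))
glance(res)[c("acc", "mcc", "tpr", "tnr")]
```
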