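---
title: "Two-level classification of thyroid cytology from correlative color and RI images: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cytofuse methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Thyroid fine-needle aspiration biopsy (FNAB) cytology is read cluster by
cluster: groups of follicular cells on a Papanicolaou-stained slide are
judged benign or malignant. Correlative optical diffraction tomography can
record, for the same cluster, a conventional color brightfield image and a
label-free refractive-index (RI) tomogram, collapsed here to a 2D
Z-projection registered to the color image. The two contrasts carry
complementary information: color mostly exposes nuclear size and
chromasia, while the quantitative RI channel resolves structural detail
around and inside the nuclear envelope (margination, clearing,
micronucleoli) that is diagnostic of papillary carcinoma.

`cytofuse` implements the full two-level analysis around that idea:

1. **Tiling.** Each cluster's registered image pair is cut into 256 x 256
   pixel patches (26.1 um at 0.102 um/px) with a 128-pixel stride; a patch
   is retained when the pooled mean of its color counts is at least 170.
   The filter is the only selection step: bright background patches that
   pass it are kept without manual curation.
2. **Patch scoring.** A convolutional network per modality scores each
   patch with the probability that it came from a malignant cluster. Patch
   labels are inherited from the cluster (weak supervision).
3. **Cluster classification.** Scores are arranged on the tile grid as a
   per-cluster prediction map; 13 order statistics of the map feed a
   gradient-boosted tree classifier, fitted per modality and for the
   concatenated ("combined") feature vector.
4. **Evaluation.** Confusion matrices and accuracy / sensitivity /
   specificity / PPV / NPV, with clusters represented by fewer than five
   retained patches excluded from cluster-level result tables.
5. **Explanation.** Grad-CAM saliency, 0.05-wide score histograms,
   0.2-wide score bins summarised by mean nucleus area and mean Brenner
   gradient (30 sampled patches per bin), and exact t-SNE of
   penultimate-layer patch embeddings.

Real correlative FNAB image sets are not publicly deposited, so the
package ships a synthetic-data module that emulates the statistical
structure of the task and provides ground-truth nuclear masks; every
stochastic claim the package makes is demonstrated on that generator.

## The synthetic correlative cytology generator

`generator_config()` encodes the study conditions. Each patient carries a
benign or malignant diagnosis (drawn with probability 0.265 of
malignancy, the class balance of a 1535-cluster FNAB series); all clusters
from one patient share the label, mirroring per-patient diagnosis. Each
cluster is one 1024 x 1024 image pair (a 7 x 7 patch grid, so every
cluster clears the five-patch eligibility rule).

Nuclei are ellipses (axis ratio 0.75-1, eccentricity at most 0.7) placed
as a Gaussian clump with a minimum centre separation. The two
class-discriminative axes are:

* **Size.** Equivalent nucleus radius is Gaussian: benign 3.5 +/- 0.5 um,
  malignant 5.0 +/- 0.8 um. Benign follicular nuclei are around 7 um in
  diameter; papillary carcinoma nuclei are enlarged by roughly half. The
  distributions overlap so the task stays non-trivial.
* **Intranuclear detail.** A dimensionless detail contrast (benign 0.15,
  malignant 0.45) scales three RI-only features modelled on papillary
  carcinoma cytology: a nuclear-envelope ring (chromatin margination), a
  central clearing (the "ground-glass" nucleus) and intranuclear speckles
  (micronucleoli, chromatin granules).

**Color rendering.** Bright background near 200 counts (channel offsets
sum to zero so the pooled mean equals the configured level), darker
blue-purple nuclear ellipses with a faint cytoplasm halo, and Gaussian
per-channel noise (sd 3). The darkening amplitudes were chosen so that
windows overlapping a cluster keep pooled means above the 170-count
filter: on generated clusters at the default geometry at least 99% of
patches pass, so the filter behaves as a background/dark-field guard, not
as a hidden segmentation step. The color channel carries **no**
intranuclear detail by construction.

**RI rendering.** Each nucleus contributes a projected-ellipsoid dome
whose integrated value is fixed per nucleus ("dry mass" conservation with
15% log-normal jitter): larger nuclei are proportionally dimmer, so the
coarse-scale RI intensity is nearly size-blind and the RI class signal
rides on the detail features. The envelope ring amplitude likewise scales
inversely with radius (fixed ring mass). The dome is kept faint relative
to ring and speckles. A faint cytoplasm plateau, non-negative clipping
and Gaussian noise (sd 0.02, arbitrary projected-RI units) complete the
image. The projection convention and units of real 2D RI maps are not
standardised; the generator emits an abstract non-negative "projected RI
excess" and no 3D tomogram.

**Staining artifacts.** Staining contaminates real RI images. The
generator adds smooth raised-cosine blobs and streaks to the RI channel
only, with amplitudes comparable to nuclear domes and support capped at
12% of the image. Because the blobs overlap the nucleus size range they
act as size confounders for the RI model, while their smoothness keeps
the Brenner gradient low — which is what places artifact-dominated
patches in the intermediate score bins of the explanatory analysis.

**Determinism.** The master seed fixes patient labels and per-cluster
render seeds; each cluster renders independently and reproducibly, so
datasets can be streamed cluster by cluster or regenerated selectively.
The large noise fields use a dedicated, platform-stable normal generator
(Marsaglia polar on an `mt19937_64` stream); all geometry sampling uses
R's RNG under the cluster seed.

What the generator does **not** emulate: optical diffraction, halo and
coherence artifacts of real ODT, Bethesda-indeterminate morphologies,
overlapping three-dimensional cell stacks, slide-level staining
variability, and human annotation noise beyond the weak patch labels.
Passing the synthetic acceptance suite therefore shows that the pipeline
recovers the signals it is designed for — not that it would reach the
same operating points on clinical material.

## Patch-level model

The reference architecture for this task at full scale is DenseNet-169;
training it is far outside a laptop-sized budget and needs a
deep-learning runtime, so the package's working backbone is a small CNN:
four 3 x 3 same-padded conv blocks (8/16/32/32 filters) with ReLU,
max-pooling after the early blocks, global average pooling and a sigmoid
head — about 15k parameters trained with Adam on class-weighted binary
cross-entropy. `backbone = "densenet169"` remains a recognised
configuration value but raises an informative error. The trainer is
implemented from first principles (im2col convolutions, max-pool argmax
routing, analytic backprop verified against finite differences to 1e-10),
which also gives Grad-CAM its gradients for free.

Inputs are block-mean-downsampled patches of side 16 px (the block mean
of a 256-px patch; 16 was chosen as the smallest size at which both the
nuclear size signal and the detail-driven intensity signal remain
separable while a five-replicate study trains in minutes). Color patches
enter as optical density relative to the dataset-median background count
— background maps to ~0 and stained structure to positive values, which
conditions the ReLU network far better than raw counts. RI patches are
min-max scaled with dataset-level constants estimated on the training
partition only; both normalisation constants are recorded in the model
object so held-out data reuse them.

Training choices the source architecture leaves open and that are fixed
here: Adam with constant learning rate 3e-3, batch 64, 10 epochs,
horizontal/vertical flip augmentation (rotation-safe for cytology),
inverse-frequency class weights, best epoch selected by validation loss.
Training is single-threaded and bit-reproducible given the seed.

## Cluster-level model

The heatmap feature set is deliberately simple and versioned through its
names: patch count; mean, sd, min, max; the 10/25/50/75/90% quantiles
(type-7); the fractions of scores strictly above 0.5 and 0.9; and the
mean of the top five scores. The combined model concatenates the color
and RI vectors (26 features) rather than averaging scores, which is the
most direct realisation of training one cluster model on both image
types together. The default classifier is gradient-boosted trees with
small capacity (150 rounds, depth 3, learning rate 0.1) to suit datasets
of a few hundred clusters; random forest, RBF support-vector machine and
a single-hidden-layer perceptron are selectable for robustness checks.
The decision threshold is fixed at 0.5 throughout; the evaluation module
reports single operating points and no ROC.

## Evaluation conventions

Metrics are exact ratios; rounding (half-up to three decimals, with exact
unity printed as "1.0") happens only in formatting. A metric with a zero
denominator is reported as missing, never as 0 or 1. Cluster-level result
tables exclude clusters with fewer than five retained patches; the filter
applies to evaluation only, never to training.

## Explanatory analyses

* **Brenner gradient.** The named focus/detail measure is implemented as
  the mean over interior pixels of squared two-pixel forward differences
  along both axes. Mean (not sum) normalisation makes values comparable
  across patch sizes; the measure is shift-invariant. Color patches are
  reduced to Rec. 601 luminance first; RI patches use the raw channel.
* **Score bins.** Half-open bins with the top bin closed, for both the
  0.05 histogram and the 0.2 summary bins; up to 30 patches are sampled
  per bin without replacement under a seed. Mean nucleus area uses the
  ground-truth masks (mask pixels x pixel pitch squared, averaged over
  the nuclei visible in a patch); patches without nuclei contribute no
  area value. `segment_nuclei()` (Otsu threshold, connected components,
  2 um^2 minimum) provides the same measurement when no mask exists.
* **Grad-CAM.** Standard formulation on the last conv block: channel
  weights are the spatially averaged gradients of the target-class logit,
  the weighted activation sum is rectified, bilinearly upsampled to patch
  size and max-normalised. With a GAP head the channel weights reduce to
  the (signed) output weights over the map area. An all-zero map warns
  and returns flat saliency.
* **t-SNE.** No t-SNE implementation ships with the environment's R
  stack, so the package carries an exact O(n^2) implementation:
  perplexity calibration by bisection per point, symmetrised affinities,
  early exaggeration (x12 for 100 iterations), momentum with adaptive
  gains, seeded Gaussian initialisation. It is meant for the few hundred
  sampled patch embeddings the pipeline retains, not for full datasets.
  Class separation of a layout is summarised by the mean silhouette
  width of the diagnosis labels.

## Problem sizes and replication

The package's own studies (tests and the acceptance script) run the full
pipeline at 124 patients with one to two clusters each (about 190
clusters, about 9,000 retained patches), five replicates under seeds 1-5,
with 0.64/0.17/0.19 cluster-grouped stratified splits. These sizes were
fixed once, before the acceptance checks were written, as the smallest
design in which all five replicates train both modality models and the
three cluster models in a few minutes each; the cluster counts per
patient are below clinical practice (up to 20 per slide), which mainly
reduces the number of clusters per patient-level label draw. The
modality-complementarity experiments use 40 balanced patients so that
accuracy differences are not masked by base rates.

## Known limitations

* Synthetic imagery only; see the generator's non-goals above.
* The patch models consume 16-px block means, so sub-block texture enters
  the classifier only through its effect on local means; the Brenner and
  Grad-CAM analyses, by contrast, run at full resolution.
* The heatmap feature set is one reasonable choice, not a reconstruction
  of an unpublished one; alternates can be compared by extending
  `extract_features()` and re-fitting.
* Patch-level labels are weak: background patches inherit their cluster's
  label, which bounds attainable patch accuracy and is visible in the
  score histograms as a mid/low-score background mode.
* With cluster-level grouping (the default), two clusters of one patient
  may fall into different partitions; `by_patient = TRUE` gives the
  stricter split.
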