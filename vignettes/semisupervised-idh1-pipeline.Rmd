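---
title: "Semi-supervised radiomics for IDH1 status: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised radiomics for IDH1 status: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gliosemi)
```

This vignette is the package's account of the science it implements: the
models and their assumptions, the parameters that matter, what the
synthetic phantoms do and do not emulate, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## Problem setting

IDH1 mutation status is a binary molecular marker central to glioma
diagnosis and prognosis, normally obtained from tissue after surgery.
Predicting it preoperatively from MRI is attractive, but genotyped
cohorts are small while ungenotyped imaging is plentiful. The pipeline
therefore (i) builds a cheap, interpretable per-feature classifier on the
labeled subset to *pseudo-label* the rest, and (ii) trains a deep
sequence classifier on labeled plus pseudo-labeled data, with the
pseudo-labels down-weighted by a tuned factor α so that wrong
pseudo-labels cannot destabilize training.

## Texture features

Intensities are first normalized into the quantizer's gray limits
(default `[0, 2100]`, mode `"rescale"`; a `"clip"` mode exists for data
already calibrated to that range). This choice anchors the otherwise
scanner-dependent parameters: with 100 levels the bin width is exactly
21 intensity units.

GLCM matrices count co-occurrences of quantized levels at displacement
(direction, offset); GLRLM matrices count maximal constant-level runs by
level and length. Both are computed per 2-D slice and *summed across
slices before* feature evaluation (the common 2.5-D convention; a
per-slice-feature-mean alternative is configurable). Features follow the
standard Haralick and Galloway/Chu definitions, with these numerical
conventions:

* natural logarithms everywhere, with `0·log 0 := 0`;
* `Variance` is the variance of the row-marginal level distribution and
  `SumVariance` is centered on `SumAverage`;
* `Correlation` and both information measures of correlation are defined
  as 0 on degenerate (constant-image) matrices;
* `InverseVariance` sums off-diagonal terms only.

The enumeration convention — per-(direction, offset) values plus a
direction-averaged value per offset for GLCM, per-direction plus
direction-averaged for GLRLM — is the only one consistent with the
printed totals of 330 GLCM-derived and 33 GLRLM-derived columns per
sequence, and the tests assert those counts. Features are computed on the
whole slice by default (the classifier is deliberately
segmentation-free); an optional mask argument restricts both pair
counting and run scanning, and a masked computation is invariant to
appending background slices.

## Feature screening and rough-set reduction

Screening uses the classical pooled-variance two-sample *t*-test
(Welch optional), retaining `p < alpha` with strict inequality and no
multiple-testing correction — the screen is deliberately permissive; the
reduction handles redundancy.

Rough-set reduction needs discrete attributes, so features are
quantile-binned (default 4 bins) with edges fitted on labeled data only
and replayed verbatim on unlabeled data. The positive region of a
decision table is the union of attribute-indiscernibility classes that
are pure in the decision; it can only shrink when attributes are removed
(anti-monotonicity, which the tests check). Reduction deletes attributes
one at a time whenever the positive region is unchanged, sweeping
repeatedly until stable; the result preserves |POS| exactly and is
1-minimal, verified in the tests against exhaustive subset search.
Reducts are not unique: the default deletion order tries the weakest
attributes (smallest |t|) first, so discriminative features tend to
survive; a seeded random order is available. On small cohorts (tens of
labeled patients) the positive region is often preserved by one or two
attributes — reducts shrink aggressively, which is faithful rough-set
behavior, and means the subsequent vote may rest on few rules.

## Youden threshold rules and pseudo-labeling

For each reduct feature the rule scans every observed value as a cutoff,
in both orientations, and keeps the maximizer of
J = sensitivity + specificity − 1. Orientation `">"` is inclusive (a
value at or above the cutoff votes mutant). Ties in J are broken toward
higher specificity, then the smaller cutoff, then `"<="` — preferring the
rule that is most conservative about calling mutants, the minority class
in typical glioma cohorts. Rules record the empirical rank AUC (of
mutant over wild values, so a rule whose mutant side is *low* can
legitimately report AUC < 0.5) and the feature's pooled *t*-test p-value.

Unlabeled patients receive the majority vote of all rules; an exact tie
defaults to wild type (the majority class), and a Youden-weighted vote is
available. The vote fraction is kept as a confidence surrogate but is not
calibrated.

## SCSO and the weighted loss

The semi-supervised loss is
`L = Σ_labeled ℓ(f(x), y) + α Σ_pseudo ℓ(f(x), y)` with ℓ = cross-entropy.
α multiplies the *loss term*, not the prediction: weighting the
prediction inside ℓ would leave the domain of the cross-entropy and
contradicts α's meaning as an instance weight. At α = 1 the loss reduces
to the plain supervised sum over all instances, at α = 0 to the
labeled-only sum (both asserted at machine precision).

Sand Cat Swarm Optimization tunes α over [0, 1]. Per iteration the
general sensitivity decays linearly, `rG = sM(1 − t/T)` with the default
ceiling `sM = 2` (mirroring the sand cat's 0–2 kHz hearing range); each
agent draws `R ~ U(−rG, rG)` and `r = rG·u`. With `|R| ≤ 1` the agent
attacks — `x ← x_best − r·|u′·x_best − x|·cos θ` with θ drawn uniformly
over 0–360° (an equal-weight roulette wheel, since no angle weights are
given) — otherwise it searches. Two exploration forms are implemented:
the default `r·(x_best + u″·x)` and the classical `r·(x_best − u″·x)`,
selectable as `explore_form`. Out-of-bounds positions are clipped. The
linear decay guarantees pure exploitation (|R| ≤ 1 surely) over the final
third of the iterations for sM = 2. The fitness used by the pipeline is
the validation loss of a short weighted CRNN training run with a fixed
inner seed, making the search deterministic given the config.

## UCNet

The feature extractor is a 2-D convolutional autoencoder applied per
slice, with the sequences of a patient stacked as input channels:

* **Encoder** — two dense blocks of 4 conv layers (channel plan
  64/64/128/128 at full scale; kernel sizes 5, 3, 3, 1), each layer
  consuming the concatenation of the block input and all previous layer
  outputs. Literal *summation* of previous outputs is ill-typed across
  unequal channel counts, so DenseNet-style concatenation is used.
  Blocks are joined by a 1×1 convolution plus 2×2 average pooling.
* **Decoder** — two residual blocks (same plans, 1×1-projected identity
  shortcut), each preceded by nearest-neighbour upsampling and
  concatenation with the equal-size encoder skip; a linear 1×1 head
  reconstructs the input.
* The per-slice feature vector is the globally average-pooled bottleneck;
  which activations form the feature was unspecified, and the bottleneck
  GAP is the natural information-bottleneck choice.

Training uses Adam on mean-squared reconstruction error (full-scale defaults:
learning rate 1e-5, batch 4 patients, up to 300 epochs with patience
early stopping). The classifier is a CRNN: a kernel-3 1-D convolution
over the slice axis, an LSTM whose final state passes through dropout
(0.5) to a 2-class softmax, trained with the weighted loss (full-scale
defaults: lr 1e-4, batch 40 supervised / 30 semi-supervised). Because
the GAP bottleneck features are tiny in scale (standard deviations of
order 1e-2), the classifier z-scores each feature dimension with
training-set statistics stored in the model and replayed at inference —
without this, LSTM training stalls. Splits are always patient-level,
never slice-level, so slices of one patient can never straddle train and
validation.

All layers are implemented in the package — the 2-D convolutions as
compiled im2col+GEMM kernels, everything else in R — with hand-derived
backpropagation verified against central finite differences (relative
error ~1e-6) in development. Dropout masks, shuffles and weight
initialization all derive from the config seed, so training is
bit-reproducible.

## Synthetic phantoms

`generate_cohort()` emulates what the pipeline needs from real cohorts:
per-patient multi-sequence volumes containing an ellipsoidal "tumor"
blob on a smooth background, with additive white scanner noise
(`noise_sd = 20` intensity units by default). The class signal is the
*spatial correlation length* of the blob texture: the mutant-class field
is rough (Gaussian smoothing σ = 0.6 px) and the wild-class field is
smoother (σ = 0.6 + 0.45·effect), with both fields rescaled to a common
marginal standard deviation (300 units) so mean and variance carry no
class information — only second-order texture (GLCM/GLRLM) does. At
`class_texture_effect = 0` the classes are exchangeable; at the default
effect 2 the designated GLCM Contrast feature separates them with rank
AUC above 0.9 (a tested property). Unlabeled phantoms keep their true
class in a `hidden_label` field used only to score recovery.

The phantoms do **not** emulate: anatomy, inter-sequence contrast
relationships, registration or motion artefacts, bias fields,
heterogeneous tumor subregions, or class-imbalanced cohorts. Passing
tests therefore demonstrate that the machinery is correct and that the
pipeline recovers a known texture signal — not that real-world IDH1
accuracy is reproduced; the printed clinical accuracies depend on a
private cohort and GPU-scale training and are intentionally out of
scope.

## Problem sizes used by the tests

Test and acceptance runs use desk-scale configurations chosen so the
whole suite runs in minutes on one CPU: 16×16 to 64×64 slices, 2–8
slices per volume, channel plans 4/4/8/8, ≤ 50 classifier epochs, and
SCSO populations of 3–5 agents for weight tuning (the α landscape over
[0, 1] is low-dimensional and smooth at these scales). The
semi-supervised comparison property runs the complete flow on 32×32×4
volumes with 30 labeled plus 30 unlabeled patients across 5 seeds. The
full-scale preset (`ucnet_config_full()`: 256×256×16, channel plan
64/64/128/128, 300 epochs) is provided but not exercised by the tests.

## Degenerate inputs and numerical guards

Constant volumes pass normalization unchanged with a warning; constant
images quantize to a single level, and their texture features take the
documented degenerate values. A GLCM offset exceeding the image extent
yields an all-zero matrix with a warning. Empty run matrices, empty rule
lists, single-class training sets, untrained models at prediction time,
weights outside [0, 1], and unknown augmentation operations are all
rejected with informative errors. Non-finite training losses abort with
a diagnostic rather than propagating. ε-guards: probabilities are floored
at 1e-12 inside logs.

## Known limitations

* Reducts — and therefore rule votes — can be very small on small
  cohorts; vote-fraction confidence from one rule is binary.
* The pseudo-label vote is uncalibrated; `vote_fraction` should not be
  read as a probability.
* SCSO's inner fitness retrains only the CRNN (the extractor is trained
  once on all volumes), a deliberate economy; jointly re-training the
  extractor per candidate α would be faithful to a larger compute budget.
* 3-D (26-neighbourhood) texture matrices and wavelet/shape/first-order
  radiomics families are out of scope.
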