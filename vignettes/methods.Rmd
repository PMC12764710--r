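---
title: "Attention-based CT slice fusion for discrete-time survival: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based CT slice fusion for discrete-time survival: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Two-year overall survival of lung-cancer patients is to be predicted from a
baseline thoracic CT scan alone. Survival data are censored: for many
patients we only know they were alive up to some month. `attnsurv`
implements a pipeline that (i) reduces a CT volume to the axial slices that
actually contain lung, (ii) encodes each slice with a 2D backbone,
(iii) fuses the per-slice embeddings into a single volume representation
with learned soft attention, and (iv) maps that representation to a
discrete monthly event-time distribution whose training loss respects
censoring. Model quality is read off with the time-dependent concordance
index, and two significance tools (a patient-level permutation test and the
exact Wilcoxon signed-rank test with effect size r) support model
comparisons.

## Preprocessing model

A scan is converted to Hounsfield units, resampled to (1, 1, 3) mm by
trilinear interpolation (output shape = rounded physical extent over target
spacing), and segmented into lungs. The default segmenter is deliberately
simple and fully deterministic: threshold below -320 HU, discard
6-connected components touching the in-plane volume border (outside air),
keep the two largest remaining components, one step of morphological
closing. A learned segmenter can be plugged in through the `segmenter`
argument; the package does not ship one.

Slices whose lung area is below 2% of the slice area are excluded; exactly
2% is retained ("less than" excludes). By default every sub-threshold slice
is dropped, including interior ones; `mode = "trim"` restricts exclusion to
the apical/basal runs, since the wording of the underlying procedure admits
both readings. One in-plane bounding box - the union of per-slice lung
boxes over the retained slices - is applied to every retained slice, so no
masked lung pixel of a retained slice is lost. Each slice is then resized
to 224x224 (bilinear, aspect ratio not preserved) and windowed from
(-1000, 400) HU linearly onto [0, 1]. The window spans air to soft tissue;
the choice is the package's own, as is the convention that relative slice
position runs from 0 at the most apical retained slice to 1 at the most
basal (a single retained slice gets position 0).

Training-time augmentation flips and/or rotates a slice (uniform angle in
+/-20 degrees) with probability 0.2. The desk-scale training profile keeps
augmentation off: it operates on cached pooled features for speed, and the
phantom world (below) has no pose variability for augmentation to factor
out.

## Slice encoding and the toy backbone

The encoder contract is: one embedding per slice, computed independently
per slice. Real deployments plug in a pretrained 2D CNN; the shipped
default is a small deterministic "toy" backbone so that nothing needs to be
downloaded and the whole test-suite runs on one CPU:

1. **Fixed feature stage (parameter-free, the frozen "pretrained body").**
   Each slice is reduced to 32 deterministic features: a 24-bin intensity
   histogram over the [0, 1] window, the occupancy, centroid and
   dispersion of the intensity band just above lung parenchyma
   (0.17-0.35, where lesion-like soft structure lives), and four intensity
   summaries (mean, sd, 90th and 99th percentiles). Like the features of a
   network pretrained on natural images, these are informative about
   generic structure without ever having seen the cohort, and they are
   smooth, low-dimensional functions of the slice - robust to pixel noise
   and hard to memorize patients through.
2. **Trainable head.** One ReLU layer 32 -> 32 (d_e = 32), followed by
   layer normalization of each slice embedding (mean 0, unit variance, no
   learned affine), which bounds the attention logits and the risk
   network's input scale the way batch/layer normalization does in
   full-size backbones.

This design was not the first attempt, and the failure modes of the
alternatives are instructive (probed during development with regularized
linear models on the synthetic cohort): a frozen stack of random ReLU
layers degrades the linearly recoverable hazard signal layer by layer, so
it is a poor stand-in for a backbone whose frozen layers were trained to
be useful; a frozen random *linear* projection preserves the signal for a
shrunken linear probe but also passes the per-patient pixel-noise
fingerprint through untouched, and the risk network then memorizes
training patients (training concordance near the ceiling with held-out
concordance at chance and no correlation with the true hazard). The fixed
low-dimensional feature stage resolves both failure modes; the acceptance
suite's recovery experiment measures where the resulting pipeline lands
relative to the generator's constructed ceiling.

Freeze strategies mirror the two named configurations: `feature_extractor`
freezes everything except the last layer; `half_frozen` freezes the first
half of the layers by count. For the toy backbone - whose only
parameterized layer is the head - both leave exactly the head trainable;
they differ for deeper plug-in backbones.

## Aggregation

Soft attention scores each slice embedding with one learnable linear
functional (`W s_j + b`), softmaxes the scores over the volume's slices
(max-subtraction for overflow safety) and returns the convex combination
`x = sum_j w_j s_j`. Invariants tested: weights nonnegative and summing to
1 within 1e-6, shift-invariance of the logits, padded slots receiving
exactly zero weight, and the output bounded coordinate-wise by the slice
extrema. Two ablation aggregators are included: the unweighted average, and
one multi-head self-attention block (4 heads, width d_e, no positional
encoding, residual connection) over the sequence with a prepended class
token whose transformed value is returned; without positional encoding it
is permutation-invariant. The class-token block runs with fixed random
projections - a random-features ablation; training it end-to-end is out of
desk scope and only downstream parameters receive gradients.

## Risk network and loss

The risk head is the DeepHit layout restricted to a single event: a shared
sub-network of 5 fully connected ReLU layers of 100 units with dropout 0.2,
a cause-specific part consuming the concatenation `(f_s(x), x)` (the
residual input connection), and a single softmax over 24 monthly bins. The
output layer is initialized with small weights so the initial distribution
is near uniform regardless of input scale.

With `y` the predicted monthly distribution and
`F(t) = sum_{m<=t} y_m` the estimated cumulative incidence,

* `L1 = -sum_i [ 1(k_i=1) log y_{i,s_i} + 1(k_i=0) log(1 - F_i(s_i)) ]`,
* `L2` accumulates `exp(-(F_i(s_i) - F_j(s_i)) / sigma)` with sigma = 0.1
  over acceptable pairs (`k_i = 1`, `s_i < s_j`), by default as the mean
  over pairs so the alpha/beta balance is batch-size independent (a flag
  restores the plain sum),
* `L = alpha L1 + beta L2` with alpha = beta = 0.5.

Numerical choices: a 1e-7 floor inside logarithms; softmax with
max-subtraction; time index 1..24 with `s = 0` remapped to month 1 under a
warning (a first hitting time of zero is not representable in a monthly
softmax) and times beyond the horizon censored at 24. For a patient
censored exactly at the horizon, `1 - F(24)` is identically zero under the
softmax parameterization; the floored term contributes the constant
`-log(eps)` whose gradient through the softmax is exactly zero, so such
patients inform training only through the ranking term - which is precisely
the information they carry. All gradients are analytic and verified against
central differences at 1e-4 relative tolerance.

Censoring convention: the event indicator uses k = 0 for
censoring/truncation throughout (one of the two notations used for the
same quantity in the source material).

## Evaluation and comparison statistics

The time-dependent concordance compares, over acceptable pairs, the CIFs at
the earlier patient's event time with a strict inequality (ties score 0; a
flag credits ties 0.5). The permutation comparison swaps the two models'
predictions patient-wise with probability 0.5, 5000 times by default, and
reports the add-one-smoothed two-sided p-value for the observed concordance
difference (a t-like statistic over per-event-time concordance differences
is available behind a flag, since the procedure's name and its description
admit either statistic). The Wilcoxon signed-rank test drops zero
differences, uses average ranks, takes the smaller signed-rank sum as the
statistic and computes the exact two-sided p by convolution over all sign
assignments (equivalent to full enumeration, n <= 25), with no continuity
correction; the effect size is |Z|/sqrt(n) with the no-correction normal
standardization, which reproduces r = 0.899 for six one-signed differences.

## The phantom world

The simulator is a stated world, not an anatomical model. A soft-tissue
body ellipsoid (+40 HU) in air (-1000 HU) contains two lung ellipsoids
(-800 HU) whose in-plane cross-section tapers toward the apex and widens
toward the base - real lungs are basally larger, and this asymmetry is what
makes axial position readable from slice content at all. An optional
spherical lesion (+60 HU above parenchyma, so threshold segmentation keeps
it inside the lung mask) is clipped to the lung interior; its realized
volume in cm^3 and its relative depth drive a constant per-month hazard
`h = plogis(-5.0 + 0.8 vol + 1.2 depth)` over 24 months. Lesions are
present with probability 0.8, radius uniform on 4-9 mm, depth basally
skewed (0.15 + 0.7 Beta(2, 1.2)); censoring is an independent uniform clock
applied with probability 0.3 plus administrative truncation at the horizon.
Geometry constants keep the lungs strictly inside the body at every 3 mm
axial step under the +/-4% per-phantom shape jitter, so the segmenter's
border-component rule cannot leak.

The hazard coefficients were calibrated once, by ranking simulated patients
by their true hazard, to a Bayes-optimal time-dependent concordance of
about 0.75 with roughly half the cohort experiencing the event, and then
frozen. Because administrative truncation adds censored mass on top of the
clock, the realized censored fraction is about 0.5; the generator's
property test checks the realized fraction against this closed-form law
rather than against the clock rate alone.

The transfer-learning surrogate uses its own, deliberately harder world:
heavy image noise (45 HU) in both the 120-patient source and the
40-patient target makes the feature-to-hazard mapping data-hungry (with
the default mild noise, the fixed feature stage is informative enough
that even a small from-scratch fit sits near the ceiling and pretraining
has nothing left to add), and the target adds a mild scanner-style
contrast shift (lung parenchyma -780 HU, soft tissue +60 HU). Each of the
six paired repeats runs a full 4-fold cross-validation of the target with
identical fold partitions in the fine-tuned and from-scratch arms, so the
repeat values compare like with like.

What a green recovery test establishes: that the full pipeline - phantom
in, preprocessing, encoding, attention fusion, risk head, cross-validated
training with selection by validation concordance - can recover a known
lesion-burden-to-hazard mapping well enough to approach the generator's
own discrimination ceiling, and that it finds no signal when none was
constructed. What it does not establish: performance on real CT data, with
real anatomy, scanner variation, or hazard shapes other than
constant-per-patient.

## Training profiles

Paper-scale defaults are kept verbatim in `cv_config()`: AdamW, base
learning rate 1e-4, decoupled weight decay 1e-2, batch size 4 volumes,
100 epochs, tenfold cross-validation with an inner 90/10 split, per-epoch
checkpointing and selection by validation concordance (ties to the earliest
epoch). The `"desk"` profile differs in one number: learning rate 1e-3.
The rationale is that 1e-4 is a fine-tuning rate for a pretrained backbone,
while the toy head and risk network start from random initialization; with
Adam's unit-scale steps, 100 epochs at 1e-4 move parameters a total
distance too small to fit even the training fold. Optional gradient
clipping (norm 5) exists behind a flag and is off by default; it is not
part of the reference procedure.

Fold splitting is unstratified at patient level. All randomness - fold
assignment, inner splits, initialization, dropout, permutation draws -
derives from one configuration seed via labelled child seeds, so any
command reruns bit-identically.

## Known limitations

* The validation folds at desk scale contain ~18-20 patients; concordance
  estimated on them is noisy, and the best-epoch selection rule therefore
  occasionally picks an early, undertrained checkpoint. This is a faithful
  property of the reference selection procedure at this cohort size, not an
  implementation artifact; the recovery experiment averages it over ten
  folds.
* The class-token ablation is inference-only (fixed random projections).
* NIfTI support covers the little-endian single-file subset the package
  itself writes; orientation matrices are ignored. DICOM support covers
  uncompressed single-frame explicit-VR-little-endian series.
* Multiple competing events are out of scope (k is binary), as is any
  learned segmentation model.
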