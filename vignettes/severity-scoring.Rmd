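---
title: "Continuous severity scores from ordinal labels: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous severity scores from ordinal labels: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many imaging endpoints — retinopathy-of-prematurity grade, the
Kellgren–Lawrence knee-osteoarthritis scale, mammographic breast
density — are recorded as K ordered categories although the underlying
biology is continuous. A model trained on those categories can still
carry fine-grained severity information in its *soft* outputs. This
package implements four ways of extracting a continuous severity score
from models trained with discrete ordinal labels only, and an
evaluation protocol that judges the scores against references finer
than the training labels.

## Models and score conversions

All four families share a small 3-block CNN backbone (3×3
convolutions, ReLU, 2×2 average pooling, global average pooling;
channel widths 8–16–32 by default). The heads differ:

* **Multi-class**: K softmax outputs, cross-entropy training. Score:
  the expected class index $\sum_{i=1}^{K} p_i (i-1)$, which is linear
  in the probabilities and spans $[0, K-1]$.
* **Ordinal (CORAL)**: $K-1$ binary threshold tasks "is the label
  above threshold $k$?". The head shares one weight vector across
  tasks with $K-1$ free biases, which structurally forces the
  threshold logits — and after sorting the biases, the sigmoid
  probabilities — to be rank-monotone. The loss is the sum of the
  $K-1$ binary cross-entropies with targets $\mathbb{1}[y > k]$.
  Score: $\sum_k \sigma(\hat y_k)$.
* **Regression**: one linear output trained by squared error on the
  integer labels; the raw output is the score (optionally clipped to
  $[0, K-1]$ for rescaled-error comparisons; clipping is irrelevant
  for rank metrics, which are monotone-invariant).
* **Twin**: a shared-weight embedding branch trained with a
  contrastive loss (margin 2.0) on same/different-class image pairs.
  Score: the median Euclidean distance between the target embedding
  and a pool of ten lowest-class anchor images. The even pool size
  makes the median the mean of the two central order statistics.

Two conventions deserve emphasis because printed sources are
inconsistent about them:

* **Threshold indicator direction.** We use $\mathbb{1}[y > k]$ as the
  positive target of threshold $k$. The opposite convention
  ($y \le k$) would make the threshold-probability *sum* decrease with
  severity, contradicting the score definition; the convention used
  here is the original CORAL one and makes the score increase with
  severity. The target vector is a run of ones followed by zeros and
  sums to $y$, which the unit tests pin down.
* **Ordinal score summation range.** The score sums exactly the $K-1$
  threshold probabilities the head produces (a sum "over K outputs" is
  not well-formed for a $K-1$-neuron head).

### Monte Carlo dropout

MC variants insert spatial (channel-wise) dropout after each backbone
block, train with it active, and keep it active at inference: N = 50
stochastic passes are averaged elementwise and the per-pass standard
deviation is reported as epistemic uncertainty. The default rate is
0.2 (rates in the 0.1–0.2 range are typical for this design; the rate
is a single per-model configuration value). Averaging is done on the
*probability* outputs; because the multi-class, ordinal and regression
scores are linear in those outputs, averaging before or after scoring
is identical to numerical precision (asserted at 1e−10 in the tests).
The twin median is nonlinear, so for twin models the per-pass median
distances are averaged instead — embeddings have no canonical mean
scale, distances do.

One master seed drives all per-pass dropout masks, so MC inference is
exactly reproducible.

### Rescaling to the 1–9 expert scale

Bounded scores are mapped affinely. The default `"paper"` mapping is
$3 \cdot \mathrm{score} + 1$, which for K = 3 spans $[1, 7]$ rather
than the full rating range; the `"full_range"` alternative
$8/(K-1)\cdot\mathrm{score} + 1$ spans $[1, 9]$ for any K. Both are
offered deliberately — the compressed map is the published default, the
full-range map the mathematically natural one — and the choice is a
config switch rather than a silent fix. Unbounded twin scores are
shifted by +1 and clipped; all outputs are clipped to $[1, 9]$.

## The synthetic data generator

The generator is first-class, tested code, not a fixture. It emulates
the study design:

* a continuous latent severity $s \sim U(0,1)$ per subject;
* a rendered 64×64 image whose central "lesion" disc grows in radius
  (3 px at $s=0$ to 0.3·side at $s=1$) and intensity (0.55 to 0.9),
  plus a vessel-like curve whose tortuosity grows with $s$, a smooth
  per-subject background (amplitude ≤ 0.3) fixed by a subject seed,
  and additive Gaussian pixel noise (sd 0.05 by default);
* ordinal labels by threshold discretization of $s$ (half-open bins:
  a severity exactly on a threshold belongs to the upper class —
  either convention would do, this one is documented and tested);
* test-split references finer than the labels: a total rank list
  (ascending in $s$; ties, which have probability zero for continuous
  $s$, would be broken by subject id so rank lists are total orders),
  9-point median ratings from five simulated raters
  ($\mathrm{clip}(\mathrm{round}(1 + 8(s + \varepsilon)), 1, 9)$,
  rater noise sd 0.1), and a continuous reference $s + N(0, 0.05^2)$
  standing in for an independent software-derived measurement;
* longitudinal second timepoints for 30% of subjects with
  $s_2 = \mathrm{clip}(s_1 + U(-0.3, 0.3), 0, 1)$, rendered on the
  same subject background — the change span deliberately covers both
  within-class and across-boundary transitions.

Splits are subject-level (all timepoints of a subject share a split),
with largest-remainder rounding of the split fractions.

What the generator does *not* emulate: photorealistic anatomy, rater
bias structure beyond i.i.d. Gaussian noise, label noise (labels are
exact discretizations of $s$), and class imbalance (severities are
uniform). Consequences for interpreting green tests: the synthetic
task is far easier than clinical data — the lesion is salient and the
latent severity nearly fully recoverable — so all model families reach
Spearman correlations near 1 and the *relative* ordering between
families compresses into sampling noise. Passing rank-recovery checks
demonstrates that the pipeline trains, scores and evaluates correctly;
it does not demonstrate clinical-scale performance differences between
families, which require hard data where multi-class models saturate
into per-class plateaus.

## Evaluation protocol

* **Spearman ρ** between predicted score and reference rank: Pearson
  correlation of average-tie rank vectors; zero rank variance is an
  explicit error, not an NA.
* **Normalized-rank MSE**: predicted ranks (average ties) and
  reference ranks both divided by n, mean squared difference;
  invariant under monotone transforms of the scores.
* **Clinically relevant AUROC**: Mann–Whitney formulation (ties count
  ½) at a binary grouping cut — classes ≤ c negative, > c positive;
  c = 1 for the default 3-class scheme, the analogue of
  normal/pre-plus vs plus.
* **Rating MSE**: rescaled scores vs 9-point median ratings.
* **Temporal-change MSE**: per subject, predicted change
  $\Delta\mathrm{score}$ vs reference change $\Delta\mathrm{rating}$
  between timepoints; differencing removes per-subject offsets, which
  the tests assert.

All metrics are bootstrapped (500 resamples by default) with 2.5/97.5
percentile intervals. The resampling unit is the image for
cross-sectional metrics and the subject pair for the temporal metric
(the unit is otherwise underdetermined; this is the natural choice).
Degenerate resamples — e.g. a single-class AUROC draw — are redrawn and
counted; a metric undefined on most draws is an error. Model pairs are
compared by a two-sided t-test on the two bootstrap sample vectors
with significance at p < 0.05. Bootstrap samples are not independent
draws, so this t-test is a fidelity-over-orthodoxy reproduction of the
published protocol rather than our statistical recommendation; the
comparison grid for 8 model variants has $\binom{8}{2} = 28$ cells per
metric. Zero-variance sample vectors are handled explicitly (identical
constants compare as p = 1, separated constants as significant) since
a t-test is undefined there.

## Numerical and design choices

* **CORAL bias ordering** is enforced by sorting at evaluation time
  rather than constrained optimization: simpler, testable, and
  preserves the monotonicity invariant whatever the optimizer did.
* **Binary cross-entropy with logits** uses the stable form
  $\max(x,0) - x t + \log(1 + e^{-|x|})$.
* **Anchor "typicality"** is operationalized two ways, both recorded
  in the pool object: the n class-0 training images with the highest
  class-0 confidence under an auxiliary multi-class model, or a seeded
  uniform sample when no auxiliary model is supplied.
* **Optimizer**: Adam, lr 1e−3, batch 32 — conventional defaults at
  this scale, recorded in the training config so runs are
  reproducible. Model selection keeps the epoch with the lowest
  validation loss (computed with dropout off, so selection is
  deterministic even for MC models).
* **Class balancing** (optional) is inverse-frequency sampling with
  replacement.
* **Determinism**: every stochastic operation runs under a locally
  set, restored RNG state derived from named seeds; training, MC
  inference, bootstrap and data generation are bit-reproducible given
  their seed arguments.
* **Engine**: the CNN is implemented in vectorized base R (padded
  im2col + one GEMM per convolution, hand-written backpropagation,
  verified against central finite differences in the tests at 1e−4).
  At the 64 px scale with the default 8–16–32 channel widths (a few
  thousand parameters) this trains a model in well under a minute on
  one CPU, which keeps the full test suite and the acceptance script
  inside a desk-scale budget.

## Problem sizes

The end-to-end study runs use 800 subjects (600 train / 100 validation
/ 100 ranked-test), K = 3, 64×64 images, 8 training epochs, 50 MC
passes and 500 bootstrap iterations — the package's chosen desk-scale
design point. Unit tests use 32 px images and smaller n so the whole
suite stays fast.

## Known limitations

* The backbone is a small CNN; residual-scale architectures and
  pretrained weights are out of scope, as is reproducing clinical
  results.
* Labels are noise-free discretizations, raters are i.i.d. Gaussian,
  severities uniform: inter-rater structure, label noise and class
  imbalance — all prominent in clinical data — are not modeled.
* On this easy synthetic task all families score near the ceiling, so
  between-family contrasts (the interesting clinical finding) are not
  resolvable here; the package demonstrates machinery, not clinical
  effect sizes.
* The t-test on bootstrap samples reproduces the published protocol;
  for new studies a paired bootstrap or permutation test would be
  preferable.
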